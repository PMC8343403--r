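test_that("sample weights are inversely proportional to class frequency", {
  labels <- rep(c("Relevant", "NotRelevant"), c(2, 8))
  w <- computeSampleWeights(labels)
  # 20% prevalence -> Relevant loss scaled by a factor of five
  expect_equal(unique(w[labels == "Relevant"]), 5)
  expect_equal(unique(w[labels == "NotRelevant"]), 1.25)
  # conservation: weights sum to n_classes x n
  expect_equal(sum(w), 2 * 10)
  # balanced classes -> uniform weight 2
  wBal <- computeSampleWeights(rep(c("Relevant", "NotRelevant"), 5))
  expect_true(all(wBal == 2))
  expect_error(computeSampleWeights(rep("Relevant", 5)), "both classes")
})

test_that("a linearly separable problem reaches dev F1 = 1 before the round cap", {
  sep <- separableFeatures(n = 120, seed = 1)
  idx <- stratifiedSplit(sep$y, c(train = 0.6, dev = 0.4), seed = 1)
  fit <- fitBoostedClassifier(sep$x[idx$train, ], sep$y[idx$train],
                              sep$x[idx$dev, ], sep$y[idx$dev],
                              config = fastConfig())
  expect_s4_class(fit, "TrainedPipeline")
  expect_equal(max(fit@devHistory), 1)
  expect_lt(fit@bestIteration, fit@config@maxRounds)
  # truncated ensemble classifies the dev part perfectly
  pred <- predict(fit, sep$x[idx$dev, ])
  expect_equal(precisionRecallF1(sep$y[idx$dev], pred$label)[["f1"]], 1)
})

test_that("label-shuffled data stays near the label-independent F1 ceiling", {
  set.seed(33)
  n <- 200
  y <- factor(rep(c("Relevant", "NotRelevant"), c(40, 160)),
              levels = labelLevels())
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  idx <- stratifiedSplit(y, c(train = 0.6, dev = 0.2, test = 0.2), seed = 2)
  fit <- fitBoostedClassifier(x[idx$train, ], y[idx$train],
                              x[idx$dev, ], y[idx$dev],
                              config = fastConfig())
  pred <- suppressMessages(predict(fit, x[idx$test, ]))
  f1 <- suppressMessages(
    precisionRecallF1(y[idx$test], pred$label))[["f1"]]
  # best label-independent F1 is the all-positive baseline 2p/(1+p)
  baseline <- 2 * 0.2 / 1.2
  expect_lt(f1, baseline + 0.25)
})

test_that("early stopping respects the patience window and the round cap", {
  sep <- separableFeatures(n = 80, seed = 3)
  idx <- stratifiedSplit(sep$y, c(train = 0.7, dev = 0.3), seed = 3)
  cfg <- boosterConfig(maxRounds = 40L, patience = 5L)
  fit <- fitBoostedClassifier(sep$x[idx$train, ], sep$y[idx$train],
                              sep$x[idx$dev, ], sep$y[idx$dev], config = cfg)
  expect_lte(fit@bestIteration, 40L)
  expect_lte(length(fit@devHistory), 40L)
  # recorded best is the running maximum of the history
  expect_equal(fit@devHistory[fit@bestIteration], max(fit@devHistory))
  # patience must be a positive number of rounds
  expect_error(boosterConfig(patience = 0L), "patience")
})

test_that("a dev set without positives is rejected", {
  sep <- separableFeatures(n = 60, seed = 4)
  devIdx <- which(sep$y == "NotRelevant")[1:10]
  trIdx <- setdiff(seq_along(sep$y), devIdx)
  expect_error(
    fitBoostedClassifier(sep$x[trIdx, ], sep$y[trIdx],
                         sep$x[devIdx, ], sep$y[devIdx],
                         config = fastConfig()),
    "no Relevant")
})

test_that("prediction handles thresholds, empty input and layout mismatches", {
  sep <- separableFeatures(n = 80, seed = 5)
  idx <- stratifiedSplit(sep$y, c(train = 0.7, dev = 0.3), seed = 5)
  fit <- fitBoostedClassifier(sep$x[idx$train, ], sep$y[idx$train],
                              sep$x[idx$dev, ], sep$y[idx$dev],
                              config = fastConfig())
  # boundary thresholds
  all_pos <- predict(fit, sep$x, threshold = 0)
  expect_true(all(all_pos$label == "Relevant"))
  none <- predict(fit, sep$x, threshold = 1.000001)
  expect_true(all(none$label == "NotRelevant"))
  # empty input -> empty output
  empty <- predict(fit, sep$x[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
  expect_identical(levels(empty$label), labelLevels())
  # repeated prediction is identical
  expect_identical(predict(fit, sep$x), predict(fit, sep$x))
  # column mismatch errors name the offending columns
  bad <- sep$x
  colnames(bad)[2] <- "unexpected"
  expect_error(predict(fit, bad), "unexpected")
})

test_that("scaling all sample weights by a constant leaves predictions unchanged", {
  sep <- separableFeatures(n = 100, seed = 6)
  idx <- stratifiedSplit(sep$y, c(train = 0.6, dev = 0.4), seed = 6)
  w <- computeSampleWeights(sep$y[idx$train])
  fit1 <- fitBoostedClassifier(sep$x[idx$train, ], sep$y[idx$train],
                               sep$x[idx$dev, ], sep$y[idx$dev],
                               config = fastConfig(), weights = w)
  fit2 <- fitBoostedClassifier(sep$x[idx$train, ], sep$y[idx$train],
                               sep$x[idx$dev, ], sep$y[idx$dev],
                               config = fastConfig(), weights = 7 * w)
  expect_equal(predict(fit1, sep$x)$probability,
               predict(fit2, sep$x)$probability, tolerance = 1e-6)
})

test_that("planted signal tokens dominate the fitted model's gain ranking", {
  gen <- generateCorpus(generatorConfig(nDocs = 300, seed = 8))
  fm <- featurizeCorpus(gen$corpus, minDF = 3)
  lab <- gen$labels$label
  idx <- stratifiedSplit(lab, c(train = 0.7, dev = 0.3), seed = 8)
  x <- combinedMatrix(fm)
  fit <- fitBoostedClassifier(x[idx$train, ], lab[idx$train],
                              x[idx$dev, ], lab[idx$dev],
                              config = fastConfig())
  top <- topGainFeatures(fit, 10)
  planted <- porterStem(c("clearance", "bioavailability", "cmax", "auc"))
  expect_true(any(top$feature %in% planted))
})

test_that("class weighting improves recall under strong imbalance", {
  # 5% prevalence; compare dev recall with and without weighting over
  # repeated seeds and require a strict majority-level improvement
  recalls <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 160
    nPos <- 8
    y <- factor(rep(c("Relevant", "NotRelevant"), c(nPos, n - nPos)),
                levels = labelLevels())
    y <- sample(y)
    # weak, noisy signal so the unweighted fit under-predicts positives
    x <- cbind(sig = ifelse(y == "Relevant", 1, 0) * 0.6 + rnorm(n, 0, 0.6),
               matrix(rnorm(n * 4), n, 4,
                      dimnames = list(NULL, paste0("n", 1:4))))
    idx <- stratifiedSplit(y, c(train = 0.6, dev = 0.4), seed = s)
    cfg <- fastConfig(seed = s)
    fitW <- fitBoostedClassifier(x[idx$train, ], y[idx$train],
                                 x[idx$dev, ], y[idx$dev], config = cfg)
    fitU <- fitBoostedClassifier(x[idx$train, ], y[idx$train],
                                 x[idx$dev, ], y[idx$dev], config = cfg,
                                 weights = rep(1, length(idx$train)))
    predW <- suppressMessages(predict(fitW, x[idx$dev, ]))
    predU <- suppressMessages(predict(fitU, x[idx$dev, ]))
    suppressMessages(c(
      precisionRecallF1(y[idx$dev], predW$label)[["recall"]],
      precisionRecallF1(y[idx$dev], predU$label)[["recall"]]))
  }, numeric(2))
  # paired one-sided comparison: weighted recall exceeds unweighted
  expect_gt(mean(recalls[1, ]), mean(recalls[2, ]))
  expect_gt(sum(recalls[1, ] > recalls[2, ]), sum(recalls[1, ] < recalls[2, ]))
})
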