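test_that("precision/recall/F1 follow the standard definitions", {
  # 2 TP, 0 FP, 2 FN: P = 1, R = 0.5, F1 = 2/3
  yTrue <- c("Relevant", "Relevant", "Relevant", "Relevant", "NotRelevant")
  yPred <- c("Relevant", "Relevant", "NotRelevant", "NotRelevant",
             "NotRelevant")
  m <- precisionRecallF1(yTrue, yPred)
  expect_equal(unname(m), c(1, 0.5, 2 / 3))
  # perfect prediction
  expect_equal(unname(precisionRecallF1(yTrue, yTrue)), c(1, 1, 1))
  # no predicted positives with true positives present -> all zeros
  expect_message(
    m0 <- precisionRecallF1(yTrue, rep("NotRelevant", 5)), "degenerate")
  expect_equal(unname(m0), c(0, 0, 0))
  expect_error(precisionRecallF1(yTrue, yPred[-1]), "length")
  # harmonic mean lies between precision and recall
  expect_true(m[["f1"]] >= min(m[["precision"]], m[["recall"]]))
  expect_true(m[["f1"]] <= max(m[["precision"]], m[["recall"]]))
})

test_that("Cohen's kappa matches its defining identity", {
  a <- rep(c("Relevant", "NotRelevant"), c(50, 50))
  k1 <- cohenKappa(a, a)
  expect_equal(k1@kappa, 1)
  # worked 2x2 example: 40 both-Relevant, 10 A-only, 5 B-only, 45 both-Not
  annA <- rep(c("R", "R", "N", "N"), c(40, 10, 5, 45))
  annB <- rep(c("R", "N", "R", "N"), c(40, 10, 5, 45))
  k <- cohenKappa(annA, annB)
  expect_equal(k@po, 0.85)
  expect_equal(k@pe, 0.5)
  expect_equal(k@kappa, 0.7)
  # chance-level agreement -> K = 0 (independent marginals constructed)
  annC <- rep(c("R", "R", "N", "N"), c(25, 25, 25, 25))
  annD <- rep(c("R", "N", "R", "N"), c(25, 25, 25, 25))
  expect_equal(cohenKappa(annC, annD)@kappa, 0)
  # symmetry
  k2 <- cohenKappa(annB, annA)
  expect_equal(k@kappa, k2@kappa)
  # degenerate chance agreement
  expect_error(cohenKappa(rep("R", 4), rep("R", 4)), "undefined")
})

test_that("stratified splits have exact sizes and per-part class balance", {
  labels <- rep(c("Relevant", "NotRelevant"), c(20, 80))
  idx <- stratifiedSplit(labels, c(train = 0.6, dev = 0.2, test = 0.2),
                         seed = 1)
  expect_identical(lengths(idx), c(train = 60L, dev = 20L, test = 20L))
  # each part's Relevant fraction within one document of 20%
  for (p in idx) {
    nRel <- sum(labels[p] == "Relevant")
    expect_lte(abs(nRel - 0.2 * length(p)), 1)
  }
  # parts partition the corpus
  all_idx <- unname(sort(unlist(idx)))
  expect_identical(all_idx, seq_along(labels))
  # deterministic given the seed, different across seeds
  idx2 <- stratifiedSplit(labels, seed = 1)
  expect_identical(idx, idx2)
  expect_false(identical(idx, stratifiedSplit(labels, seed = 2)))
  # a stratum too small for all parts errors
  expect_error(
    stratifiedSplit(rep(c("Relevant", "NotRelevant"), c(2, 98))),
    "too few")
})

test_that("metric summaries use interpolated percentiles and percent-scale IQV", {
  # constant samples collapse the interval
  const <- data.frame(precision = rep(0.8, 10), recall = rep(0.8, 10),
                      f1 = rep(0.8, 10))
  s <- summarizeMetrics(const)
  expect_true(all(s$summary$lower == 0.8 & s$summary$upper == 0.8))
  expect_equal(s$f1IQV, 0)
  # samples k/200: median 0.5025 under the interpolated percentile rule
  x <- (1:200) / 200
  s2 <- summarizeMetrics(data.frame(precision = x, recall = x, f1 = x))
  expect_equal(s2$summary$median[3], 0.5025)
  # symmetric samples: median equals mean
  sym <- c(0.2, 0.3, 0.5, 0.7, 0.8)
  s3 <- summarizeMetrics(data.frame(precision = sym, recall = sym, f1 = sym))
  expect_equal(s3$summary$median[1], mean(sym))
  # permutation invariance over iteration order
  perm <- sample(x)
  s4 <- summarizeMetrics(data.frame(precision = perm, recall = perm,
                                    f1 = perm))
  expect_equal(s4$summary, s2$summary)
})

test_that("the full hyperparameter grid enumerates 162 configurations", {
  g <- hyperGrid()
  expect_identical(nrow(g), 162L)
  expect_identical(sort(unique(g$minDF)), as.integer(2^(1:9)))
  expect_identical(sort(unique(g$maxDepth)), as.integer(2^(1:6)))
  expect_equal(sort(unique(g$colsampleBytree)), c(1/3, 2/3, 1))
  expect_error(gridSearchCV(list(), character(), grid = g[0, ]),
               "non-empty")
})

test_that("bootstrap comparison is deterministic and partitions every iteration", {
  sep <- separableFeatures(n = 100, prevalence = 0.2, seed = 9)
  bs1 <- bootstrapCompare(sep$x, sep$y, nIterations = 5,
                          config = fastConfig(), seed = 7)
  bs2 <- bootstrapCompare(sep$x, sep$y, nIterations = 5,
                          config = fastConfig(), seed = 7)
  expect_equal(bs1@samples, bs2@samples)
  expect_equal(bs1@summary, bs2@summary)
  expect_identical(nrow(bs1@samples), 5L)
  # 100 documents -> 60/20/20 split sizes, logged per iteration
  msgs <- capture_messages(
    bootstrapCompare(sep$x, sep$y, nIterations = 2, config = fastConfig(),
                     seed = 7, verbose = TRUE))
  expect_match(paste(msgs, collapse = ""), "split 60/20/20")
  expect_error(bootstrapCompare(sep$x, sep$y, nIterations = 2,
                                config = fastConfig()),
               "seed is mandatory")
})

test_that("grid search prefers the min_df that keeps a rare planted signal", {
  # the only informative term appears in exactly 3 documents, all Relevant;
  # any min_df > 3 destroys the informative column
  set.seed(14)
  nDocs <- 40
  labels <- rep("NotRelevant", nDocs)
  labels[1:3] <- "Relevant"
  terms <- lapply(seq_len(nDocs), function(i)
    sample(letters[1:6], 8, replace = TRUE))
  for (i in 1:3) terms[[i]] <- c(terms[[i]], "plantedsignal")
  names(terms) <- as.character(seq_len(nDocs))
  grid <- hyperGrid(minDF = c(2L, 8L), maxDepth = 2L, colsampleBytree = 1)
  res <- suppressMessages(
    gridSearchCV(terms, labels, grid = grid, kFolds = 2L,
                 config = fastConfig(), seed = 3))
  expect_identical(nrow(res$table), 2L)
  expect_lte(res$best$minDF, 3L)
  # single-point grid returns that point
  one <- suppressMessages(
    gridSearchCV(terms, labels, grid = grid[1, ], kFolds = 2L,
                 config = fastConfig(), seed = 3))
  expect_identical(one$best$minDF, grid$minDF[1])
})

test_that("stratified k folds keep both classes in every fold", {
  labels <- rep(c("Relevant", "NotRelevant"), c(15, 35))
  folds <- stratifiedKFolds(labels, k = 5, seed = 2)
  expect_identical(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_true(any(labels[folds == f] == "Relevant"))
    expect_true(any(labels[folds == f] == "NotRelevant"))
  }
  expect_error(stratifiedKFolds(rep(c("Relevant", "NotRelevant"),
                                    c(3, 47)), k = 5), "fewer")
})
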