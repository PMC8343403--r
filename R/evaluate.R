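# Metrics, inter-annotator agreement, the stratified bootstrap comparison
# protocol and grid-search cross-validation.

#' Precision, recall and F1 for the Relevant class
#'
#' F1 is the harmonic mean of precision and recall. Degenerate denominators
#' (no predicted positives, or no true positives) yield 0 with a message.
#'
#' @param yTrue,yPred equal-length label vectors (Relevant/NotRelevant,
#'   factor or character).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @examples
#' precisionRecallF1(c("Relevant", "Relevant", "NotRelevant"),
#'                   c("Relevant", "NotRelevant", "NotRelevant"))
#' @export
precisionRecallF1 <- function(yTrue, yPred) {
  yt <- .labels01(yTrue)
  yp <- .labels01(yPred)
  if (length(yt) != length(yp))
    stop("label vectors have different lengths: ", length(yt), " vs ",
         length(yp))
  tp <- sum(yp == 1L & yt == 1L)
  predPos <- sum(yp == 1L)
  truePos <- sum(yt == 1L)
  if (predPos == 0L || truePos == 0L)
    message("degenerate precision/recall denominator; reporting 0")
  p <- if (predPos > 0L) tp / predPos else 0
  r <- if (truePos > 0L) tp / truePos else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement `K = (p_o - p_e) / (1 - p_e)`, where `p_o` is
#' the fraction of documents with identical labels and `p_e = sum_c
#' marginal_a(c) * marginal_b(c)` the agreement expected by chance from the
#' annotators' marginal label frequencies.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return An [AgreementResult-class].
#' @examples
#' a <- rep(c("Relevant", "NotRelevant"), c(50, 50))
#' cohenKappa(a, a)  # K = 1
#' @export
cohenKappa <- function(labelsA, labelsB) {
  a <- as.character(labelsA)
  b <- as.character(labelsB)
  if (length(a) != length(b)) stop("label vectors have different lengths")
  if (length(a) == 0L) stop("empty label vectors")
  levs <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum(vapply(levs, function(l) mean(a == l) * mean(b == l), 0))
  if (abs(1 - pe) < 1e-12)
    stop("chance agreement p_e = 1: kappa undefined")
  new("AgreementResult", po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

#' Stratified three-way split
#'
#' Randomly partitions indices into parts with the given fractions while
#' preserving class proportions in every part (each class is allocated by
#' largest-remainder rounding, so each part's class count is within one
#' document of the exact proportion). Errors when a class is too small to
#' put at least one document in every part.
#'
#' @param labels label vector.
#' @param fractions numeric vector summing to 1, default `c(train = 0.6,
#'   dev = 0.2, test = 0.2)`.
#' @param seed integer seed for the split.
#' @return named list of integer index vectors (disjoint, union =
#'   `seq_along(labels)`).
#' @export
stratifiedSplit <- function(labels,
                            fractions = c(train = 0.6, dev = 0.2, test = 0.2),
                            seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- paste0("part", seq_along(fractions))
  lab <- as.character(labels)
  parts <- lapply(fractions, function(f) integer())
  rng <- .seededRNG(seed)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    if (length(idx) < length(fractions))
      stop("class '", cl, "' has only ", length(idx),
           " document(s): too few to populate all parts")
    idx <- rng$shuffle(idx)
    target <- fractions * length(idx)
    nPer <- floor(target)
    rem <- length(idx) - sum(nPer)
    if (rem > 0) {
      extra <- order(target - nPer, decreasing = TRUE)[seq_len(rem)]
      nPer[extra] <- nPer[extra] + 1L
    }
    if (any(nPer == 0L))
      stop("class '", cl, "' has only ", length(idx),
           " document(s): too few to populate all parts")
    cuts <- cumsum(c(0L, nPer))
    for (p in seq_along(fractions))
      parts[[p]] <- c(parts[[p]], idx[(cuts[p] + 1L):cuts[p + 1L]])
  }
  lapply(parts, sort)
}

# localised RNG: draws do not disturb (or depend on) the global stream
.seededRNG <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  withState <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      res <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
      res
    }
  }
  list(shuffle = withState(function(x) if (length(x) == 1L) x else sample(x)),
       runif = withState(stats::runif),
       rbinom = withState(stats::rbinom),
       sample = withState(sample),
       sampleInt = withState(sample.int))
}

#' Summarise bootstrap metric samples
#'
#' Median and 95% CI as the empirical 2.5th/97.5th percentiles (linear
#' interpolation between closest ranks, R's default type-7 quantile rule),
#' plus the F1 interquartile spread (IQV) on the percent scale.
#'
#' @param samples data.frame with columns `precision`, `recall`, `f1` (one
#'   row per iteration; at least 2 rows).
#' @return list with `summary` (data.frame metric, median, lower, upper)
#'   and `f1IQV` (75th minus 25th F1 percentile, x100).
#' @export
summarizeMetrics <- function(samples) {
  stopifnot(all(c("precision", "recall", "f1") %in% names(samples)))
  if (nrow(samples) < 2L) stop("need at least 2 samples to summarise")
  summ <- do.call(rbind, lapply(c("precision", "recall", "f1"), function(m) {
    x <- samples[[m]]
    q <- quantile(x, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
    data.frame(metric = m, median = q[2], lower = q[1], upper = q[3])
  }))
  iqr <- diff(quantile(samples$f1, c(0.25, 0.75), type = 7, names = FALSE))
  list(summary = summ, f1IQV = 100 * iqr)
}

.alignLabels <- function(labels, pmids) {
  if (is.data.frame(labels)) {
    idx <- match(pmids, labels$pmid)
    if (anyNA(idx)) stop("labels missing for pmid(s): ",
                         paste(head(pmids[is.na(idx)], 5), collapse = ", "))
    canonicalLabels(labels$label[idx])
  } else {
    canonicalLabels(labels)
  }
}

#' Bootstrap comparison of a pipeline configuration
#'
#' Repeats, `nIterations` times: stratified split of the corpus into temp
#' training / temp dev / temp test (default 60/20/20); fit on temp training
#' with inverse-class-frequency weights and F1 early stopping on temp dev;
#' record precision/recall/F1 on temp test. Iterations are independently
#' seeded from the master seed via a counter, so any single iteration is
#' reproducible in isolation, and two configurations run with the same seed
#' see identical splits.
#'
#' @param features a [FeatureMatrix-class] (or numeric/sparse matrix).
#' @param labels data.frame with `pmid`/`label` (matched against the
#'   feature rows) or a label vector aligned with the rows.
#' @param nIterations bootstrap iterations, default 200.
#' @param split fractions for training/dev/test, default `c(0.6, 0.2,
#'   0.2)`.
#' @param config a [BoosterConfig-class].
#' @param seed master seed (mandatory).
#' @param verbose log one line per iteration (iteration id, split sizes,
#'   best iteration, F1).
#' @return A [BootstrapSummary-class].
#' @export
bootstrapCompare <- function(features, labels, nIterations = 200L,
                             split = c(train = 0.6, dev = 0.2, test = 0.2),
                             config = boosterConfig(), seed,
                             verbose = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  x <- .asDesign(features)
  pmids <- if (is(features, "FeatureMatrix")) features@pmid else rownames(x)
  lab <- .alignLabels(labels, pmids)
  if (anyNA(lab)) stop("labels contain non-canonical values")
  if (length(lab) != nrow(x)) stop("labels and features sizes differ")
  if (length(unique(lab)) < 2L) stop("corpus must contain both classes")
  rows <- vector("list", nIterations)
  for (i in seq_len(nIterations)) {
    iterSeed <- as.integer((as.numeric(seed) + i) %% (2^31 - 1))
    idx <- stratifiedSplit(lab, split, seed = iterSeed)
    cfg <- config
    cfg@seed <- iterSeed
    fit <- fitBoostedClassifier(x[idx[[1]], , drop = FALSE], lab[idx[[1]]],
                                x[idx[[2]], , drop = FALSE], lab[idx[[2]]],
                                config = cfg)
    pred <- predict(fit, x[idx[[3]], , drop = FALSE])
    m <- precisionRecallF1(lab[idx[[3]]], pred$label)
    if (verbose)
      message(sprintf(
        "iteration %d: split %d/%d/%d, best_iteration %d, F1 %.3f",
        i, length(idx[[1]]), length(idx[[2]]), length(idx[[3]]),
        fit@bestIteration, m[["f1"]]))
    rows[[i]] <- data.frame(iteration = i, precision = m[["precision"]],
                            recall = m[["recall"]], f1 = m[["f1"]])
  }
  samples <- do.call(rbind, rows)
  s <- summarizeMetrics(samples)
  new("BootstrapSummary", samples = samples, summary = s$summary,
      f1IQV = s$f1IQV, nIterations = as.integer(nIterations),
      seed = as.integer(seed))
}

#' The exhaustive hyperparameter grid
#'
#' Cartesian product of `min_df` in (2, 512, x2), `max_depth` in (2, 64,
#' x2) and `colsample_bytree` in (1/3, 1, +1/3): 9 x 6 x 3 = 162
#' configurations. The number of boosting rounds is set by early stopping,
#' not by the grid. Defaults outside the search: min_df 20, max_depth 4,
#' colsample 1.
#'
#' @param minDF,maxDepth,colsampleBytree candidate values.
#' @return data.frame with one row per grid point.
#' @export
hyperGrid <- function(minDF = 2^(1:9), maxDepth = 2^(1:6),
                      colsampleBytree = c(1/3, 2/3, 1)) {
  expand.grid(minDF = as.integer(minDF), maxDepth = as.integer(maxDepth),
              colsampleBytree = colsampleBytree, KEEP.OUT.ATTRS = FALSE)
}

#' Stratified k folds
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..k), class-balanced.
#' @export
stratifiedKFolds <- function(labels, k = 5L, seed = 1L) {
  lab <- as.character(labels)
  folds <- integer(length(lab))
  rng <- .seededRNG(seed)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer documents than folds")
    idx <- rng$shuffle(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Exhaustive grid search with stratified cross-validation
#'
#' For every grid point, the bag-of-words vocabulary is rebuilt at that
#' point's `min_df`, and the mean Relevant-class F1 across stratified folds
#' is computed, with early stopping inside each fold using the fold's
#' held-out part as the dev set. Ties are broken by smaller `min_df`, then
#' smaller `max_depth`, then larger `colsample_bytree`. A grid point whose
#' `min_df` empties the vocabulary scores `NA` and cannot win.
#'
#' @param termsList per-document term lists (from [documentTerms()]).
#' @param labels labels aligned with `termsList` (vector, or data.frame
#'   with pmid/label matched against `names(termsList)`).
#' @param grid data.frame as from [hyperGrid()]; must be non-empty.
#' @param kFolds number of folds, default 5.
#' @param config base [BoosterConfig-class] (eta, rounds, patience,
#'   threshold).
#' @param seed integer seed for fold assignment and the engine.
#' @param dense optional dense block (documents x dims) appended to every
#'   encoding, e.g. pooled embeddings.
#' @return list with `best` (named list minDF/maxDepth/colsampleBytree),
#'   `meanF1`, and `table` (the grid with a meanF1 column).
#' @export
gridSearchCV <- function(termsList, labels, grid = hyperGrid(), kFolds = 5L,
                         config = boosterConfig(), seed = 1L, dense = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("grid must be non-empty")
  lab <- if (is.data.frame(labels)) .alignLabels(labels, names(termsList))
         else canonicalLabels(labels)
  if (anyNA(lab)) stop("labels contain non-canonical values")
  folds <- stratifiedKFolds(lab, kFolds, seed = seed)
  meanF1 <- rep(NA_real_, nrow(grid))
  encCache <- new.env(parent = emptyenv())
  for (g in seq_len(nrow(grid))) {
    key <- as.character(grid$minDF[g])
    x <- encCache[[key]]
    if (is.null(x)) {
      x <- tryCatch({
        vocab <- buildVocabulary(termsList, minDF = grid$minDF[g])
        bow <- encodeBow(termsList, vocab)
        if (!is.null(dense)) cbind(bow, Matrix::Matrix(dense, sparse = TRUE))
        else bow
      }, error = function(e) NULL)
      encCache[[key]] <- if (is.null(x)) "empty" else x
      x <- encCache[[key]]
    }
    if (identical(x, "empty")) next
    f1s <- numeric(kFolds)
    for (f in seq_len(kFolds)) {
      trIdx <- which(folds != f)
      heldIdx <- which(folds == f)
      cfg <- config
      cfg@maxDepth <- grid$maxDepth[g]
      cfg@colsampleBytree <- grid$colsampleBytree[g]
      cfg@seed <- as.integer((as.numeric(seed) + 1000 * g + f) %% (2^31 - 1))
      fit <- fitBoostedClassifier(x[trIdx, , drop = FALSE], lab[trIdx],
                                  x[heldIdx, , drop = FALSE], lab[heldIdx],
                                  config = cfg)
      pred <- predict(fit, x[heldIdx, , drop = FALSE])
      f1s[f] <- precisionRecallF1(lab[heldIdx], pred$label)[["f1"]]
    }
    meanF1[g] <- mean(f1s)
  }
  if (all(is.na(meanF1)))
    stop("no grid point produced a usable vocabulary")
  ord <- order(-meanF1, grid$minDF, grid$maxDepth, -grid$colsampleBytree,
               na.last = TRUE)
  bestIdx <- ord[1]
  tab <- cbind(grid, meanF1 = meanF1)
  list(best = list(minDF = grid$minDF[bestIdx],
                   maxDepth = grid$maxDepth[bestIdx],
                   colsampleBytree = grid$colsampleBytree[bestIdx]),
       meanF1 = meanF1[bestIdx], table = tab)
}
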