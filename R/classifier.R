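# Class-weighted gradient-boosted tree classifier with F1-based early
# stopping. The boosting engine is xgboost, wrapped behind this module's
# surface; the ensemble is H_L(x) = sum_l eta * w_l * f_l(x) with each
# learner's weight w_l absorbed into its fitted leaf values.

.labels01 <- function(labels) {
  lab <- canonicalLabels(labels)
  if (anyNA(lab)) stop("labels must be Relevant / NotRelevant")
  as.integer(lab == "Relevant")
}

#' Inverse-class-frequency sample weights
#'
#' Sample `i` gets weight `n / n_class(i)`, i.e. a class with frequency `p`
#' is weighted `1/p`: at 20% prevalence every Relevant sample's loss is
#' scaled by a factor of five. Weights sum to (number of classes) x n.
#'
#' @param labels Relevant/NotRelevant labels (factor or character).
#' @return numeric vector of per-sample weights.
#' @examples
#' computeSampleWeights(rep(c("Relevant", "NotRelevant"), c(2, 8)))
#' @export
computeSampleWeights <- function(labels) {
  y <- .labels01(labels)
  n <- length(y)
  nPos <- sum(y)
  if (nPos == 0L || nPos == n)
    stop("both classes must be present to compute class weights")
  ifelse(y == 1L, n / nPos, n / (n - nPos))
}

.f1FromCounts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# weights enter the engine normalised to mean 1 so that the overall weight
# scale cannot interact with the engine's L2 leaf regularisation: only the
# weight ratios matter, and rescaling all weights by a positive constant
# leaves the fit unchanged
.normWeights <- function(weights) {
  if (any(weights <= 0)) stop("sample weights must be positive")
  weights / mean(weights)
}

# dev-set F1 at probability threshold 0.5; the engine hands the custom
# metric raw margins, and margin 0 is probability 0.5
.f1EvalMetric <- function(preds, dtrain) {
  lab <- xgboost::getinfo(dtrain, "label")
  pos <- preds >= 0
  tp <- sum(pos & lab == 1)
  list(metric = "f1",
       value = .f1FromCounts(tp, sum(pos) - tp, sum(lab == 1) - tp))
}

.asDesign <- function(x) {
  if (is(x, "FeatureMatrix")) combinedMatrix(x)
  else if (is.matrix(x) || is(x, "sparseMatrix")) x
  else stop("features must be a FeatureMatrix, matrix or sparse matrix")
}

#' Fit the boosted triage classifier
#'
#' Trees are added sequentially to minimise the weighted average
#' cross-entropy; training samples carry inverse-class-frequency weights
#' (from [computeSampleWeights()], or user-supplied). Boosting halts at
#' `maxRounds` or when the F1 on the dev set (at threshold 0.5) has not
#' improved for `patience` rounds, and the returned ensemble is truncated
#' to the best-dev-F1 iteration. All engine hyperparameters not exposed in
#' [boosterConfig()] stay at the engine's documented defaults.
#'
#' @param x training features: [FeatureMatrix-class], matrix or sparse
#'   matrix.
#' @param y training labels (Relevant/NotRelevant).
#' @param xDev,yDev dev set used for early stopping; `yDev` must contain at
#'   least one Relevant document (otherwise F1 is undefined as a stopping
#'   signal).
#' @param config a [BoosterConfig-class].
#' @param weights per-sample training weights; default
#'   `computeSampleWeights(y)`. Weights are normalised to mean 1 before
#'   fitting, so only their ratios matter and rescaling all weights by a
#'   positive constant leaves the fit unchanged.
#' @return A [TrainedPipeline-class].
#' @export
fitBoostedClassifier <- function(x, y, xDev, yDev,
                                 config = boosterConfig(),
                                 weights = computeSampleWeights(y)) {
  stopifnot(is(config, "BoosterConfig"))
  xm <- .asDesign(x)
  xd <- .asDesign(xDev)
  yTrain <- .labels01(y)
  yD <- .labels01(yDev)
  if (length(yTrain) != nrow(xm)) stop("x and y sizes differ")
  if (length(yD) != nrow(xd)) stop("xDev and yDev sizes differ")
  if (sum(yD) == 0L)
    stop("dev set has no Relevant documents; F1 early stopping undefined")
  if (!is.null(colnames(xm)) && !is.null(colnames(xd)) &&
      !identical(colnames(xm), colnames(xd)))
    stop("train and dev feature layouts differ")
  dtrain <- xgboost::xgb.DMatrix(xm, label = yTrain,
                                 weight = .normWeights(weights),
                                 nthread = 1)
  ddev <- xgboost::xgb.DMatrix(xd, label = yD, nthread = 1)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    learning_rate = config@eta,
    max_depth = config@maxDepth,
    colsample_bytree = config@colsampleBytree,
    seed = config@seed,
    nthread = 1)
  bst <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = config@maxRounds,
    evals = list(dev = ddev), custom_metric = .f1EvalMetric,
    early_stopping_rounds = config@patience, maximize = TRUE, verbose = 0)
  bestIter0 <- as.integer(xgboost::xgb.attr(bst, "best_iteration"))
  if (length(bestIter0) == 0L || is.na(bestIter0))
    bestIter0 <- xgboost::xgb.get.num.boosted.rounds(bst) - 1L
  evalLog <- attributes(bst)$evaluation_log
  devHistory <- if (!is.null(evalLog)) as.numeric(evalLog$dev_f1) else numeric()
  featNames <- colnames(xm)
  if (is.null(featNames)) featNames <- sprintf("f%d", seq_len(ncol(xm)))
  new("TrainedPipeline", booster = bst, bestIteration = bestIter0 + 1L,
      threshold = config@threshold, featureNames = featNames,
      config = config, devHistory = devHistory)
}

#' Predict Relevant-class probabilities and labels
#'
#' Uses the ensemble truncated at the best early-stopping iteration. A
#' document is labelled `Relevant` iff its probability is `>= threshold`.
#'
#' @param object a [TrainedPipeline-class].
#' @param newdata features with the training column layout
#'   ([FeatureMatrix-class], matrix or sparse matrix); zero rows allowed.
#' @param threshold decision threshold override; default the pipeline's.
#' @param ... ignored.
#' @return data.frame with columns `probability` and `label` (factor with
#'   [labelLevels()]), one row per input document.
#' @export
setMethod("predict", "TrainedPipeline",
  function(object, newdata, threshold = object@threshold, ...) {
    xm <- .asDesign(newdata)
    if (!is.null(colnames(xm)) &&
        !identical(colnames(xm), object@featureNames)) {
      missing <- setdiff(object@featureNames, colnames(xm))
      extra <- setdiff(colnames(xm), object@featureNames)
      stop("feature layout mismatch; missing: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...", "; extra: ",
           paste(head(extra, 5), collapse = ", "),
           if (length(extra) > 5) " ...")
    }
    if (ncol(xm) != length(object@featureNames))
      stop("expected ", length(object@featureNames), " feature columns, got ",
           ncol(xm))
    if (nrow(xm) == 0L)
      return(data.frame(probability = numeric(),
                        label = factor(character(), levels = labelLevels())))
    prob <- predict(object@booster, xm,
                    iterationrange = c(1, object@bestIteration))
    lab <- factor(ifelse(prob >= threshold, "Relevant", "NotRelevant"),
                  levels = labelLevels())
    out <- data.frame(probability = as.numeric(prob), label = lab)
    if (!is.null(rownames(xm))) out$pmid <- rownames(xm)
    out
  })

#' Features ranked by total split gain
#'
#' @param pipeline a [TrainedPipeline-class].
#' @param k number of features to return (default 10).
#' @return data.frame with columns `feature` and `gain`, highest gain
#'   first.
#' @export
topGainFeatures <- function(pipeline, k = 10L) {
  stopifnot(is(pipeline, "TrainedPipeline"))
  imp <- xgboost::xgb.importance(model = pipeline@booster)
  head(data.frame(feature = imp$Feature, gain = imp$Gain), k)
}
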