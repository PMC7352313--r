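#' Tie-aware AUC by rank concordance
#'
#' Computes the area under the ROC curve as the Mann-Whitney concordance
#' probability: the fraction of (case, control) pairs in which the case
#' outscores the control, counting ties as one half --
#' \deqn{AUC = (\#\{case > control\} + 0.5\,\#\{ties\}) / (n_{case} n_{control}).}
#' For tie-free scores this equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric score vector (any monotone transform gives the
#'   same AUC).
#' @param labels \code{case}/\code{control} vector aligned with
#'   \code{scores}; at least one of each is required.
#' @return AUC in \eqn{[0, 1]}.
#' @examples
#' computeAUC(c(0.9, 0.1), c("case", "control"))   # 1
#' computeAUC(c(0.5, 0.5), c("case", "control"))   # 0.5
#' @export
computeAUC <- function(scores, labels) {
  labels <- checkLabels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  isCase <- labels == "case"
  m <- sum(isCase)
  n <- sum(!isCase)
  if (m == 0L || n == 0L) {
    stop("AUC requires at least one case and one control")
  }
  r <- rank(scores)  # midranks make the concordance tie-aware
  (sum(r[isCase]) - m * (m + 1) / 2) / (m * n)
}

#' Score threshold achieving a target specificity
#'
#' Returns the operating threshold \eqn{t} for the decision rule
#' \dQuote{call case iff score > t}: the smallest control order statistic
#' whose achieved specificity (fraction of controls with score
#' \eqn{\le t}) is at least \code{target}, i.e. the
#' \eqn{\lceil target \cdot n \rceil}-th smallest control score. The
#' achieved training specificity is therefore always \eqn{\ge} target,
#' and no smaller order statistic achieves it.
#'
#' @param controlScores Non-empty numeric vector of control scores.
#' @param target Target specificity in (0, 1].
#' @return The threshold (a control score value).
#' @examples
#' thresholdAtSpecificity(1:20 / 20, 0.95)  # the 19th smallest, 0.95
#' @export
thresholdAtSpecificity <- function(controlScores, target) {
  if (!length(controlScores)) stop("control scores must be non-empty")
  if (length(target) != 1L || is.na(target) || target <= 0 || target > 1) {
    stop("target specificity must be in (0, 1]")
  }
  n <- length(controlScores)
  k <- as.integer(ceiling(target * n - 1e-9))
  sort(controlScores)[k]
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Applies the rule \dQuote{case iff score > t} (strict, so tied-at-
#' threshold subjects are called control -- this matters for discrete
#' vote-fraction scores) and reports sensitivity (fraction of cases above
#' \code{t}), specificity (fraction of controls at or below \code{t}),
#' raw accuracy, and, when stages are supplied, sensitivity within each
#' tumor stage's cases.
#'
#' @param scores Numeric scores.
#' @param labels \code{case}/\code{control} vector.
#' @param threshold Finite decision threshold.
#' @param stages Optional integer stages 1-4 for cases (\code{NA} allowed
#'   for controls); when given, every case must have a stage.
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy} and \code{perStageSensitivity}
#'   (named numeric over stages \code{"1".."4"}, \code{NA} where a stage
#'   has no cases; \code{NULL} when \code{stages} is missing).
#' @examples
#' evaluateAtThreshold(c(0.9, 0.8, 0.2, 0.1),
#'                     c("case", "case", "control", "control"), 0.5)
#' @export
evaluateAtThreshold <- function(scores, labels, threshold, stages = NULL) {
  labels <- checkLabels(labels)
  stopifnot(length(scores) == length(labels),
            length(threshold) == 1L, is.finite(threshold))
  isCase <- labels == "case"
  called <- scores > threshold
  sens <- if (any(isCase)) mean(called[isCase]) else NA_real_
  spec <- if (any(!isCase)) mean(!called[!isCase]) else NA_real_
  acc <- mean(called == isCase)
  perStage <- NULL
  if (!is.null(stages)) {
    perStage <- stageSensitivity(scores, labels, stages, threshold)
  }
  list(threshold = threshold, sensitivity = sens, specificity = spec,
       accuracy = acc, perStageSensitivity = perStage)
}

#' Stage-stratified sensitivity
#'
#' Sensitivity of the rule \dQuote{case iff score > t} computed within
#' each tumor stage's cases; a stage with no cases is reported as
#' \code{NA}. Used to check that diagnostic performance holds in early
#' (stage 1-2) disease, where single markers are weakest.
#'
#' @inheritParams evaluateAtThreshold
#' @param stages Integer stages 1-4; required (non-\code{NA}) for every
#'   case.
#' @param threshold Decision threshold.
#' @return Named numeric vector over stages \code{"1".."4"}.
#' @examples
#' stageSensitivity(c(0.9, 0.2, 0.8, 0.1),
#'                  c("case", "case", "case", "control"),
#'                  c(1, 2, 3, NA), 0.5)
#' @export
stageSensitivity <- function(scores, labels, stages, threshold) {
  labels <- checkLabels(labels)
  stopifnot(length(scores) == length(labels), length(stages) == length(labels))
  isCase <- labels == "case"
  if (any(is.na(stages[isCase]))) {
    stop("every case must have a stage")
  }
  called <- scores > threshold
  vapply(as.character(1:4), function(s) {
    idx <- isCase & !is.na(stages) & stages == as.integer(s)
    if (any(idx)) mean(called[idx]) else NA_real_
  }, numeric(1))
}

#' Label-stratified fold assignment
#'
#' Assigns each subject to one of \code{k} folds, balancing the
#' case/control ratio across folds: within each class the fold sizes
#' differ by at most one.
#'
#' @param labels Class labels (any two-or-more-level vector).
#' @param k Number of folds (\eqn{\ge 2}); every class must have at least
#'   \code{k} members.
#' @param ids Optional unique subject identifiers; when given, folds are
#'   drawn over id-sorted strata so each subject's fold depends only on
#'   its id, not on row order.
#' @return Integer vector of fold ids in \code{1..k}.
#' @examples
#' table(stratifiedFolds(rep(c("case", "control"), c(10, 20)), 5))
#' @export
stratifiedFolds <- function(labels, k, ids = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  labels <- as.character(labels)
  folds <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < k) {
      stop(sprintf(
        "class '%s' has %d subjects, fewer than k = %d folds; lower k",
        lab, length(idx), k))
    }
    if (!is.null(ids)) idx <- idx[order(ids[idx], method = "radix")]
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Pooled out-of-fold scores under stratified k-fold cross-validation
#'
#' Fits the algorithm on each of \code{k} label-stratified training folds
#' and scores the held-out subjects, returning the pooled out-of-fold
#' score vector (every subject scored exactly once by a model that never
#' saw it). Fold assignment and each per-fold fit are seeded
#' deterministically from \code{seed}.
#'
#' @param spec A \linkS4class{ModelSpec}.
#' @param features Numeric subjects x features matrix.
#' @param labels \code{case}/\code{control} vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Numeric vector of out-of-fold scores aligned with the input
#'   rows.
#' @seealso [crossValidatedAUC()]
#' @export
crossValidatedScores <- function(spec, features, labels, k = 10L, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  labels <- factor(checkLabels(labels), levels = c("control", "case"))
  folds <- withSeed(deriveSeed(seed, "folds", k),
                    stratifiedFolds(labels, k, rownames(features)))
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    hold <- folds == f
    foldSpec <- new("ModelSpec", algorithm = spec@algorithm,
                    hyperparameters = spec@hyperparameters,
                    seed = deriveSeed(seed, spec@algorithm, f))
    scorer <- fitClassifier(foldSpec, features[!hold, , drop = FALSE],
                            labels[!hold])
    scores[hold] <- scoreSamples(scorer, features[hold, , drop = FALSE])
  }
  scores
}

#' Cross-validated AUC
#'
#' Stratified k-fold cross-validation of one algorithm on one feature
#' matrix. By default the out-of-fold scores are pooled and a single AUC
#' is computed on the pooled vector (lower-variance than per-fold
#' averaging, and well-defined even when a fold is small);
#' \code{pooling = "average"} instead averages the per-fold AUCs.
#'
#' @inheritParams crossValidatedScores
#' @param pooling \code{"pooled"} (default) or \code{"average"}.
#' @return A single AUC estimate.
#' @examples
#' x <- cbind(m = c(rnorm(30, 3), rnorm(30)))
#' y <- rep(c("case", "control"), each = 30)
#' crossValidatedAUC(modelSpec("GLM"), x, y, k = 5, seed = 1)
#' @export
crossValidatedAUC <- function(spec, features, labels, k = 10L, seed = 1L,
                              pooling = c("pooled", "average")) {
  pooling <- match.arg(pooling)
  labels <- checkLabels(labels)
  if (pooling == "pooled") {
    scores <- crossValidatedScores(spec, features, labels, k, seed)
    return(computeAUC(scores, labels))
  }
  folds <- withSeed(deriveSeed(seed, "folds", k),
                    stratifiedFolds(factor(labels,
                                           levels = c("control", "case")),
                                    k, rownames(features)))
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    hold <- folds == f
    foldSpec <- new("ModelSpec", algorithm = spec@algorithm,
                    hyperparameters = spec@hyperparameters,
                    seed = deriveSeed(seed, spec@algorithm, f))
    scorer <- fitClassifier(foldSpec, features[!hold, , drop = FALSE],
                            labels[!hold])
    aucs[f] <- computeAUC(
      scoreSamples(scorer, features[hold, , drop = FALSE]), labels[hold])
  }
  mean(aucs)
}
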