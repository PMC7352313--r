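#' @importFrom glmnet glmnet cv.glmnet
#' @importFrom e1071 svm
#' @importFrom ranger ranger
NULL

#' Default hyperparameters of the classifier suite
#'
#' Random forest: 500 trees, \code{sqrt(p)} candidate features per split.
#' SVM: radial kernel, unit cost, kernel width \code{1/p}. Ridge: penalty
#' chosen by 5-fold internal cross-validation on the training data unless
#' \code{lambda} is fixed. GLM: plain IRLS logistic regression.
#' \code{maxFeatures} is a hard cap on the feature count accepted by
#' [fitClassifier()].
#'
#' @return Named list of per-algorithm hyperparameter lists.
#' @examples
#' defaultHyperparameters()$RF
#' @export
defaultHyperparameters <- function() {
  list(GLM = list(maxit = 50L, maxFeatures = 64L),
       RIDGE = list(lambda = NULL, internalFolds = 5L, nlambda = 100L,
                    maxFeatures = 64L),
       SVM = list(cost = 1, gamma = NULL, kernel = "radial",
                  maxFeatures = 64L),
       RF = list(numTrees = 500L, mtry = NULL, maxFeatures = 64L),
       GLM_RF = list(maxit = 50L, numTrees = 500L, mtry = NULL,
                     maxFeatures = 64L))
}

#' Construct a ModelSpec
#'
#' @param algorithm One of \code{"GLM"}, \code{"RIDGE"}, \code{"SVM"},
#'   \code{"RF"}, \code{"GLM_RF"}.
#' @param hyperparameters Named list overriding entries of
#'   [defaultHyperparameters()] for that algorithm; unknown names are an
#'   error.
#' @param seed Integer seed making the fit deterministic.
#' @return A validated \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("RF", list(numTrees = 100L), seed = 3)
#' @export
modelSpec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithm <- as.character(algorithm)
  if (length(algorithm) != 1L || !algorithm %in% panelAlgorithms()) {
    stop("algorithm must be one of ",
         paste(panelAlgorithms(), collapse = ", "))
  }
  hp <- modifyList(defaultHyperparameters()[[algorithm]],
                   hyperparameters, keep.null = TRUE)
  new("ModelSpec", algorithm = algorithm, hyperparameters = hp,
      seed = as.integer(seed))
}

checkFeatures <- function(features, labels, hp, fitting = TRUE) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("features must be a numeric matrix")
  }
  if (is.null(colnames(features)) || anyDuplicated(colnames(features))) {
    stop("feature columns must have unique names")
  }
  if (anyNA(features)) stop("features must not contain missing values")
  if (fitting) {
    if (ncol(features) > hp$maxFeatures) {
      stop(sprintf("feature count %d exceeds maxFeatures = %d",
                   ncol(features), hp$maxFeatures))
    }
    tab <- table(factor(labels, levels = c("control", "case")))
    if (any(tab < 2L)) {
      stop("training data must contain at least 2 subjects per class")
    }
  }
  invisible(TRUE)
}

#' Fit one of the five classification algorithms
#'
#' Fits the algorithm named by \code{spec} to a feature matrix and binary
#' labels, returning a \linkS4class{PanelScorer} whose scores (via
#' [scoreSamples()]) are probability-scale: in \eqn{[0, 1]}, higher means
#' more case-like.
#'
#' \itemize{
#'   \item \code{GLM}: unpenalized logistic regression; score is the
#'     fitted case probability.
#'   \item \code{RIDGE}: L2-penalized logistic regression; the penalty is
#'     fixed via the \code{lambda} hyperparameter or chosen by stratified
#'     internal cross-validation on the training data.
#'   \item \code{SVM}: radial-kernel support vector machine; the margin is
#'     mapped to \eqn{[0, 1]} by a monotone sigmoid, which leaves AUCs
#'     unchanged (rank-preserving) and only affects threshold placement.
#'   \item \code{RF}: probability random forest; score is the case vote
#'     fraction.
#'   \item \code{GLM_RF}: fits both GLM and RF; score is their unweighted
#'     mean, combining the linear and non-linear views of the data.
#' }
#'
#' Fits are deterministic given \code{spec@seed}; refitting with the same
#' seed reproduces identical scores.
#'
#' @param spec A \linkS4class{ModelSpec}.
#' @param features Numeric subjects x features matrix with column names.
#' @param labels Factor or character vector of \code{case}/\code{control},
#'   at least 2 subjects per class.
#' @return A \linkS4class{PanelScorer}.
#' @examples
#' x <- cbind(m = c(rnorm(20, 2), rnorm(20)))
#' y <- rep(c("case", "control"), each = 20)
#' sc <- fitClassifier(modelSpec("GLM"), x, y)
#' range(scoreSamples(sc, x))
#' @export
fitClassifier <- function(spec, features, labels) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  labels <- factor(checkLabels(labels), levels = c("control", "case"))
  hp <- spec@hyperparameters
  checkFeatures(features, labels, hp)
  if (nrow(features) != length(labels)) {
    stop("features and labels must have matching lengths")
  }
  fits <- withSeed(spec@seed, switch(spec@algorithm,
    GLM = list(glm = fitLogistic(features, labels, hp$maxit)),
    RIDGE = list(ridge = fitRidge(features, labels, hp, spec@seed)),
    SVM = list(svm = fitSvm(features, labels, hp)),
    RF = list(rf = fitForest(features, labels, hp, spec@seed)),
    GLM_RF = list(glm = fitLogistic(features, labels, hp$maxit),
                  rf = fitForest(features, labels, hp,
                                 deriveSeed(spec@seed, "rf")))))
  new("PanelScorer", spec = spec, fits = fits,
      schema = colnames(features))
}

fitLogistic <- function(x, y, maxit) {
  fit <- suppressWarnings(stats::glm.fit(
    cbind("(Intercept)" = 1, x), as.integer(y == "case"),
    family = binomial(), control = list(maxit = maxit)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased columns contribute nothing
  list(beta = beta)
}

scoreLogistic <- function(fit, x) {
  plogis(drop(cbind(1, x) %*% fit$beta))
}

fitRidge <- function(x, y, hp, seed) {
  pad <- ncol(x) == 1L  # glmnet requires >= 2 columns
  if (pad) x <- cbind(x, .pad0 = 0)
  if (!is.null(hp$lambda)) {
    fit <- glmnet(x, y, family = "binomial", alpha = 0,
                  lambda = hp$lambda)
    lambda <- hp$lambda
  } else {
    foldid <- withSeed(deriveSeed(seed, "ridge-cv"),
                       stratifiedFolds(y, hp$internalFolds))
    cv <- cv.glmnet(x, y, family = "binomial", alpha = 0,
                    foldid = foldid, nlambda = hp$nlambda)
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  }
  list(fit = fit, lambda = lambda, pad = pad)
}

scoreRidge <- function(fit, x) {
  if (fit$pad) x <- cbind(x, .pad0 = 0)
  drop(predict(fit$fit, newx = x, s = fit$lambda, type = "response"))
}

fitSvm <- function(x, y, hp) {
  args <- list(x = x, y = y, kernel = hp$kernel, cost = hp$cost,
               probability = FALSE)
  if (!is.null(hp$gamma)) args$gamma <- hp$gamma
  suppressWarnings(do.call(svm, args))  # constant columns cannot be scaled
}

scoreSvm <- function(fit, x) {
  pred <- suppressWarnings(predict(fit, x, decision.values = TRUE))
  d <- drop(attr(pred, "decision.values"))
  # the decision value is positive for the class named first in the
  # "<first>/<second>" column label; orient so higher = case
  first <- strsplit(colnames(attr(pred, "decision.values")),
                    "/", fixed = TRUE)[[1L]][1L]
  if (identical(first, "case")) plogis(d) else plogis(-d)
}

fitForest <- function(x, y, hp, seed) {
  args <- list(x = x, y = y, num.trees = hp$numTrees, probability = TRUE,
               num.threads = 1L, seed = seed)
  if (!is.null(hp$mtry)) args$mtry <- hp$mtry
  do.call(ranger, args)
}

scoreForest <- function(fit, x) {
  predict(fit, data = x, num.threads = 1L)$predictions[, "case"]
}

#' Score subjects with a fitted classifier
#'
#' @param scorer A \linkS4class{PanelScorer} from [fitClassifier()].
#' @param features Numeric matrix whose columns match the training schema
#'   (any column order; a mismatch in the column set is an error).
#' @return Numeric vector of scores in \eqn{[0, 1]}, one per row; higher
#'   means more case-like. Zero rows give an empty vector.
#' @examples
#' x <- cbind(m = c(rnorm(20, 2), rnorm(20)))
#' y <- rep(c("case", "control"), each = 20)
#' sc <- fitClassifier(modelSpec("RF", list(numTrees = 50L)), x, y)
#' scoreSamples(sc, x[1:3, , drop = FALSE])
#' @export
scoreSamples <- function(scorer, features) {
  stopifnot(is(scorer, "PanelScorer"))
  checkFeatures(features, NULL, NULL, fitting = FALSE)
  if (!setequal(colnames(features), scorer@schema)) {
    stop("feature columns do not match the fitted schema; expected: ",
         paste(scorer@schema, collapse = ", "))
  }
  features <- features[, scorer@schema, drop = FALSE]
  if (nrow(features) == 0L) return(numeric(0))
  s <- switch(scorer@spec@algorithm,
    GLM = scoreLogistic(scorer@fits$glm, features),
    RIDGE = scoreRidge(scorer@fits$ridge, features),
    SVM = scoreSvm(scorer@fits$svm, features),
    RF = scoreForest(scorer@fits$rf, features),
    GLM_RF = combineGlmRf(scoreLogistic(scorer@fits$glm, features),
                          scoreForest(scorer@fits$rf, features)))
  unname(pmin(pmax(s, 0), 1))
}

#' Combine GLM and RF scores
#'
#' The GLM+RF algorithm joins a linear and a non-linear view of the data
#' by taking the unweighted element-wise mean of the two probability-scale
#' score vectors.
#'
#' @param glmScores,rfScores Equal-length numeric score vectors in
#'   \eqn{[0, 1]}, aligned subject-by-subject.
#' @return Numeric vector of averaged scores.
#' @examples
#' combineGlmRf(c(0, 1), c(1, 0))
#' @export
combineGlmRf <- function(glmScores, rfScores) {
  if (length(glmScores) != length(rfScores)) {
    stop("score vectors must have equal length")
  }
  (glmScores + rfScores) / 2
}
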