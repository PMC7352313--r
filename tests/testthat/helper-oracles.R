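# Independent brute-force oracles used to check the package's
# implementations on small instances.

`%||%` <- function(a, b) if (is.null(a)) b else a

# AUC by exhaustive pairwise concordance (ties count one half).
aucBrute <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cs) * length(ct))
}

# Trapezoidal area under the empirical ROC curve (tie-free scores).
aucTrapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == "case"] >= t),
                numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == "control"] >= t),
                numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Two-sided Mann-Whitney p-value by full enumeration of the C(m+n, m)
# group assignments (distance of U from its null mean mn/2).
enumWilcoxP <- function(x, y) {
  z <- c(x, y)
  m <- length(x)
  uOf <- function(caseIdx) {
    cs <- z[caseIdx]
    ct <- z[-caseIdx]
    tot <- 0
    for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
    tot
  }
  uObs <- uOf(seq_len(m))
  c0 <- m * (length(z) - m) / 2
  all <- utils::combn(length(z), m, uOf)
  mean(abs(all - c0) >= abs(uObs - c0) - 1e-12)
}

# Smallest threshold among candidate values achieving specificity >= target
# under the rule "case iff score > t".
thresholdScan <- function(controls, target) {
  cand <- sort(unique(controls))
  for (t in cand) {
    if (mean(controls <= t) >= target - 1e-12) return(t)
  }
  max(cand)
}

# Hyperparameters that keep the many-fit tests quick without changing
# any algorithm's structure.
fastHyper <- list(RF = list(numTrees = 50L), RIDGE = list(lambda = 0.1),
                  GLM_RF = list(numTrees = 50L))

# Two well-separated Gaussian clouds: every sensible classifier separates
# them perfectly in and out of sample.
makeSeparated <- function(nPerClass = 20L, p = 2L, gap = 10, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(nPerClass * p, mean = gap), ncol = p),
             matrix(rnorm(nPerClass * p, mean = 0), ncol = p))
  colnames(x) <- paste0("m", seq_len(p))
  rownames(x) <- paste0("s", seq_len(2L * nPerClass))
  list(features = x,
       labels = rep(c("case", "control"), each = nPerClass))
}

# A tiny raw-scale cohort built directly from a value matrix.
makeCohort <- function(values, label = NULL, stage = NULL, age = NULL,
                       sex = NULL) {
  n <- ncol(values)
  if (is.null(label)) label <- rep(c("case", "control"), length.out = n)
  if (is.null(stage)) stage <- ifelse(label == "case", 2L, NA_integer_)
  if (is.null(age)) age <- seq(40, 75, length.out = n)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(n))
  }
  MarkerCohort(values, age = age, sex = sex, label = label, stage = stage)
}
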