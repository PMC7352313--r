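#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif qnorm pnorm plogis rbinom binomial
#'   wilcox.test predict sd
#' @importFrom utils read.csv write.csv modifyList head
NULL

# Byte-wise (C locale) sort so enumeration order and panel ids are
# platform-independent.
sortMarkers <- function(x) sort(x, method = "radix")

#' Derive a reproducible sub-seed from a global seed and a task key
#'
#' Every stochastic step of the pipeline (split, fold assignment, each
#' classifier fit) draws its own seed from the global seed plus a string key
#' identifying the task, so results do not depend on the order in which
#' tasks are executed.
#'
#' @param seed Integer global seed.
#' @param ... Character/numeric components of the task key.
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @examples
#' deriveSeed(1, "split")
#' deriveSeed(1, "ApoA1+CEA", "RF", 3)
#' @export
deriveSeed <- function(seed, ...) {
  key <- paste(..., sep = "|")
  h <- as.double(as.integer(seed) %% 2147483647L)
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draws via inverse-CDF so a single runif stream drives
# them (keeps the draw order stable whatever the truncation point).
rnormTrunc <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, min = p0, max = 1), mean, sd)
}

checkLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) {
    stop("labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  labels
}
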