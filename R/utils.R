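#' @useDynLib lvprs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd cor median rnorm rbinom runif qnorm pnorm pchisq
#'   pt lm glm binomial coef vcov resid residuals p.adjust complete.cases
#'   quantile rgamma dbinom setNames prcomp optimize rexp
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream so that re-running a
#' single stage reproduces its output regardless of what ran before it.
#' Streams are derived deterministically from the master seed and a stage
#' label, and kept inside the 32-bit signed integer range.
#'
#' @param seed master integer seed
#' @param stage character stage label
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483647)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# weighted mean/sd used in a few places; NA-safe
safe_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate vector: zero variance", call. = FALSE)
  s
}
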