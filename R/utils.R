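#' @useDynLib dfcbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor mad median p.adjust prcomp pnorm pt quantile rbinom
#'   rnorm runif sd var runmed lm.fit plogis
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_validation("`%s` must be a single integer >= %d (got %s)",
                    name, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

#' Derive a per-unit seed from a master seed
#'
#' All randomness in a cohort flows from one master seed; per-subject and
#' per-iteration seeds are derived deterministically so that any subject can
#' be regenerated in isolation. Derived seeds are kept strictly below
#' `2^31 - 1`.
#'
#' @param seed master seed (single integer).
#' @param index non-negative integer offset (subject or iteration index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 1) %%
    2147483629
  as.integer(s)
}

# Upper-triangle (i < j) edge indexing in R's native column-major order,
# the edge-ordering convention shared by the dispersion, distance and
# report code.
upper_tri_index <- function(n) {
  which(upper.tri(matrix(0, n, n)))
}

upper_tri_pairs <- function(n) {
  which(upper.tri(diag(n)), arr.ind = TRUE)
}

vec_upper <- function(m) {
  m[upper.tri(m)]
}

is_square_sym <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
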