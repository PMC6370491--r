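# Edge dispersion across sliding windows: C = sigma^2 / mu per edge.

#' Edge dispersion of a connectivity stack
#'
#' For every edge, computes the variance of its Fisher-z values across the
#' `T` windows divided by their mean. Edges that show no fluctuation
#' across windows (zero variance) get a dispersion of 0. Under the
#' negative-retain policy an edge mean can vanish while its variance does
#' not; those degenerate-mean edges are also set to 0 and flagged. The
#' variance uses the `T - 1` (sample) denominator by default.
#'
#' @param stack a `dfc_stack` with at least 2 windows.
#' @param variance `"sample"` (denominator `T - 1`, default) or
#'   `"population"` (denominator `T`).
#' @param mean_tol magnitude below which an edge mean counts as degenerate
#'   (default 1e-8).
#' @return object of class `dfc_dispersion`: list with symmetric `C`,
#'   `mean`, `var` (n x n matrices) and a logical `degenerate_mean`
#'   matrix flagging zeroed edges with nonzero variance.
#' @export
edge_dispersion <- function(stack, variance = c("sample", "population"),
                            mean_tol = 1e-8) {
  stopifnot(inherits(stack, "dfc_stack"))
  variance <- match.arg(variance)
  t_win <- dim(stack$z)[1L]
  n <- dim(stack$z)[2L]
  if (t_win < 2L) stop_validation("dispersion needs at least 2 windows")
  flat <- matrix(stack$z, t_win, n * n)
  mu <- colMeans(flat)
  v <- colSums(sweep(flat, 2L, mu, "-")^2)
  v <- v / if (variance == "sample") (t_win - 1) else t_win
  zero_var <- v <= 0
  degen <- !zero_var & abs(mu) < mean_tol
  c_val <- numeric(n * n)
  ok <- !zero_var & !degen
  c_val[ok] <- v[ok] / mu[ok]
  structure(list(
    C = matrix(c_val, n, n),
    mean = matrix(mu, n, n),
    var = matrix(v, n, n),
    degenerate_mean = matrix(degen, n, n)
  ), class = "dfc_dispersion")
}

#' Upper-triangle dispersion vector
#'
#' Vectorizes the dispersion matrix over the package's shared edge
#' ordering (upper triangle, column-major).
#'
#' @param disp a `dfc_dispersion`.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @export
dispersion_edges <- function(disp) {
  stopifnot(inherits(disp, "dfc_dispersion"))
  vec_upper(disp$C)
}
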