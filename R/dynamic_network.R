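# Sliding-window Fisher-z connectivity stacks.

#' Sliding-window scheme
#'
#' Divides a series of `n_frames` frames into windows of `window_length`
#' frames with the given fractional overlap. Start indices are 0-based and
#' windows are half-open intervals `[start, start + window_length)`;
#' trailing frames that do not fill a window are dropped, so every window
#' has the same length. The window count follows
#' `floor((n_frames - window_length) / step) + 1` with
#' `step = round(window_length * (1 - overlap))`.
#'
#' @param n_frames number of frames in the series.
#' @param window_length window length in frames (default 20 TRs = 60 s at
#'   a 3 s TR).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return object of class `dfc_windows`: list with `window_length`,
#'   `step` and 0-based `starts`.
#' @export
make_windows <- function(n_frames, window_length = 20L, overlap = 0.5) {
  n_frames <- assert_count(n_frames, "n_frames")
  window_length <- assert_count(window_length, "window_length", min = 2L)
  if (n_frames < window_length) {
    stop_validation("window length %d exceeds series length %d",
                    window_length, n_frames)
  }
  if (overlap < 0 || overlap >= 1) stop_validation("need 0 <= overlap < 1")
  step <- as.integer(round(window_length * (1 - overlap)))
  if (step < 1L) stop_validation("overlap too large: step would be < 1")
  n_win <- (n_frames - window_length) %/% step + 1L
  structure(list(
    window_length = window_length,
    step = step,
    starts = step * (0:(n_win - 1L))
  ), class = "dfc_windows")
}

#' Windowed Fisher-z connectivity stack
#'
#' For every window, computes the Pearson correlation between all node
#' pairs, optionally zeroes negative correlations, clips perfect
#' correlations to `1 - 1e-6` in magnitude, applies the Fisher
#' z-transform (`atanh`), and zeroes the diagonal. Nodes with zero
#' variance inside a window get zero edges with a warning.
#'
#' @param signals nodes x frames matrix of (residual) time series.
#' @param scheme a `dfc_windows` scheme; default derives one from the
#'   frame count with 20-frame windows and 50% overlap.
#' @param negative_policy `"zero"` (negative correlations set to 0 before
#'   the transform) or `"retain"`.
#' @return object of class `dfc_stack`: list with `z` (array
#'   T x n x n), `negative_policy` and `scheme`.
#' @export
window_connectivity <- function(signals, scheme = NULL,
                                negative_policy = c("zero", "retain")) {
  stopifnot(is.matrix(signals), all(is.finite(signals)))
  negative_policy <- match.arg(negative_policy)
  if (is.null(scheme)) scheme <- make_windows(ncol(signals))
  stopifnot(inherits(scheme, "dfc_windows"))
  n <- nrow(signals)
  t_win <- length(scheme$starts)
  z <- array(0, dim = c(t_win, n, n))
  clip <- 1 - 1e-6
  warned <- FALSE
  for (w in seq_len(t_win)) {
    idx <- scheme$starts[w] + seq_len(scheme$window_length)
    x <- t(signals[, idx, drop = FALSE])
    sds <- apply(x, 2L, sd)
    degenerate <- sds < 1e-14
    if (any(degenerate) && !warned) {
      warning("zero-variance node(s) in a window; their edges are set to 0")
      warned <- TRUE
    }
    r <- suppressWarnings(cor(x))
    r[!is.finite(r)] <- 0
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
    if (negative_policy == "zero") r[r < 0] <- 0
    r <- pmin(pmax(r, -clip), clip)
    diag(r) <- 0
    z[w, , ] <- atanh(r)
  }
  structure(list(
    z = z,
    negative_policy = negative_policy,
    scheme = scheme
  ), class = "dfc_stack")
}
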