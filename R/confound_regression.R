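# Node-level analogues of regression-based de-noising pipelines:
# regressor assembly and expansion, band-pass filtering of data and
# regressors, despiking, CompCor-style components, and residualization.

#' Backward-difference temporal derivative
#'
#' First temporal derivative as used for realignment-parameter expansion:
#' backward difference with the first element set to 0.
#'
#' @param series numeric vector (or frames x k matrix, differenced
#'   column-wise).
#' @return object of the same shape.
#' @export
temporal_derivative <- function(series) {
  if (is.matrix(series)) {
    return(apply(series, 2L, temporal_derivative))
  }
  if (length(series) < 2L) stop_validation("need at least 2 frames")
  c(0, diff(series))
}

#' Friston 24-parameter expansion of realignment parameters
#'
#' Expands the six realignment parameters into 24 regressors in the column
#' order `[rp6, d(rp6), rp6^2, d(rp6)^2]`: the six parameters, their
#' backward-difference temporal derivatives, their squares, and the squares
#' of the derivatives.
#'
#' @param rp6 frames x 6 matrix of realignment parameters.
#' @return frames x 24 matrix.
#' @export
expand_friston <- function(rp6) {
  if (!is.matrix(rp6) || ncol(rp6) != 6L) {
    stop_validation("`rp6` must be a frames x 6 matrix")
  }
  d <- temporal_derivative(rp6)
  out <- cbind(rp6, d, rp6^2, d^2)
  colnames(out) <- c(paste0("rp", 1:6), paste0("rp_d", 1:6),
                     paste0("rp_sq", 1:6), paste0("rp_dsq", 1:6))
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass filter (default first order, passband
#' 0.01-0.08 Hz) and applies it forward-backward for zero phase, which
#' doubles the effective order. Columns are demeaned before filtering, so
#' the DC component is removed exactly. The same filter is applied to
#' nuisance regressors before regression so that data and confounds share
#' a frequency content.
#'
#' @param series numeric vector or frames x k matrix.
#' @param tr sampling interval (repetition time), seconds.
#' @param f_lo,f_hi passband edges in Hz; `f_hi` must be below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @param order filter order of the one-way design (default 1).
#' @return filtered object of the same shape.
#' @export
bandpass <- function(series, tr, f_lo = 0.01, f_hi = 0.08, order = 1L) {
  nyq <- 1 / (2 * tr)
  if (!(f_lo > 0 && f_lo < f_hi)) {
    stop_validation("need 0 < f_lo < f_hi")
  }
  if (f_hi >= nyq) {
    stop_validation("f_hi = %.4f Hz is not below Nyquist = %.4f Hz",
                    f_hi, nyq)
  }
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  filt1 <- function(x) {
    signal::filtfilt(bf, x - mean(x))
  }
  if (is.matrix(series)) {
    out <- apply(series, 2L, filt1)
    out <- matrix(out, nrow(series), ncol(series),
                  dimnames = dimnames(series))
    out
  } else {
    filt1(series)
  }
}

#' Attenuate intensity spikes in node time series
#'
#' Per-node despiking by robust shrinkage: residuals from a running-median
#' fit whose magnitude exceeds `c_mad` scaled-MAD units are compressed by a
#' saturating (tanh) map that approaches `c_cap` MAD units, so the output
#' residual magnitude never exceeds `c_cap * MAD`. Non-outlying samples are
#' returned unchanged.
#'
#' @param signals nodes x frames matrix (or a single series).
#' @param c_mad outlier threshold in MAD units (default 2.5).
#' @param c_cap asymptotic cap in MAD units (default 4.0).
#' @param k running-median window width (odd, default 7).
#' @return despiked object of the same shape.
#' @export
despike <- function(signals, c_mad = 2.5, c_cap = 4.0, k = 7L) {
  if (c_cap <= c_mad) stop_validation("need c_cap > c_mad")
  one <- function(x) {
    if (length(x) < 5L) stop_validation("need at least 5 frames")
    med <- runmed(x, k = min(k, length(x) - (length(x) + 1L) %% 2L),
                  endrule = "median")
    res <- x - med
    m <- mad(res)
    if (m <= 0) return(x)
    a <- abs(res) / m
    out <- a > c_mad
    if (!any(out)) return(x)
    shrunk <- c_mad + (c_cap - c_mad) * tanh((a[out] - c_mad) / (c_cap - c_mad))
    res[out] <- sign(res[out]) * shrunk * m
    med + res
  }
  if (is.matrix(signals)) {
    out <- t(apply(signals, 1L, one))
    dimnames(out) <- dimnames(signals)
    out
  } else {
    one(signals)
  }
}

#' CompCor-style principal component regressors
#'
#' Standardizes the noise-pool channels and returns the leading principal
#' component time series, ordered by explained variance and normalized to
#' an orthonormal set.
#'
#' @param noise_pool frames x q matrix of noise channels.
#' @param n_components number of components to return.
#' @return frames x `n_components` matrix with orthonormal columns.
#' @export
compcor <- function(noise_pool, n_components) {
  stopifnot(is.matrix(noise_pool))
  n_components <- assert_count(n_components, "n_components")
  if (ncol(noise_pool) < n_components) {
    stop_validation("noise pool has %d channels < %d components",
                    ncol(noise_pool), n_components)
  }
  s <- apply(noise_pool, 2L, sd)
  s[s < 1e-12] <- 1
  z <- sweep(sweep(noise_pool, 2L, colMeans(noise_pool), "-"), 2L, s, "/")
  r <- qr(z)$rank
  if (n_components > r) {
    stop_validation("requested %d components but pool rank is %d",
                    n_components, r)
  }
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  comp <- pc$x[, seq_len(n_components), drop = FALSE]
  nrm <- sqrt(colSums(comp^2))
  comp <- sweep(comp, 2L, nrm, "/")
  colnames(comp) <- paste0("pc", seq_len(n_components))
  comp
}

#' Select high-temporal-variance channels (temporal CompCor pool)
#'
#' Keeps the top `ceiling(fraction * q)` channels ranked by temporal
#' standard deviation.
#'
#' @param channels frames x q matrix, q >= 10.
#' @param fraction fraction of channels to keep (default 0.02).
#' @return frames x q' matrix of the selected channels.
#' @export
select_high_variance_pool <- function(channels, fraction = 0.02) {
  stopifnot(is.matrix(channels))
  if (ncol(channels) < 10L) stop_validation("need at least 10 channels")
  keep <- ceiling(fraction * ncol(channels))
  keep <- max(1L, min(ncol(channels), keep))
  s <- apply(channels, 2L, sd)
  idx <- order(s, decreasing = TRUE)[seq_len(keep)]
  channels[, sort(idx), drop = FALSE]
}

#' Local white-matter regressor for one node
#'
#' Unweighted mean of white-matter channels whose coordinates lie within
#' `radius` mm of the node; when no channel is that close, falls back to
#' the nearest channel with a warning.
#'
#' @param node_coord length-3 coordinate in mm.
#' @param wm_channels frames x w matrix of WM channel time series.
#' @param wm_coords w x 3 matrix of the channel coordinates.
#' @param radius inclusion radius in mm (default 15).
#' @return frames-length numeric vector.
#' @export
local_wm_regressor <- function(node_coord, wm_channels, wm_coords,
                               radius = 15) {
  stopifnot(is.matrix(wm_channels), nrow(wm_coords) == ncol(wm_channels))
  d <- sqrt(colSums((t(wm_coords) - node_coord)^2))
  within <- which(d <= radius)
  if (length(within) == 0L) {
    warning(sprintf(
      "no WM channel within %.0f mm of node; using nearest at %.1f mm",
      radius, min(d)))
    within <- which.min(d)
  }
  rowMeans(wm_channels[, within, drop = FALSE])
}

# ---- pipeline registry ------------------------------------------------

.pipeline_registry <- c("NONE", "2P", "6P", "9P", "24P", "36P",
                        "36P_DESPIKE", "ACOMPCOR", "TCOMPCOR",
                        "WMMEAN", "WMLOCAL")

#' De-noising pipeline specification
#'
#' Resolves a pipeline name from the registry of regression-based
#' strategies. `NONE` is the no-regression baseline (intercept only).
#' `9P`, `36P` and `36P_DESPIKE` include the global signal by definition
#' and reject `gsr = FALSE`; for other pipelines `gsr = TRUE` appends a
#' global-signal column.
#'
#' @param name one of `NONE`, `2P`, `6P`, `9P`, `24P`, `36P`,
#'   `36P_DESPIKE`, `ACOMPCOR`, `TCOMPCOR`, `WMMEAN`, `WMLOCAL`.
#' @param gsr logical; add global signal regression. Default `NA` resolves
#'   to the pipeline's definition.
#' @return an object of class `dfc_pipeline_spec`.
#' @export
pipeline_spec <- function(name, gsr = NA) {
  if (!name %in% .pipeline_registry) {
    stop_validation("unknown pipeline '%s'; registry: %s", name,
                    paste(.pipeline_registry, collapse = ", "))
  }
  has_gsr <- name %in% c("9P", "36P", "36P_DESPIKE")
  if (has_gsr && isFALSE(gsr)) {
    stop_validation("pipeline %s includes GSR by definition", name)
  }
  structure(list(
    name = name,
    gsr = if (is.na(gsr)) has_gsr else isTRUE(gsr),
    despike = name %in% c("36P_DESPIKE", "WMMEAN", "WMLOCAL")
  ), class = "dfc_pipeline_spec")
}

#' Registered pipeline names
#' @return character vector of registry names.
#' @export
pipeline_names <- function() .pipeline_registry

#' Assemble the nuisance design for a subject and pipeline
#'
#' Builds the regressor matrix the pipeline prescribes from the subject's
#' realignment parameters and nuisance channels, then band-pass filters
#' every column with the same filter applied to the data. For the local-WM
#' pipeline the node-specific WM column is returned separately as a
#' frames x nodes matrix.
#'
#' @param subject a `dfc_subject`.
#' @param spec a `dfc_pipeline_spec`.
#' @param tr repetition time in seconds.
#' @param atlas the cohort `dfc_atlas` (needed for the local-WM pipeline).
#' @return object of class `dfc_regressors`: list with `matrix`
#'   (frames x p, possibly p = 0), `labels`, `provenance`, `local_wm`
#'   (frames x nodes or `NULL`) and `spec`.
#' @export
assemble_regressors <- function(subject, spec, tr = 3, atlas = NULL) {
  stopifnot(inherits(subject, "dfc_subject"),
            inherits(spec, "dfc_pipeline_spec"))
  rp6 <- subject$motion$realign_params
  nuis <- subject$nuisance
  wm_mean <- rowMeans(nuis$wm$channels)
  csf_mean <- rowMeans(nuis$csf_like)
  glob <- nuis$global
  n_frames <- length(glob)

  cols <- list(); prov <- character(0)
  add <- function(x, labels, from) {
    x <- as.matrix(x)
    colnames(x) <- labels
    cols[[length(cols) + 1L]] <<- x
    prov <<- c(prov, rep(from, ncol(x)))
  }

  name <- spec$name
  if (name == "2P") {
    add(cbind(wm_mean, csf_mean), c("wm_mean", "csf_mean"), "tissue")
  } else if (name == "6P") {
    add(rp6, colnames(rp6), "realignment")
  } else if (name == "9P") {
    add(rp6, colnames(rp6), "realignment")
    add(cbind(wm_mean, csf_mean), c("wm_mean", "csf_mean"), "tissue")
    add(glob, "global", "gsr")
  } else if (name == "24P") {
    f24 <- expand_friston(rp6)
    add(f24, colnames(f24), "friston24")
  } else if (name %in% c("36P", "36P_DESPIKE")) {
    f24 <- expand_friston(rp6)
    add(f24, colnames(f24), "friston24")
    for (nm in c("wm_mean", "csf_mean", "global")) {
      x <- switch(nm, wm_mean = wm_mean, csf_mean = csf_mean,
                  global = glob)
      d <- temporal_derivative(x)
      add(cbind(x, d, x^2, d^2),
          paste0(nm, c("", "_d", "_sq", "_dsq")),
          if (nm == "global") "gsr" else "tissue")
    }
  } else if (name == "ACOMPCOR") {
    add(rp6, colnames(rp6), "realignment")
    add(temporal_derivative(rp6), paste0("rp_d", 1:6), "realignment")
    wm_pc <- compcor(nuis$wm$channels, 5L)
    csf_pc <- compcor(nuis$csf_like, 5L)
    add(wm_pc, paste0("wm_", colnames(wm_pc)), "acompcor")
    add(csf_pc, paste0("csf_", colnames(csf_pc)), "acompcor")
  } else if (name == "TCOMPCOR") {
    pool <- select_high_variance_pool(nuis$high_variance_pool)
    add(compcor(pool, 6L), paste0("hv_pc", 1:6), "tcompcor")
  } else if (name %in% c("WMMEAN", "WMLOCAL")) {
    add(rp6, colnames(rp6), "realignment")
    add(temporal_derivative(rp6), paste0("rp_d", 1:6), "realignment")
    if (name == "WMMEAN") add(wm_mean, "wm_mean", "tissue")
  }
  if (spec$gsr && !name %in% c("9P", "36P", "36P_DESPIKE")) {
    add(glob, "global", "gsr")
  }

  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, n_frames, 0L)
  if (ncol(mat) > 0L) {
    mat <- bandpass(mat, tr = tr)
    r <- qr(mat)$rank
    if (r < ncol(mat)) {
      warning(sprintf(
        "design for %s is rank-deficient after assembly (rank %d of %d)",
        name, r, ncol(mat)))
    }
  }

  local_wm <- NULL
  if (name == "WMLOCAL") {
    if (is.null(atlas)) stop_validation("WMLOCAL needs the cohort atlas")
    local_wm <- vapply(seq_len(atlas$n_nodes), function(i) {
      suppressWarnings(local_wm_regressor(
        atlas$coord_mm[i, ], nuis$wm$channels, nuis$wm$coords))
    }, numeric(n_frames))
    local_wm <- bandpass(local_wm, tr = tr)
  }

  structure(list(
    matrix = mat,
    labels = colnames(mat),
    provenance = prov,
    local_wm = local_wm,
    spec = spec
  ), class = "dfc_regressors")
}

#' Apply a de-noising pipeline to one subject
#'
#' Runs the pipeline in the order despike (when the pipeline prescribes
#' it), band-pass data and regressors, then per-node ordinary
#' least-squares residualization on the regressors plus an intercept.
#' Collinear design columns are dropped with a warning rather than
#' failing. Residuals are exactly orthogonal to every retained regressor
#' column.
#'
#' @param subject a `dfc_subject`.
#' @param spec a `dfc_pipeline_spec` (or pipeline name).
#' @param tr repetition time in seconds.
#' @param atlas cohort atlas, required for the local-WM pipeline.
#' @param extra_regressors optional frames x k matrix appended to the
#'   design after band-pass filtering (e.g. a known artifact series).
#' @return nodes x frames matrix of residual time series.
#' @export
apply_pipeline <- function(subject, spec, tr = 3, atlas = NULL,
                           extra_regressors = NULL) {
  if (is.character(spec)) spec <- pipeline_spec(spec)
  stopifnot(inherits(subject, "dfc_subject"),
            inherits(spec, "dfc_pipeline_spec"))
  signals <- subject$contaminated_signals
  if (spec$despike) signals <- despike(signals)
  y <- bandpass(t(signals), tr = tr)          # frames x nodes

  regs <- assemble_regressors(subject, spec, tr = tr, atlas = atlas)
  x <- regs$matrix
  if (!is.null(extra_regressors)) {
    x <- cbind(x, bandpass(as.matrix(extra_regressors), tr = tr))
  }
  design <- cbind(intercept = rep(1, nrow(y)), x)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(colnames(design), colnames(design)[keep])
    warning(sprintf("dropping collinear regressor column(s): %s",
                    paste(dropped, collapse = ", ")))
    design <- design[, keep, drop = FALSE]
    qx <- qr(design)
  }
  res <- qr.resid(qx, y)                      # frames x nodes

  if (!is.null(regs$local_wm)) {
    # residual of y_i on [design, local_i] via residualized local column
    lw <- qr.resid(qx, regs$local_wm)
    denom <- colSums(lw^2)
    denom[denom < 1e-12] <- Inf               # degenerate local column
    beta <- colSums(lw * res) / denom
    res <- res - sweep(lw, 2L, beta, "*")
  }
  t(res)
}
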