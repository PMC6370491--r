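# Benchmark statistics: metric-motion partial correlations with BH-FDR,
# distance-dependence with Steiger equality tests, Q identifiability and
# Q-motion association, and reconfiguration-motion associations.

residualize <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  x <- cbind(rep(1, nrow(y)), covariates)
  qr.resid(qr(x), y)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on an intercept
#' plus the covariate columns, with a two-sided p-value from
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - q - 2`. With no covariates
#' this is the plain Pearson correlation. Zero-variance residuals give
#' `r = 0`, `p = 1` and `flag = TRUE`.
#'
#' @param x,y numeric vectors of equal length `n`.
#' @param covariates optional n x q matrix/data.frame of covariates.
#' @return list with `r`, `p`, `df`, `flag`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= q + 3L) stop_validation("need n > q + 3 observations")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  sx <- sd(rx); sy <- sd(ry)
  df <- n - q - 2L
  if (sx < 1e-14 || sy < 1e-14) {
    return(list(r = 0, p = 1, df = df, flag = TRUE))
  }
  r <- as.numeric(cor(rx, ry))
  r <- max(-1, min(1, r))
  tt <- r * sqrt(df / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df, flag = FALSE)
}

#' Benjamini-Hochberg false discovery rate mask
#'
#' Step-up procedure at level `alpha`: rejects the `k*` smallest p-values
#' where `k* = max(k : p_(k) <= k * alpha / m)`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with logical `mask` and `n_rejected`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  mask <- p.adjust(p, method = "BH") <= alpha
  list(mask = mask, n_rejected = sum(mask))
}

# Vectorized partial correlations of many metric columns against one
# variable, sharing a single residualizing projection.
partial_correlation_many <- function(metric, x, covariates = NULL) {
  metric <- as.matrix(metric)
  n <- nrow(metric)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= q + 3L) stop_validation("need n > q + 3 subjects")
  rm_ <- residualize(metric, covariates)
  rx <- as.numeric(residualize(x, covariates))
  sx <- sqrt(sum(rx^2))
  s_m <- sqrt(colSums(rm_^2))
  flag <- s_m < 1e-12 | sx < 1e-12
  denom <- s_m * sx
  denom[flag] <- Inf
  r <- as.numeric(crossprod(rm_, rx)) / denom
  r <- pmin(pmax(r, -1), 1)
  df <- n - q - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tt), df)
  p[flag] <- 1
  list(r = unname(r), p = unname(p), df = df, flag = unname(flag))
}

#' Unitwise metric-motion association with FDR summaries
#'
#' For every unit (edge or node), the partial correlation between the
#' unit's metric values and subject motion, controlling for age and sex.
#' Constant metric units are kept with `r = 0`, `p = 1` and a flag so that
#' the percentage summaries stay comparable across pipelines.
#'
#' @param metric subjects x units matrix.
#' @param covariates data.frame with columns `mean_rel_rms`, `age`, `sex`
#'   (see [cohort_covariates()]).
#' @param alpha significance level (default 0.05).
#' @return object of class `dfc_edge_assoc`: list with `r`, `p`,
#'   `fdr_mask`, `uncorrected_mask`, `pct_significant_fdr`,
#'   `pct_significant_uncorrected`, `median_abs_r`, `sd_r`, `mean_r`,
#'   `flags`.
#' @export
unitwise_motion_association <- function(metric, covariates, alpha = 0.05) {
  metric <- as.matrix(metric)
  stopifnot(nrow(metric) == nrow(covariates))
  if (nrow(covariates) < 10L) stop_validation("need >= 10 subjects")
  covs <- cbind(age = covariates$age, sex = covariates$sex)
  pc <- partial_correlation_many(metric, covariates$mean_rel_rms, covs)
  fdr <- bh_fdr(pc$p, alpha)
  m <- ncol(metric)
  structure(list(
    r = pc$r, p = pc$p,
    fdr_mask = fdr$mask,
    uncorrected_mask = pc$p <= alpha,
    pct_significant_fdr = 100 * fdr$n_rejected / m,
    pct_significant_uncorrected = 100 * sum(pc$p <= alpha) / m,
    median_abs_r = median(abs(pc$r)),
    sd_r = sd(pc$r),
    mean_r = mean(pc$r),
    flags = pc$flag,
    alpha = alpha
  ), class = "dfc_edge_assoc")
}

#' Scalar metric-motion association
#'
#' Partial correlation between one per-subject scalar (e.g. mean Q, global
#' flexibility) and motion, controlling for age and sex.
#'
#' @param values per-subject numeric vector.
#' @param covariates covariate data.frame (see [cohort_covariates()]).
#' @return list with `r`, `p`, `df`, `flag`.
#' @export
scalar_motion_association <- function(values, covariates) {
  if (nrow(covariates) < 10L) stop_validation("need >= 10 subjects")
  partial_correlation(values, covariates$mean_rel_rms,
                      cbind(age = covariates$age, sex = covariates$sex))
}

#' Euclidean inter-node distance matrix
#'
#' @param atlas a `dfc_atlas` (or an n x 3 coordinate matrix, mm).
#' @return symmetric n x n matrix of distances in mm, zero diagonal.
#' @export
distance_matrix <- function(atlas) {
  coords <- if (inherits(atlas, "dfc_atlas")) atlas$coord_mm else atlas
  stopifnot(all(is.finite(coords)))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d
}

#' Distance-dependence of the motion association
#'
#' Pearson correlation over edges between the inter-node Euclidean
#' distance and the edgewise metric-motion correlation, with a p-value
#' from the t transform. Degenerate (constant) inputs return `r_dd = 0`
#' with a flag.
#'
#' @param edge_r per-edge motion-correlation vector (upper-triangle
#'   ordering) or a `dfc_edge_assoc`.
#' @param d distance matrix from [distance_matrix()] (or an
#'   upper-triangle vector aligned with `edge_r`).
#' @return list with `r_dd`, `p_dd`, `n_edges`, `flag`.
#' @export
distance_dependence <- function(edge_r, d) {
  if (inherits(edge_r, "dfc_edge_assoc")) edge_r <- edge_r$r
  dv <- if (is.matrix(d)) vec_upper(d) else d
  stopifnot(length(dv) == length(edge_r))
  n_edges <- length(edge_r)
  if (sd(edge_r) < 1e-14 || sd(dv) < 1e-14) {
    return(list(r_dd = 0, p_dd = 1, n_edges = n_edges, flag = TRUE))
  }
  r <- as.numeric(cor(dv, edge_r))
  df <- n_edges - 2L
  tt <- r * sqrt(df / max(1 - r^2, 1e-300))
  list(r_dd = r, p_dd = 2 * pt(-abs(tt), df), n_edges = n_edges,
       flag = FALSE)
}

#' Steiger test for two dependent correlations sharing one variable
#'
#' Tests the equality of `cor(d, a)` and `cor(d, b)` when both share the
#' variable `d` (here: inter-node distance shared between two pipelines'
#' edgewise motion-correlation vectors). Fisher-z transforms the two
#' correlations and uses the common-element covariance correction
#' evaluated at the back-transform of the mean z.
#'
#' @param r_j1 correlation of the shared variable with vector 1.
#' @param r_j2 correlation of the shared variable with vector 2.
#' @param r_12 correlation between vectors 1 and 2.
#' @param n_edges sample size the correlations were computed over.
#' @return list with `z` (test statistic) and `p` (two-sided).
#' @export
steiger_equality <- function(r_j1, r_j2, r_12, n_edges) {
  if (n_edges <= 10L) stop_validation("need n_edges > 10")
  if (abs(r_j1) >= 1 || abs(r_j2) >= 1 || abs(r_12) > 1) {
    stop_validation("correlations must lie strictly inside (-1, 1)")
  }
  if (r_j1 == r_j2) {
    # equal correlations, including the degenerate r_12 = 1 case
    return(list(z = 0, p = 1))
  }
  z1 <- atanh(r_j1)
  z2 <- atanh(r_j2)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_12^2)
  s <- psi / (1 - rbar^2)^2
  z <- sqrt(n_edges - 3) * (z1 - z2) / sqrt(2 - 2 * s)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Paired t test on two aligned value vectors
#'
#' Standard paired t on the differences; zero-variance differences are
#' returned flagged (with an infinite statistic when the mean difference
#' is nonzero) instead of failing.
#'
#' @param v1,v2 numeric vectors of equal length >= 3.
#' @return list with `t`, `df`, `p`, `flag`.
#' @export
paired_t <- function(v1, v2) {
  stopifnot(length(v1) == length(v2), length(v1) >= 3L)
  d <- v1 - v2
  n <- length(d)
  s <- sd(d)
  if (s < 1e-14) {
    m <- mean(d)
    t_stat <- if (abs(m) < 1e-14) 0 else sign(m) * Inf
    return(list(t = t_stat, df = n - 1L,
                p = if (t_stat == 0) 1 else 0, flag = TRUE))
  }
  tt <- stats::t.test(v1, v2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flag = FALSE)
}

#' Per-subnetwork proportion of significant nodes
#'
#' @param mask logical per-node significance flags.
#' @param atlas a `dfc_atlas` (uses `subnetwork_label`).
#' @return named numeric vector: proportion of significant nodes within
#'   each subnetwork.
#' @export
subnetwork_breakdown <- function(mask, atlas) {
  stopifnot(inherits(atlas, "dfc_atlas"),
            length(mask) == atlas$n_nodes)
  tapply(mask, atlas$subnetwork_label, mean)
}
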