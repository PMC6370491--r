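# Per-pipeline benchmark report assembly.

#' Compute per-subject dynamic metrics for one pipeline
#'
#' Applies the de-noising pipeline to every subject, builds the windowed
#' Fisher-z stack, and computes edge dispersion and (optionally) the
#' multilayer modularity statistics and reconfiguration profiles.
#'
#' @param cohort a `dfc_cohort`.
#' @param pipeline pipeline name or `dfc_pipeline_spec`.
#' @param window_length,overlap sliding-window parameters.
#' @param negative_policy negative-edge policy for the stack.
#' @param do_modularity run multilayer modularity (default `TRUE`).
#' @param gamma,omega,n_iterations modularity parameters (defaults 1, 1,
#'   100).
#' @param seed seed for the modularity restarts (per-subject seeds are
#'   derived from it).
#' @return object of class `dfc_pipeline_metrics`: list with `pipeline`,
#'   `dispersion` (subjects x edges), `mean_Q`, `sd_Q_within`,
#'   `flexibility`, `promiscuity` (subjects x nodes), `global_F`,
#'   `global_Psi`.
#' @export
pipeline_metrics <- function(cohort, pipeline, window_length = 20L,
                             overlap = 0.5, negative_policy = "zero",
                             do_modularity = TRUE, gamma = 1, omega = 1,
                             n_iterations = 100L, seed = 1L) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  if (is.character(pipeline)) pipeline <- pipeline_spec(pipeline)
  n_sub <- length(cohort$subjects)
  n <- cohort$atlas$n_nodes
  scheme <- make_windows(cohort$n_frames, window_length, overlap)
  n_edges <- n * (n - 1L) / 2L

  disp <- matrix(NA_real_, n_sub, n_edges)
  q_mean <- q_sd <- rep(NA_real_, n_sub)
  flex <- prom <- matrix(NA_real_, n_sub, n)
  g_f <- g_psi <- rep(NA_real_, n_sub)

  for (i in seq_len(n_sub)) {
    resid <- suppressWarnings(apply_pipeline(
      cohort$subjects[[i]], pipeline, tr = cohort$tr,
      atlas = cohort$atlas))
    stack <- suppressWarnings(
      window_connectivity(resid, scheme, negative_policy))
    disp[i, ] <- dispersion_edges(edge_dispersion(stack))
    if (do_modularity) {
      net <- multilayer_network(stack, omega = omega)
      mm <- maximize_modularity(net, gamma = gamma,
                                n_iterations = n_iterations,
                                seed = derive_seed(seed, i))
      q_mean[i] <- mm$mean_Q
      q_sd[i] <- sd(mm$Q_values)
      prof <- average_profiles(mm)
      flex[i, ] <- prof$flexibility
      prom[i, ] <- prof$promiscuity
      g_f[i] <- prof$global_F
      g_psi[i] <- prof$global_Psi
    }
  }
  structure(list(
    pipeline = pipeline$name,
    dispersion = disp,
    mean_Q = q_mean, sd_Q_within = q_sd,
    flexibility = flex, promiscuity = prom,
    global_F = g_f, global_Psi = g_psi,
    do_modularity = do_modularity
  ), class = "dfc_pipeline_metrics")
}

assoc_summary <- function(assoc) {
  list(r = assoc$r,
       pct_significant_fdr = assoc$pct_significant_fdr,
       pct_significant_uncorrected = assoc$pct_significant_uncorrected,
       median_abs_r = assoc$median_abs_r,
       sd_r = assoc$sd_r, mean_r = assoc$mean_r,
       fdr_mask = assoc$fdr_mask,
       uncorrected_mask = assoc$uncorrected_mask)
}

#' Build the per-pipeline benchmark report
#'
#' Runs every requested pipeline on the same cohort and assembles the four
#' benchmark families: (a) edgewise dispersion-motion partial correlations
#' with BH-FDR summaries, (b) distance-dependence of the dispersion-motion
#' correlations, (c) multilayer modularity quality and its motion
#' association, (d) nodewise and global flexibility/promiscuity motion
#' associations with per-subnetwork breakdowns. Pairwise pipeline
#' comparisons use paired t tests on the edgewise correlation vectors and
#' Steiger equality tests on the distance-dependence correlations; the
#' cross-benchmark association between pipeline mean Q and pipeline
#' Q-motion correlation is included when at least four pipelines carry
#' modularity results.
#'
#' @param cohort a `dfc_cohort`.
#' @param pipelines character vector of registry pipeline names.
#' @param alpha significance level for the association masks.
#' @param metrics optional precomputed list of `dfc_pipeline_metrics`
#'   (named by pipeline), bypassing recomputation.
#' @inheritParams pipeline_metrics
#' @return object of class `dfc_benchmark_report`.
#' @export
build_report <- function(cohort, pipelines = c("2P", "6P", "9P", "24P",
                                               "36P", "36P_DESPIKE",
                                               "ACOMPCOR", "TCOMPCOR",
                                               "WMMEAN", "WMLOCAL"),
                         window_length = 20L, overlap = 0.5,
                         negative_policy = "zero", do_modularity = TRUE,
                         gamma = 1, omega = 1, n_iterations = 100L,
                         alpha = 0.05, seed = 1L, metrics = NULL) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  covs <- cohort_covariates(cohort)
  d_upper <- vec_upper(distance_matrix(cohort$atlas))

  per_pipeline <- list()
  for (pn in pipelines) {
    m <- if (!is.null(metrics) && pn %in% names(metrics)) metrics[[pn]]
    else pipeline_metrics(cohort, pn, window_length, overlap,
                          negative_policy, do_modularity, gamma, omega,
                          n_iterations, seed = derive_seed(seed, match(pn, pipelines)))
    disp_assoc <- unitwise_motion_association(m$dispersion, covs, alpha)
    dd <- distance_dependence(disp_assoc, d_upper)
    entry <- list(
      pipeline = pn,
      dispersion = assoc_summary(disp_assoc),
      distance_dependence = dd
    )
    if (isTRUE(m$do_modularity)) {
      q_assoc <- scalar_motion_association(m$mean_Q, covs)
      fx <- unitwise_motion_association(m$flexibility, covs, alpha)
      pr <- unitwise_motion_association(m$promiscuity, covs, alpha)
      entry$modularity <- list(
        mean_Q = mean(m$mean_Q), sd_Q = sd(m$mean_Q),
        q_motion_r = q_assoc$r, q_motion_p = q_assoc$p)
      entry$flexibility <- c(
        assoc_summary(fx),
        list(global_assoc = scalar_motion_association(m$global_F, covs),
             subnetwork_prop =
               subnetwork_breakdown(fx$uncorrected_mask, cohort$atlas)))
      entry$promiscuity <- c(
        assoc_summary(pr),
        list(global_assoc = scalar_motion_association(m$global_Psi, covs),
             subnetwork_prop =
               subnetwork_breakdown(pr$uncorrected_mask, cohort$atlas)))
    }
    per_pipeline[[pn]] <- entry
  }

  # pairwise comparisons over the shared edge set
  pairs <- if (length(pipelines) >= 2L) utils::combn(pipelines, 2L) else NULL
  comparisons <- list()
  if (!is.null(pairs)) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      ra <- per_pipeline[[a]]$dispersion$r
      rb <- per_pipeline[[b]]$dispersion$r
      pt_res <- paired_t(ra, rb)
      r12 <- as.numeric(cor(ra, rb))
      st <- steiger_equality(per_pipeline[[a]]$distance_dependence$r_dd,
                             per_pipeline[[b]]$distance_dependence$r_dd,
                             r12, length(ra))
      comparisons[[paste(a, b, sep = "_vs_")]] <- list(
        pipelines = c(a, b), paired_t = pt_res, steiger = st,
        r12 = r12)
    }
  }

  # rankings (ascending = more effective for motion benchmarks)
  median_abs <- vapply(per_pipeline, function(e) e$dispersion$median_abs_r, 0)
  abs_dd <- vapply(per_pipeline,
                   function(e) abs(e$distance_dependence$r_dd), 0)
  rankings <- list(
    median_abs_dispersion_motion_r = names(sort(median_abs)),
    abs_distance_dependence = names(sort(abs_dd))
  )

  cross <- NULL
  with_q <- Filter(function(e) !is.null(e$modularity), per_pipeline)
  if (length(with_q) >= 4L) {
    mq <- vapply(with_q, function(e) e$modularity$mean_Q, 0)
    qr_ <- vapply(with_q, function(e) e$modularity$q_motion_r, 0)
    rankings$mean_Q <- names(sort(mq, decreasing = TRUE))
    cross <- list(r = as.numeric(cor(mq, qr_)), n_pipelines = length(mq))
  }

  structure(list(
    pipelines = per_pipeline,
    comparisons = comparisons,
    rankings = rankings,
    cross_benchmark_q = cross,
    params = list(window_length = window_length, overlap = overlap,
                  negative_policy = negative_policy, gamma = gamma,
                  omega = omega, n_iterations = n_iterations,
                  alpha = alpha, seed = seed,
                  n_subjects = length(cohort$subjects),
                  n_nodes = cohort$atlas$n_nodes)
  ), class = "dfc_benchmark_report")
}

#' One-row-per-pipeline summary table of a report
#'
#' @param report a `dfc_benchmark_report`.
#' @return data.frame with the headline benchmark values per pipeline.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "dfc_benchmark_report"))
  rows <- lapply(report$pipelines, function(e) {
    data.frame(
      pipeline = e$pipeline,
      median_abs_dispersion_motion_r = e$dispersion$median_abs_r,
      pct_edges_fdr = e$dispersion$pct_significant_fdr,
      pct_edges_uncorrected = e$dispersion$pct_significant_uncorrected,
      distance_dependence_r = e$distance_dependence$r_dd,
      mean_Q = if (is.null(e$modularity)) NA_real_ else e$modularity$mean_Q,
      q_motion_r = if (is.null(e$modularity)) NA_real_
                   else e$modularity$q_motion_r,
      median_abs_flexibility_motion_r =
        if (is.null(e$flexibility)) NA_real_ else e$flexibility$median_abs_r,
      median_abs_promiscuity_motion_r =
        if (is.null(e$promiscuity)) NA_real_ else e$promiscuity$median_abs_r,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
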