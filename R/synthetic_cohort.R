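# Synthetic cohort generator: parcel-level BOLD-like time series with
# planted window-varying community structure, motion traces with
# framewise-displacement spikes, spatially decaying motion-coupled artifact
# shared across nodes, and tissue-like nuisance channels. The generator
# emulates the statistical structure the downstream benchmarks assume; it
# performs no voxel-level image synthesis.

#' Artifact and signal model parameters
#'
#' Bundles the parameters of the generative model used by
#' [simulate_clean_signals()] and [inject_artifact()]. Each benchmarked
#' assumption is controlled by a single named parameter so it can be
#' switched off independently: `beta_spike` gates all motion-coupled
#' contamination, `lambda_d` sets its spatial decay, `rho_in`/`rho_out`
#' plant the community structure, and `age_motion_r` couples motion to age.
#'
#' @param beta_spike artifact gain (dimensionless multiplier on the
#'   motion-coupled contamination). `0` switches contamination off
#'   entirely.
#' @param lambda_d spatial decay length of the artifact kernel, mm.
#' @param artifact_scale amplitude of the shared artifact series in
#'   signal units per mm of framewise displacement (default 8): at the
#'   cohort's typical 0.07 mm displacement and unit gain the artifact is
#'   of the same order as the neural-like signal, mirroring how strongly
#'   micromovement contaminates windowed connectivity before de-noising.
#' @param rp_artifact_frac relative amplitude (default 2) of an
#'   artifact component linear in the realignment parameter time series,
#'   the part of motion artifact that realignment-parameter regression can
#'   in principle remove (spin-history and interpolation effects follow
#'   head position); the remainder is coupled to framewise displacement
#'   and is invisible to realignment-only regression.
#' @param lambda_rp spatial decay length (mm, default 20) of the
#'   realignment-coupled component; shorter than `lambda_d`, making this
#'   component the more spatially heterogeneous, strongly
#'   distance-dependent part of the artifact.
#' @param global_drift_sd standard deviation of a slow brain-wide drift
#'   added (scaled by `beta_spike`) to every node.
#' @param rho_in target Pearson correlation between nodes sharing a
#'   planted community within an epoch.
#' @param rho_out target correlation between nodes in different
#'   communities.
#' @param ar1_coef lag-1 autoregressive coefficient of the latent
#'   innovation processes (temporal smoothness before band-limiting).
#' @param age_motion_r target correlation between age and mean relative
#'   RMS displacement across a cohort (negative: younger subjects move
#'   more).
#' @param n_sources number of spatial artifact sources.
#' @param n_csf,n_wm,n_pool number of CSF-like, white-matter-like and
#'   high-variance-pool nuisance channels generated per subject.
#' @return an object of class `dfc_artifact_model`.
#' @export
artifact_model <- function(beta_spike = 1, lambda_d = 40,
                           artifact_scale = 8, rp_artifact_frac = 2,
                           lambda_rp = 20, global_drift_sd = 0.5,
                           rho_in = 0.4, rho_out = 0.05,
                           ar1_coef = 0.3, age_motion_r = -0.3,
                           n_sources = 5L, n_csf = 20L, n_wm = 30L,
                           n_pool = 500L) {
  if (lambda_d <= 0) stop_validation("`lambda_d` must be positive")
  if (abs(rho_in) >= 1 || abs(rho_out) >= 1) {
    stop_validation("`rho_in` and `rho_out` must lie strictly inside (-1, 1)")
  }
  if (rho_out < 0 || rho_in < rho_out) {
    stop_validation(
      "community correlation targets need 0 <= rho_out <= rho_in (block %s)",
      "covariance target is not positive definite otherwise")
  }
  if (abs(age_motion_r) >= 1) stop_validation("|age_motion_r| must be < 1")
  if (artifact_scale < 0) stop_validation("`artifact_scale` must be >= 0")
  if (rp_artifact_frac < 0) stop_validation("`rp_artifact_frac` must be >= 0")
  if (lambda_rp <= 0) stop_validation("`lambda_rp` must be positive")
  structure(list(
    beta_spike = beta_spike, lambda_d = lambda_d,
    artifact_scale = artifact_scale, rp_artifact_frac = rp_artifact_frac,
    lambda_rp = lambda_rp, global_drift_sd = global_drift_sd,
    rho_in = rho_in, rho_out = rho_out, ar1_coef = ar1_coef,
    age_motion_r = age_motion_r,
    n_sources = as.integer(n_sources), n_csf = as.integer(n_csf),
    n_wm = as.integer(n_wm), n_pool = as.integer(n_pool)
  ), class = "dfc_artifact_model")
}

# Uniform draw inside a sphere of the given radius (rejection-free:
# direction times radius^(1/3) scaling).
runif_ball <- function(n, radius) {
  d <- matrix(rnorm(3L * n), ncol = 3L)
  d <- d / sqrt(rowSums(d^2))
  r <- radius * runif(n)^(1 / 3)
  d * r
}

#' Generate a node atlas with planted subnetworks and community schedule
#'
#' Places `n_nodes` node centres inside a 70 mm-radius sphere, spatially
#' clustered by subnetwork so that short-range edges are preferentially
#' within-system, and builds a ground-truth community schedule over
#' `n_epochs` epochs in which a fraction of nodes is reassigned to a
#' different community between consecutive epochs.
#'
#' @param n_nodes number of nodes (default 264, a common whole-brain
#'   spherical parcellation size).
#' @param n_subnetworks number of planted systems (default 11).
#' @param n_epochs number of ground-truth community epochs.
#' @param reassign_frac fraction of nodes reassigned between consecutive
#'   epochs (default 0.2).
#' @param seed integer seed.
#' @return an object of class `dfc_atlas` with components `node_id`
#'   (0-based), `coord_mm` (`n_nodes` x 3), `subnetwork_label` and
#'   `community_schedule` (`n_nodes` x `n_epochs`).
#' @export
generate_atlas <- function(n_nodes = 264L, n_subnetworks = 11L,
                           n_epochs = 3L, reassign_frac = 0.2,
                           seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  n_subnetworks <- assert_count(n_subnetworks, "n_subnetworks", min = 2L)
  n_epochs <- assert_count(n_epochs, "n_epochs", min = 1L)
  if (n_nodes < n_subnetworks) {
    stop_validation("need n_nodes >= n_subnetworks")
  }
  set.seed(seed)
  # subnetwork centres on a jittered Fibonacci sphere: quasi-uniform
  # coverage of the head volume, as real parcellations have, rather than
  # occasionally clumped random draws
  k <- seq_len(n_subnetworks)
  phi <- acos(1 - 2 * (k - 0.5) / n_subnetworks)
  theta <- pi * (1 + sqrt(5)) * k
  centers <- 45 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  centers <- centers + matrix(rnorm(3L * n_subnetworks, sd = 5), ncol = 3L)
  label <- rep_len(seq_len(n_subnetworks), n_nodes)
  label <- sort(label)
  coord <- centers[label, , drop = FALSE] +
    matrix(rnorm(3L * n_nodes, sd = 14), ncol = 3L)
  # keep every centre inside the 70 mm head sphere
  rad <- sqrt(rowSums(coord^2))
  too_far <- rad > 70
  if (any(too_far)) {
    coord[too_far, ] <- coord[too_far, ] * (70 / rad[too_far]) * 0.98
  }

  schedule <- matrix(0L, n_nodes, n_epochs)
  schedule[, 1L] <- label
  if (n_epochs > 1L) {
    for (e in 2L:n_epochs) {
      cur <- schedule[, e - 1L]
      move <- sample.int(n_nodes, size = max(1L, round(reassign_frac * n_nodes)))
      new_lab <- cur
      for (i in move) {
        others <- setdiff(seq_len(n_subnetworks), cur[i])
        new_lab[i] <- others[sample.int(length(others), 1L)]
      }
      # guarantee at least two distinct labels in the epoch
      if (length(unique(new_lab)) < 2L) new_lab[1L] <- cur[1L] %% n_subnetworks + 1L
      schedule[, e] <- new_lab
    }
  }
  structure(list(
    node_id = 0:(n_nodes - 1L),
    coord_mm = coord,
    subnetwork_label = label,
    community_schedule = schedule,
    n_nodes = n_nodes,
    n_subnetworks = n_subnetworks,
    seed = as.integer(seed)
  ), class = "dfc_atlas")
}

#' Generate a framewise head-motion profile
#'
#' Produces a per-frame relative RMS displacement series (mm) consisting of
#' a bounded slowly varying baseline plus occasional spike frames, scaled so
#' that the series mean equals `target_mean_rms` exactly. Six realignment
#' parameter series (3 translations, 3 rotations) are integrated so that
#' the Euclidean norm of the frame-to-frame translation increments
#' reproduces the framewise series. Generated profiles always satisfy the
#' micromovement inclusion rule (mean relative RMS <= 0.2 mm and at most
#' 20 frames above 0.25 mm).
#'
#' @param n_frames number of frames.
#' @param target_mean_rms target mean relative RMS displacement, mm;
#'   must lie in (0, 0.2].
#' @param spike_rate per-frame probability of a displacement spike.
#' @param seed integer seed.
#' @return an object of class `dfc_motion` with `framewise_rel_rms`,
#'   `realign_params` (`n_frames` x 6) and `mean_rel_rms`.
#' @export
generate_motion_profile <- function(n_frames = 120L, target_mean_rms = 0.07,
                                    spike_rate = 0.025, seed = 1L) {
  n_frames <- assert_count(n_frames, "n_frames", min = 5L)
  if (!is.finite(target_mean_rms) || target_mean_rms <= 0 ||
      target_mean_rms > 0.2) {
    stop_validation(
      "`target_mean_rms` must lie in (0, 0.2]; %.3f violates the %s",
      target_mean_rms, "gross-motion inclusion rule")
  }
  set.seed(seed)
  # bounded baseline in [0.75, 1.23] x scale: even at the 0.2 mm cap the
  # rescaled maximum stays below the 0.25 mm spike threshold
  u <- as.numeric(stats::filter(rnorm(n_frames), 0.5, method = "recursive"))
  base <- 0.75 + 0.48 * plogis(u)
  base[1L] <- 0  # no displacement is defined for the first frame

  spike <- rep(FALSE, n_frames)
  spike_idx <- which(runif(n_frames) < spike_rate & seq_len(n_frames) > 1L)
  if (length(spike_idx) > 20L) spike_idx <- spike_idx[1:20]
  spike[spike_idx] <- TRUE
  spike_val <- runif(sum(spike), 0.26, 0.34)
  # keep spikes from dominating the displacement budget
  budget <- 0.6 * target_mean_rms * n_frames
  while (sum(spike_val) > budget && length(spike_val) > 0L) {
    spike_val <- spike_val[-length(spike_val)]
    spike[spike_idx[length(spike_val) + 1L]] <- FALSE
  }

  fd <- base
  fd[spike] <- 0
  remaining <- target_mean_rms * n_frames - sum(spike_val)
  fd <- fd * (remaining / sum(fd))
  fd[spike] <- spike_val

  # integrate translations so that ||diff(translation)|| == fd
  dirs <- matrix(rnorm(3L * n_frames), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  incr <- dirs * fd
  trans <- apply(incr, 2L, cumsum)
  rot <- apply(matrix(rnorm(3L * n_frames, sd = 1e-3), ncol = 3L), 2L, cumsum)
  rp <- cbind(trans, rot)
  colnames(rp) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")

  structure(list(
    framewise_rel_rms = fd,
    realign_params = rp,
    mean_rel_rms = mean(fd),
    seed = as.integer(seed)
  ), class = "dfc_motion")
}

# Latent unit-variance processes: AR(1) innovations, optionally band-passed
# to the analysis band, re-standardized column-wise so that mixing weights
# translate into correlations.
latent_processes <- function(k, n_frames, ar1_coef, tr, band_limit = TRUE) {
  x <- matrix(rnorm(n_frames * k), n_frames, k)
  if (ar1_coef != 0) {
    x <- apply(x, 2L, function(col) {
      as.numeric(stats::filter(col, ar1_coef, method = "recursive"))
    })
    x <- matrix(x, n_frames, k)
  }
  if (band_limit) x <- bandpass(x, tr = tr)
  s <- apply(x, 2L, sd)
  s[s < 1e-12] <- 1
  sweep(x, 2L, s, "/")
}

#' Simulate clean parcel time series with planted community structure
#'
#' Node signals are mixtures of a shared process, per-community factor
#' processes and idiosyncratic noise, with mixing weights chosen so that
#' within-community correlations target `rho_in` and between-community
#' correlations target `rho_out` of the supplied model. The community a
#' node loads on follows the atlas community schedule, so the correlation
#' structure changes between epochs. All latent processes are band-limited
#' to 0.01-0.08 Hz.
#'
#' @param atlas a `dfc_atlas`.
#' @param model a `dfc_artifact_model`.
#' @param n_frames number of frames.
#' @param tr repetition time, seconds.
#' @param seed integer seed.
#' @param band_limit logical; band-pass the latent processes (default
#'   `TRUE`; `FALSE` exposes the raw autoregressive processes).
#' @return a nodes x frames numeric matrix.
#' @export
simulate_clean_signals <- function(atlas, model, n_frames = 120L, tr = 3,
                                   seed = 1L, band_limit = TRUE) {
  stopifnot(inherits(atlas, "dfc_atlas"), inherits(model, "dfc_artifact_model"))
  n_frames <- assert_count(n_frames, "n_frames", min = 10L)
  set.seed(seed)
  n <- atlas$n_nodes
  sched <- atlas$community_schedule
  n_epochs <- ncol(sched)
  epoch_of_frame <- rep(seq_len(n_epochs), length.out = 0L)
  sizes <- rep(n_frames %/% n_epochs, n_epochs)
  sizes[n_epochs] <- n_frames - sum(sizes[-n_epochs])
  epoch_of_frame <- rep(seq_len(n_epochs), times = sizes)

  k_comm <- max(sched)
  shared <- latent_processes(1L, n_frames, model$ar1_coef, tr, band_limit)
  factors <- latent_processes(k_comm, n_frames, model$ar1_coef, tr, band_limit)
  idio <- latent_processes(n, n_frames, model$ar1_coef, tr, band_limit)

  a_shared <- sqrt(model$rho_out)
  a_comm <- sqrt(model$rho_in - model$rho_out)
  a_idio <- sqrt(1 - model$rho_in)

  x <- matrix(0, n, n_frames)
  for (e in seq_len(n_epochs)) {
    fr <- which(epoch_of_frame == e)
    lab <- sched[, e]
    x[, fr] <- a_shared * matrix(shared[fr, 1L], n, length(fr), byrow = TRUE) +
      a_comm * t(factors[fr, lab, drop = FALSE]) +
      a_idio * t(idio[fr, , drop = FALSE])
  }
  x
}

#' Inject motion-coupled artifact and derive nuisance channels
#'
#' Adds to the clean signals an artifact term
#' `beta_spike * fd(t) * s(t) * w_i`, where `fd` is the framewise
#' displacement, `s(t)` a shared slowly varying artifact series and
#' `w_i = sum_k exp(-d(i, source_k) / lambda_d)` an exponentially decaying
#' spatial weight summed over randomly placed artifact sources. A slow
#' global drift (also gated by `beta_spike`) is added uniformly to every
#' node. With `beta_spike = 0` the contaminated signals equal the clean
#' signals exactly.
#'
#' The returned nuisance channels mirror what tissue-based de-noising
#' consumes: the true global mean of the contaminated data, CSF-like
#' channels carrying the artifact series, white-matter-like channels with
#' coordinates (their artifact loading decays with distance to the same
#' sources), and a high-variance channel pool in which a minority of
#' channels carry strong artifact.
#'
#' @param clean nodes x frames matrix from [simulate_clean_signals()].
#' @param motion a `dfc_motion`.
#' @param atlas a `dfc_atlas`.
#' @param model a `dfc_artifact_model`.
#' @param seed integer seed.
#' @return list with `contaminated` (nodes x frames) and `nuisance`
#'   (list: `global`, `csf_like`, `wm` = list(`channels`, `coords`),
#'   `high_variance_pool`).
#' @export
inject_artifact <- function(clean, motion, atlas, model, seed = 1L) {
  stopifnot(is.matrix(clean), inherits(motion, "dfc_motion"),
            inherits(atlas, "dfc_atlas"),
            inherits(model, "dfc_artifact_model"))
  n <- nrow(clean)
  n_frames <- ncol(clean)
  if (n != atlas$n_nodes) stop_validation("clean/atlas node count mismatch")
  if (length(motion$framewise_rel_rms) != n_frames) {
    stop_validation("clean/motion frame count mismatch")
  }
  set.seed(seed)
  fd <- motion$framewise_rel_rms

  sources <- runif_ball(model$n_sources, 70)
  dist_to <- function(coords) {
    # n x n_sources matrix of Euclidean distances
    d2 <- outer(rowSums(coords^2), rowSums(sources^2), "+") -
      2 * coords %*% t(sources)
    sqrt(pmax(d2, 0))
  }
  node_src_dist <- dist_to(atlas$coord_mm)
  # kernels normalized to mean weight 1 so the decay lengths shape only
  # the spatial profile while artifact_scale alone sets the amplitude
  w <- rowSums(exp(-node_src_dist / model$lambda_d))
  w <- w / mean(w)
  w_rp <- rowSums(exp(-node_src_dist / model$lambda_rp))
  w_rp <- w_rp / mean(w_rp)

  s <- as.numeric(stats::filter(rnorm(n_frames), 0.9, method = "recursive"))
  s <- s / sd(s) * model$artifact_scale
  # realignment-coupled component: linear in the rp time series, scaled by
  # the subject's motion level so it contributes to motion associations
  rp_mix <- as.numeric(motion$realign_params %*% rnorm(6L))
  if (sd(rp_mix) > 1e-12) {
    rp_mix <- (rp_mix - mean(rp_mix)) / sd(rp_mix)
  } else {
    rp_mix <- rep(0, n_frames)
  }
  art_t <- fd * s                       # displacement-coupled time course
  rp_t <- model$rp_artifact_frac * model$artifact_scale *
    motion$mean_rel_rms * rp_mix        # realignment-coupled time course
  drift <- as.numeric(stats::filter(rnorm(n_frames), 0.95,
                                    method = "recursive"))
  drift <- drift / sd(drift) * model$global_drift_sd

  contaminated <- clean +
    model$beta_spike * (w %o% art_t) +
    model$beta_spike * (w_rp %o% rp_t) +
    model$beta_spike * matrix(drift, n, n_frames, byrow = TRUE)

  noise <- function(k) matrix(rnorm(n_frames * k, sd = 1), n_frames, k)

  csf <- model$beta_spike * outer(art_t + rp_t,
                                  runif(model$n_csf, 0.5, 1.5)) +
    0.5 * noise(model$n_csf)

  wm_coords <- runif_ball(model$n_wm, 70)
  wm_src_dist <- dist_to(wm_coords)
  wm_w <- rowSums(exp(-wm_src_dist / model$lambda_d))
  wm_w <- wm_w / mean(wm_w)
  wm_w_rp <- rowSums(exp(-wm_src_dist / model$lambda_rp))
  wm_w_rp <- wm_w_rp / mean(wm_w_rp)
  wm <- model$beta_spike * (outer(art_t, wm_w) + outer(rp_t, wm_w_rp)) +
    model$beta_spike * matrix(drift, n_frames, model$n_wm) +
    0.5 * noise(model$n_wm)

  pool <- noise(model$n_pool)
  n_hot <- max(3L, round(0.03 * model$n_pool))
  hot <- sample.int(model$n_pool, n_hot)
  pool[, hot] <- pool[, hot] * 1.5 +
    model$beta_spike * outer(art_t + rp_t, runif(n_hot, 2, 3))

  list(
    contaminated = contaminated,
    nuisance = list(
      global = colMeans(contaminated),
      csf_like = csf,
      wm = list(channels = wm, coords = wm_coords),
      high_variance_pool = pool
    )
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ages uniform on 8-22 years, balanced sex, and motion
#' levels log-normally distributed around 0.07 mm with the model's target
#' age-motion correlation, then simulates clean signals and injects
#' artifact for every subject. All per-subject randomness is derived
#' deterministically from the cohort seed.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param atlas a `dfc_atlas` shared by the cohort.
#' @param model a `dfc_artifact_model`.
#' @param n_frames frames per subject (default 120).
#' @param tr repetition time in seconds (default 3).
#' @param seed master integer seed.
#' @param spike_rate per-frame spike probability passed to the motion
#'   generator.
#' @return an object of class `dfc_cohort`: list with `subjects` (each a
#'   `dfc_subject`), `atlas`, `model` and the generation parameters.
#' @export
generate_cohort <- function(n_subjects, atlas, model, n_frames = 120L,
                            tr = 3, seed = 1L, spike_rate = 0.025) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 3L)
  stopifnot(inherits(atlas, "dfc_atlas"), inherits(model, "dfc_artifact_model"))
  set.seed(derive_seed(seed, 0L))
  age <- runif(n_subjects, 8, 22)
  sex <- rep_len(c(0L, 1L), n_subjects)[sample.int(n_subjects)]
  z_age <- (age - 15) / (14 / sqrt(12))
  r <- model$age_motion_r
  z <- r * z_age + sqrt(1 - r^2) * rnorm(n_subjects)
  target <- pmin(pmax(0.07 * exp(0.35 * z), 0.02), 0.18)

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s_i <- derive_seed(seed, i)
    motion <- generate_motion_profile(n_frames, target_mean_rms = target[i],
                                      spike_rate = spike_rate, seed = s_i)
    clean <- simulate_clean_signals(atlas, model, n_frames, tr,
                                    seed = derive_seed(s_i, 1L))
    inj <- inject_artifact(clean, motion, atlas, model,
                           seed = derive_seed(s_i, 2L))
    subjects[[i]] <- structure(list(
      subject_id = sprintf("sub-%04d", i),
      age = age[i], sex = sex[i],
      motion = motion,
      clean_signals = clean,
      contaminated_signals = inj$contaminated,
      nuisance = inj$nuisance,
      seed = s_i
    ), class = "dfc_subject")
  }
  structure(list(
    subjects = subjects, atlas = atlas, model = model,
    n_frames = as.integer(n_frames), tr = tr, seed = as.integer(seed)
  ), class = "dfc_cohort")
}

#' Covariate table of a cohort
#'
#' @param cohort a `dfc_cohort`.
#' @return data.frame with `subject_id`, `age`, `sex`, `mean_rel_rms`.
#' @export
cohort_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    age = vapply(cohort$subjects, `[[`, 0, "age"),
    sex = vapply(cohort$subjects, function(s) as.numeric(s$sex), 0),
    mean_rel_rms = vapply(cohort$subjects,
                          function(s) s$motion$mean_rel_rms, 0),
    stringsAsFactors = FALSE
  )
}
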