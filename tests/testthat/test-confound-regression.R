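test_that("temporal derivative is a backward difference with leading zero", {
  expect_equal(temporal_derivative(rep(5, 10)), rep(0, 10))
  expect_equal(temporal_derivative(c(0, 1, 3)), c(0, 1, 2))
  expect_equal(temporal_derivative(1:5), c(0, 1, 1, 1, 1))
  expect_error(temporal_derivative(1), "2 frames")
})

test_that("Friston expansion yields 24 columns with the stated layout", {
  set.seed(1)
  rp <- matrix(rnorm(60), 10, 6)
  f <- expand_friston(rp)
  expect_identical(ncol(f), 24L)
  expect_equal(expand_friston(matrix(0, 10, 6)), matrix(0, 10, 24),
               ignore_attr = TRUE)
  for (i in 1:6) {
    expect_equal(f[, 6 + i], temporal_derivative(rp[, i]),
                 ignore_attr = TRUE)
    expect_equal(f[, 12 + i], rp[, i]^2, ignore_attr = TRUE)
    expect_equal(f[, 18 + i], temporal_derivative(rp[, i])^2,
                 ignore_attr = TRUE)
  }
  expect_error(expand_friston(rp[, 1:5]), "frames x 6")
})

test_that("band-pass keeps in-band sinusoids and rejects DC and out-of-band power", {
  tr <- 3
  t <- seq_len(480L)
  amp_after <- function(f_hz) {
    s <- sin(2 * pi * f_hz * (t - 1) * tr)
    y <- bandpass(s, tr)
    b <- coef(lm(y ~ sin(2 * pi * f_hz * (t - 1) * tr) +
                   cos(2 * pi * f_hz * (t - 1) * tr) - 1))
    sqrt(sum(b^2))
  }
  expect_equal(max(abs(bandpass(rep(7, 480L), tr))), 0, tolerance = 1e-8)
  a_in <- amp_after(0.04)
  expect_gte(a_in, 0.9); expect_lte(a_in, 1.0)
  expect_lt(amp_after(0.15), 0.5)
  expect_error(bandpass(rnorm(100), tr = 3, f_hi = 0.2), "Nyquist")
  # matrix input filters column-wise
  m <- cbind(sin(2 * pi * 0.04 * (t - 1) * tr), rnorm(480))
  fm <- bandpass(m, tr)
  expect_equal(fm[, 1], bandpass(m[, 1], tr))
})

test_that("despiking caps spikes and leaves non-outlying samples alone", {
  set.seed(61)
  t <- seq_len(200L)
  x <- sin(2 * pi * t / 40) + rnorm(200, sd = 0.1)
  med <- runmed(x, 7, endrule = "median")
  m <- mad(x - med)
  expect_gt(m, 0)
  # a spike-free series within the outlier threshold passes unchanged
  inliers <- abs(x - med) <= 2.5 * m
  d0 <- despike(x)
  expect_equal(d0[inliers], x[inliers])

  # a +10 MAD spike is shrunk below the 4 MAD cap; nothing else moves
  x[100] <- med[100] + 10 * m
  d <- despike(x)
  med2 <- runmed(x, 7, endrule = "median")
  m2 <- mad(x - med2)
  expect_lte(abs(d[100] - med2[100]), 4 * m2 + 1e-12)
  expect_gt(abs(d[100] - med2[100]), 2.5 * m2)
  expect_equal(d[abs(x - med2) <= 2.5 * m2], x[abs(x - med2) <= 2.5 * m2])
  # repeated application keeps every residual within the cap
  dd <- despike(d)
  expect_true(all(abs(dd - runmed(dd, 7, endrule = "median")) <=
                    4 * mad(d - runmed(d, 7, endrule = "median")) + 1e-12))
})

test_that("compcor components are orthonormal and variance-ordered", {
  set.seed(4)
  base <- rnorm(60)
  pool1 <- outer(base, runif(8, 0.5, 2))          # rank 1
  pc1 <- compcor(pool1 + matrix(rnorm(480, sd = 1e-6), 60, 8), 1L)
  z <- scale(pool1 + matrix(rnorm(480, sd = 1e-6), 60, 8))
  pv <- prcomp(z, center = FALSE)$sdev^2
  expect_gt(pv[1] / sum(pv), 0.999)

  pool <- matrix(rnorm(60 * 12), 60, 12)
  comp <- compcor(pool, 5L)
  expect_equal(crossprod(comp), diag(5), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(compcor(pool1, 5L), "rank")
})

test_that("high-variance pool selection keeps the top-SD channels", {
  set.seed(6)
  ch <- matrix(rnorm(50 * 500), 50, 500)
  expect_identical(select_high_variance_pool(ch, fraction = 1), ch)
  expect_identical(ncol(select_high_variance_pool(ch, fraction = 0.02)), 10L)
  ch[, 17] <- ch[, 17] * 100
  sel <- select_high_variance_pool(ch, fraction = 0.02)
  expect_true(any(apply(sel, 2L, function(c) all(c == ch[, 17]))))
})

test_that("local WM regressor averages in-radius channels with nearest fallback", {
  set.seed(8)
  ch <- matrix(rnorm(40 * 3), 40, 3)
  coords <- rbind(c(5, 0, 0), c(0, 8, 0), c(100, 0, 0))
  expect_equal(local_wm_regressor(c(0, 0, 0), ch[, 1, drop = FALSE],
                                  coords[1, , drop = FALSE]), ch[, 1])
  expect_equal(local_wm_regressor(c(0, 0, 0), ch, coords),
               rowMeans(ch[, 1:2]))
  expect_warning(
    far <- local_wm_regressor(c(200, 0, 0), ch, coords),
    "nearest")
  expect_equal(far, ch[, 3])
})

test_that("pipeline registry produces the documented column counts", {
  subj <- fix_subject()
  counts <- c("2P" = 2L, "6P" = 6L, "9P" = 9L, "24P" = 24L, "36P" = 36L,
              "36P_DESPIKE" = 36L, "ACOMPCOR" = 22L, "TCOMPCOR" = 6L,
              "WMMEAN" = 13L, "NONE" = 0L)
  for (nm in names(counts)) {
    rs <- assemble_regressors(subj, pipeline_spec(nm), tr = 3)
    expect_identical(ncol(rs$matrix), counts[[nm]])
  }
  # local-WM pipeline carries a per-node column
  rs <- assemble_regressors(subj, pipeline_spec("WMLOCAL"), tr = 3,
                            atlas = fix_atlas_small())
  expect_identical(ncol(rs$matrix), 12L)
  expect_identical(dim(rs$local_wm), c(120L, 20L))
  # gsr add-on appends one column; gsr pipelines refuse gsr = FALSE
  rs6g <- assemble_regressors(subj, pipeline_spec("6P", gsr = TRUE), tr = 3)
  expect_identical(ncol(rs6g$matrix), 7L)
  expect_error(pipeline_spec("XP"), "unknown pipeline")
  expect_error(pipeline_spec("36P", gsr = FALSE), "GSR by definition")
})

test_that("residuals are orthogonal to every design column for all pipelines", {
  subj <- fix_subject()
  atlas <- fix_atlas_small()
  for (nm in setdiff(pipeline_names(), "NONE")) {
    spec <- pipeline_spec(nm)
    res <- suppressWarnings(apply_pipeline(subj, spec, tr = 3, atlas = atlas))
    regs <- suppressWarnings(assemble_regressors(subj, spec, tr = 3,
                                                 atlas = atlas))
    x <- regs$matrix
    rn <- t(res)
    dots <- crossprod(x, rn) /
      outer(sqrt(colSums(x^2)), sqrt(colSums(rn^2)))
    expect_lt(max(abs(dots)), 1e-6, label = paste("pipeline", nm))
  }
})

test_that("intercept-only pipeline returns demeaned band-passed signals", {
  subj <- fix_subject()
  res <- apply_pipeline(subj, "NONE", tr = 3)
  y <- bandpass(t(subj$contaminated_signals), tr = 3)
  y <- sweep(y, 2L, colMeans(y), "-")
  expect_equal(res, t(y), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("regressing the exact artifact series recovers the clean residuals", {
  atlas <- fix_atlas_small()
  mp <- generate_motion_profile(120L, 0.07, seed = 3L)
  clean <- simulate_clean_signals(atlas, artifact_model(), 120L, 3, seed = 7L)
  inj <- inject_artifact(clean, mp, atlas, artifact_model(), seed = 5L)
  added <- inj$contaminated - clean
  energy <- order(rowSums(added^2), decreasing = TRUE)

  subj_dirty <- structure(list(
    subject_id = "s1", age = 15, sex = 0, motion = mp,
    clean_signals = clean, contaminated_signals = inj$contaminated,
    nuisance = inj$nuisance), class = "dfc_subject")
  subj_clean <- subj_dirty
  subj_clean$contaminated_signals <- clean

  # the added artifact spans three time courses; three independent
  # mixtures of node rows recover that span exactly
  extra <- cbind(added[energy[1], ], added[energy[10], ], colMeans(added))
  r_dirty <- apply_pipeline(subj_dirty, "NONE", tr = 3,
                            extra_regressors = extra)
  r_clean <- apply_pipeline(subj_clean, "NONE", tr = 3,
                            extra_regressors = extra)
  rms <- sqrt(mean((r_dirty - r_clean)^2))
  expect_lt(rms, 1e-6)
})

test_that("GSR removes the brain-wide mean component of the residuals", {
  subj <- fix_subject()
  res <- apply_pipeline(subj, "9P", tr = 3)
  g <- bandpass(subj$nuisance$global, tr = 3)
  # each node residual is exactly orthogonal to the global regressor ...
  expect_lt(max(abs(res %*% g)) / sqrt(sum(g^2)), 1e-8)
  # ... and since the global is the node mean, the residual mean series
  # vanishes to machine precision
  data_scale <- sd(bandpass(t(subj$contaminated_signals), tr = 3))
  expect_lt(max(abs(colMeans(res))), 1e-8 * data_scale)
})

test_that("adding regressors never increases residual variance", {
  subj <- fix_subject()
  v_none <- apply(apply_pipeline(subj, "NONE", tr = 3), 1L, var)
  v_6p <- apply(apply_pipeline(subj, "6P", tr = 3), 1L, var)
  v_24p <- apply(apply_pipeline(subj, "24P", tr = 3), 1L, var)
  expect_true(all(v_6p <= v_none + 1e-12))
  expect_true(all(v_24p <= v_6p + 1e-12))
})

test_that("collinear design columns are dropped with a warning, not an error", {
  subj <- fix_subject()
  dup <- subj$motion$realign_params[, 1L]
  expect_warning(
    res <- apply_pipeline(subj, "6P", tr = 3,
                          extra_regressors = cbind(dup, dup)),
    "collinear")
  expect_identical(dim(res), dim(subj$contaminated_signals))
})
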