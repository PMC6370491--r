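test_that("atlas has the requested geometry, labels and schedule", {
  atlas <- generate_atlas(264L, 11L, n_epochs = 3L, seed = 1L)
  expect_length(atlas$node_id, 264L)
  expect_identical(atlas$node_id, 0:263)
  expect_equal(sort(unique(atlas$subnetwork_label)), 1:11)
  expect_true(all(is.finite(atlas$coord_mm)))
  expect_true(all(sqrt(rowSums(atlas$coord_mm^2)) <= 70 + 1e-9))
  # every epoch keeps at least two communities
  for (e in seq_len(ncol(atlas$community_schedule))) {
    expect_gte(length(unique(atlas$community_schedule[, e])), 2L)
  }
  # consecutive epochs differ by roughly the reassignment fraction
  moved <- mean(atlas$community_schedule[, 1L] != atlas$community_schedule[, 2L])
  expect_gt(moved, 0.05)
  expect_lt(moved, 0.35)
})

test_that("single-epoch schedules are constant and atlases deterministic", {
  a1 <- generate_atlas(30L, 4L, n_epochs = 1L, seed = 3L)
  expect_identical(ncol(a1$community_schedule), 1L)
  expect_identical(generate_atlas(30L, 4L, 2L, seed = 8L),
                   generate_atlas(30L, 4L, 2L, seed = 8L))
  expect_error(generate_atlas(0L, 2L), "n_nodes")
  expect_error(generate_atlas(5L, 8L), "n_nodes >= n_subnetworks")
})

test_that("motion profiles hit their target and obey the inclusion rule", {
  mp <- generate_motion_profile(120L, 0.07, seed = 3L)
  expect_gte(mp$mean_rel_rms, 0.063)
  expect_lte(mp$mean_rel_rms, 0.077)
  expect_equal(mp$mean_rel_rms, mean(mp$framewise_rel_rms))
  expect_true(all(mp$framewise_rel_rms >= 0))
  expect_lte(sum(mp$framewise_rel_rms > 0.25), 20L)
  # translations integrate to the framewise series
  d <- sqrt(rowSums(diff(mp$realign_params[, 1:3])^2))
  expect_equal(d, mp$framewise_rel_rms[-1L], tolerance = 1e-12)
  expect_error(generate_motion_profile(120L, 0.3), "0, 0.2")
})

test_that("spike-free profiles stay below the spike threshold", {
  for (target in c(0.05, 0.12, 0.2)) {
    mp <- generate_motion_profile(150L, target, spike_rate = 0, seed = 11L)
    expect_lt(max(mp$framewise_rel_rms), 0.25)
  }
})

test_that("clean signals carry the planted community structure", {
  atlas <- fix_atlas100()
  x <- simulate_clean_signals(atlas, artifact_model(), 120L, 3, seed = 7L)
  lab <- atlas$community_schedule[, 1L]
  r <- cor(t(x[, 1:40]))
  same <- outer(lab, lab, "==") & upper.tri(r)
  diff_ <- (!outer(lab, lab, "==")) & upper.tri(r)
  gap <- mean(r[same]) - mean(r[diff_])
  expect_gte(gap, 0.1)

  # exchangeable nodes when rho_in == rho_out
  m0 <- artifact_model(rho_in = 0.2, rho_out = 0.2)
  x0 <- simulate_clean_signals(atlas, m0, 120L, 3, seed = 7L)
  r0 <- cor(t(x0[, 1:40]))
  expect_lt(abs(mean(r0[same]) - mean(r0[diff_])), 0.03)

  expect_error(artifact_model(rho_in = 0.1, rho_out = 0.3),
               "positive definite")
})

test_that("white innovations have near-zero lag-1 autocorrelation", {
  atlas <- fix_atlas_small()
  x <- simulate_clean_signals(atlas, fix_light_model(ar1_coef = 0),
                              400L, 3, seed = 13L, band_limit = FALSE)
  ac1 <- apply(x, 1L, function(s) cor(s[-1L], s[-length(s)]))
  expect_lt(max(abs(ac1)), 0.2)
  expect_lt(abs(mean(ac1)), 0.05)
})

test_that("artifact injection is gated by beta_spike and spatially flat in the large-lambda limit", {
  atlas <- fix_atlas_small()
  mp <- generate_motion_profile(120L, 0.07, seed = 3L)
  clean <- simulate_clean_signals(atlas, artifact_model(), 120L, 3, seed = 7L)

  inj0 <- inject_artifact(clean, mp, atlas, artifact_model(beta_spike = 0),
                          seed = 5L)
  expect_identical(inj0$contaminated, clean)

  inj_flat <- inject_artifact(clean, mp, atlas,
                              artifact_model(lambda_d = 1e8,
                                             lambda_rp = 1e8), seed = 5L)
  added <- inj_flat$contaminated - clean
  # all nodes receive an identical artifact when the kernel is flat
  spread <- max(abs(sweep(added, 2L, added[1L, ], "-")))
  expect_lt(spread / max(abs(added)), 1e-6)

  expect_error(inject_artifact(clean[, 1:50], mp, atlas, artifact_model()),
               "frame count")
})

test_that("cohorts satisfy inclusion, demographics and the age-motion target", {
  atlas <- fix_atlas_small()
  coh <- generate_cohort(400L, atlas, fix_light_model(), 120L, 3, seed = 11L)
  cv <- cohort_covariates(coh)
  expect_true(all(cv$mean_rel_rms <= 0.2))
  expect_true(all(cv$age >= 8 & cv$age <= 22))
  expect_lte(abs(mean(cv$sex) - 0.5), 0.01)
  expect_lt(abs(cor(cv$age, cv$mean_rel_rms) - (-0.3)), 0.1)
  ok_spikes <- vapply(coh$subjects, function(s) {
    sum(s$motion$framewise_rel_rms > 0.25) <= 20L
  }, logical(1))
  expect_true(all(ok_spikes))

  coh0 <- generate_cohort(400L, atlas, fix_light_model(age_motion_r = 0),
                          120L, 3, seed = 12L)
  cv0 <- cohort_covariates(coh0)
  expect_lt(abs(cor(cv0$age, cv0$mean_rel_rms)), 0.1)
})

test_that("cohort generation is deterministic under a fixed seed", {
  atlas <- fix_atlas_small()
  c1 <- generate_cohort(3L, atlas, fix_light_model(), 120L, 3, seed = 21L)
  c2 <- generate_cohort(3L, atlas, fix_light_model(), 120L, 3, seed = 21L)
  expect_identical(c1, c2)
})
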