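small_cfg <- function(...) {
  sim_config(n_per_group = 2, n_stims = 25, emg_rate = 1000,
             track_duration = 20, track_rate = 25, seed = 42, ...)
}

test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(spatial_sd = 0), "spatial_sd")
  expect_error(sim_config(scalp_extent = c(-60, 60)), "scalp_extent")
  expect_error(simulate_tms_session(small_cfg(), "S001", "biceps"),
               "muscle")
})

test_that("amplitude surface is the closed-form Gaussian bump", {
  expect_equal(amplitude_surface(0, 400, 10), 400)
  expect_equal(amplitude_surface(10, 400, 10), 400 * exp(-0.5),
               tolerance = 1e-12)
  # a noiseless session's amplitudes equal the surface at each distance
  cfg <- small_cfg(noise_sd = 0)
  ses <- simulate_tms_session(cfg, "S001", "longissimus_L3")
  d <- sqrt((ses$sites$x - ses$true_cog[1])^2 +
            (ses$sites$y - ses$true_cog[2])^2 +
            (ses$sites$z - ses$true_cog[3])^2)
  expect_equal(ses$sites$true_amplitude,
               amplitude_surface(d, cfg$amplitude_peak, cfg$spatial_sd),
               tolerance = 1e-9)
  # the synthetic epoch reproduces the amplitude as raw peak-to-peak
  a <- ses$sites$true_amplitude[1]
  expect_equal(peak_to_peak(ses$epochs[1, ]), a, tolerance = 1e-9)
})

test_that("same seed gives identical output; substreams are stable", {
  cfg <- small_cfg()
  s1 <- simulate_tms_session(cfg, "S001", "longissimus_L3")
  s2 <- simulate_tms_session(cfg, "S001", "longissimus_L3")
  expect_identical(s1, s2)
  t1 <- simulate_tracking_trial(cfg, "S001")
  t2 <- simulate_tracking_trial(cfg, "S001")
  expect_identical(t1, t2)
  o1 <- simulate_outcome_table(5, c("a", "b"), seed = 3)
  o2 <- simulate_outcome_table(5, c("a", "b"), seed = 3)
  expect_identical(o1, o2)
  # different subjects draw from different streams
  expect_false(identical(s1$sites,
                         simulate_tms_session(cfg, "S002",
                                              "longissimus_L3")$sites))
  # growing the cohort does not reshuffle an existing subject's session
  c2 <- simulate_cohort(small_cfg(), raw_tms = TRUE)
  c3 <- simulate_cohort(sim_config(n_per_group = 3, n_stims = 25,
                                   emg_rate = 1000, track_duration = 20,
                                   track_rate = 25, seed = 42),
                        raw_tms = TRUE)
  expect_identical(c2$sessions$S001$longissimus_L3$sites,
                   c3$sessions$S001$longissimus_L3$sites)
})

test_that("tracking generator: perfect cursor at zero lag and noise,
           Rayleigh-scale errors under isotropic noise", {
  cfg0 <- small_cfg(track_lag = 0, track_noise_sd = 0)
  tr <- simulate_tracking_trial(cfg0, "S001")
  expect_equal(tr$actual_x, tr$target_x, tolerance = 1e-12)
  expect_equal(tr$actual_y, tr$target_y, tolerance = 1e-12)
  # isotropic 0.5 deg noise: mean Euclidean error near the Rayleigh mean
  # 0.5 * sqrt(pi / 2) ~= 0.627 deg
  cfgn <- sim_config(n_per_group = 2, track_lag = 0, track_noise_sd = 0.5,
                     track_duration = 40, track_rate = 25, seed = 8)
  trn <- simulate_tracking_trial(cfgn, "S001")
  e <- tracking_error(trn)
  expect_gt(length(e), 1000)
  expect_gt(mean(e), 0.3)
  expect_lt(mean(e), 1.0)
  expect_error(sim_config(track_duration = 0), "track_duration")
})

test_that("cohort structure: 200 outcome slots, balanced groups", {
  cfg <- sim_config(n_per_group = 25, n_stims = 3, emg_rate = 500,
                    missing_rate = 0, track_duration = 2, track_rate = 5,
                    seed = 10)
  coh <- simulate_cohort(cfg, raw_tms = FALSE)
  expect_equal(nrow(coh$subjects), 50)
  expect_equal(sum(coh$subjects$group == "LBP"), 25)
  # 50 subjects x 4 muscles = 200 muscle-level outcome slots
  expect_equal(length(coh$truth$missing), 200)
  expect_true(all(!coh$truth$missing))
})

test_that("missingness is completely at random at the configured rate", {
  counts <- vapply(1:30, function(k) {
    cfg <- sim_config(n_per_group = 25, missing_rate = 0.065,
                      track_duration = 2, track_rate = 5, seed = 1000 + k)
    sum(simulate_cohort(cfg, raw_tms = FALSE)$truth$missing)
  }, numeric(1))
  # binomial(200, 0.065): mean 13, sd 3.49; the mean of 30 replicates has
  # standard error 0.64
  expect_lt(abs(mean(counts) - 13), 2)
})

test_that("planted group effects surface in the group means", {
  diffs <- vapply(1:200, function(k) {
    long <- simulate_outcome_table(10, c("a", "b"),
                                   effects = c(a = 0, b = 2),
                                   subject_sd = 0.7, residual_sd = 1,
                                   seed = k)
    oracle_mean_diffs(long)[["b"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 2), 0.12)
  # zero effects, zero noise: both groups identical on all tests
  long0 <- simulate_outcome_table(5, c("a", "b"), effects = 0,
                                  subject_sd = 0, residual_sd = 0,
                                  means = c(a = 1, b = 2), seed = 1)
  expect_equal(oracle_mean_diffs(long0), c(a = 0, b = 0))
  expect_true(all(long0$value[long0$test == "a"] == 1))
})

test_that("cohort raw records score back to the planted clinical values", {
  cfg <- small_cfg(missing_rate = 0)
  coh <- simulate_cohort(cfg, raw_tms = FALSE)
  sc <- score_cohort(coh)
  v <- coh$truth$clinical_values
  # replicate-encoded tests reproduce the planted value exactly
  # (values inside their physical scales)
  for (s in coh$subjects$subject) {
    i <- match(s, sc$subject)
    expect_equal(sc$ppt[i], max(v[s, "ppt"], 5), tolerance = 1e-9)
    expect_equal(sc$cpm_abs[i], v[s, "cpm_abs"], tolerance = 1e-9)
    expect_equal(sc$tpd[i], max(v[s, "tpd"], 20), tolerance = 1e-9)
  }
  # missing sessions contain no supra-threshold epochs
  cfgm <- small_cfg(missing_rate = 0.5)
  cohm <- simulate_cohort(cfgm, raw_tms = TRUE)
  miss <- cohm$truth$missing
  idx <- which(miss, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  s <- rownames(miss)[idx[1, 1]]
  m <- colnames(miss)[idx[1, 2]]
  ses <- cohm$sessions[[s]][[m]]
  expect_lt(max(apply(ses$epochs, 1, function(e) max(e) - min(e))), 50)
})
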