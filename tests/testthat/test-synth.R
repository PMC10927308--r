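test_that("aperiodic generator produces the target spectral slope", {
  # white noise: flat spectrum
  x <- sim_aperiodic_noise(256 * 120, 256, 0, seed = 1)
  ps <- welch_psd(matrix(x, 1), fs = 256)
  sel <- ps$freqs >= 4 & ps$freqs <= 40
  slope <- stats::coef(stats::lm(log10(ps$power[1, sel]) ~
                                   log10(ps$freqs[sel])))[2]
  expect_lt(abs(slope), 0.05)

  # chi = 2 recovered by least-squares log-log slope, averaged over seeds
  slopes <- vapply(1:20, function(s) {
    x <- sim_aperiodic_noise(256 * 120, 256, 2, seed = s)
    ps <- welch_psd(matrix(x, 1), fs = 256)
    sel <- ps$freqs >= 4 & ps$freqs <= 40
    stats::coef(stats::lm(log10(ps$power[1, sel]) ~
                            log10(ps$freqs[sel])))[2]
  }, 0)
  expect_lt(abs(mean(slopes) + 2), 0.1)
})

test_that("generators are deterministic given a seed and validate inputs", {
  expect_identical(sim_aperiodic_noise(1024, 256, 1.5, seed = 11),
                   sim_aperiodic_noise(1024, 256, 1.5, seed = 11))
  expect_identical(sim_coupled_pair(128, 10, 10, pi / 2, 0.8, seed = 3),
                   sim_coupled_pair(128, 10, 10, pi / 2, 0.8, seed = 3))
  expect_error(sim_aperiodic_noise(1024, 256, -1), "non-negative")
  expect_error(sim_aperiodic_noise(1024, 256, NaN), "finite")
  expect_error(sim_aperiodic_noise(100, 256, 1), "2 seconds")
  expect_error(sim_coupled_pair(128, 10, 10, pi / 2, 1.2), "\\[0, 1\\]")
  expect_error(sim_band_oscillation(1024, 128, 80, 1), "fs/2")
  expect_warning(sim_coupled_pair(128, 4, 10, 3 * pi / 2, 0.5, seed = 1),
                 "wrapped")
})

test_that("unit-variance output and zero mean hold for all generators", {
  for (x in list(sim_aperiodic_noise(4096, 128, 1.3, seed = 2),
                 sim_band_oscillation(4096, 128, 10, 1.5, seed = 2))) {
    expect_lt(abs(mean(x)), 1e-10)
    expect_equal(stats::sd(x), 1, tolerance = 1e-10)
  }
})

test_that("band wPLI rises monotonically with pair coupling", {
  couplings <- c(0, 0.25, 0.5, 0.75, 0.95)
  w <- vapply(couplings, function(cc) {
    pair <- sim_coupled_pair(128, 60, 10, pi / 2, cc, seed = 99)
    band_wpli_of_pair(pair, 128, c(8, 13))
  }, 0)
  expect_true(all(diff(w) >= 0))
  expect_lt(w[1], 0.2)
  expect_gt(w[5], 0.9)
})

test_that("a simulated study has the right structure and determinism", {
  cfg <- tiny_config()
  st <- simulate_study(cfg)
  expect_length(st$recordings, 8)            # 4 subjects x 2 conditions
  ages <- unique(st$ground_truth[, c("subject_id", "age")])
  expect_equal(nrow(ages), 4)                # same age in both conditions
  expect_equal(length(unique(ages$age)), 4)
  gt <- unique(st$ground_truth[, c("subject_id", "condition", "exponent")])
  wide <- tidyr::pivot_wider(gt, names_from = "condition",
                             values_from = "exponent")
  expect_equal(wide$altitude - wide$sea,
               rep(cfg$condition_effects$exponent_delta, 4))
  # determinism: regenerating one recording reproduces it exactly
  again <- simulate_recording(cfg, 2, "altitude")
  expect_identical(again$data, st$recordings[["S02_altitude"]]$data)
  # altitude boosts theta coupling strengths only (no alpha entries here)
  expect_equal(st$coupling$altitude$strength[st$coupling$sea$band == "theta"],
               pmin(0.95, st$coupling$sea$strength[
                 st$coupling$sea$band == "theta"] *
                   cfg$condition_effects$theta_coupling_boost))
})

test_that("programmed exponent contrast is recovered through the spectral fit", {
  cfg <- tiny_config(n_subjects = 3, duration = 60)
  cfg$condition_effects$exponent_delta <- -0.3
  diffs <- vapply(1:3, function(s) {
    fits <- vapply(c("sea", "altitude"), function(cond) {
      rec <- simulate_recording(cfg, s, cond)
      ps <- welch_psd(rec)
      mean(fit_aperiodic_channels(ps)$exponent)
    }, 0)
    fits[["altitude"]] - fits[["sea"]]
  }, 0)
  expect_lt(abs(mean(diffs) + 0.3), 0.1)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(fs = 30), "Nyquist|twice")
  expect_error(synth_config(exponent_base = -1), "exponent_base")
  expect_error(synth_config(age_range = c(5, 40)), "age_range")
  bad <- tibble::tibble(band = "theta", chan_i = "nope", chan_j = "ch01",
                        lag = pi / 2, strength = 0.5)
  expect_error(synth_config(n_channels = 8, coupling_spec = bad),
               "unknown channels")
  bad2 <- bad; bad2$chan_i <- "ch02"; bad2$strength <- 1.5
  expect_error(synth_config(n_channels = 8, coupling_spec = bad2),
               "\\[0, 1\\]")
})
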