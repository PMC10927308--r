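test_that("Welch PSD has the nominal resolution and conserves power", {
  set.seed(8)
  x <- rnorm(256 * 300)
  ps <- welch_psd(matrix(x, 1), fs = 256)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.25)   # 4-s window -> 0.25 Hz
  # Parseval: integral of the one-sided density equals the variance
  integral <- sum(diff(ps$freqs) *
                    (head(ps$power[1, ], -1) + tail(ps$power[1, ], -1)) / 2)
  expect_equal(integral, stats::var(x), tolerance = 0.05)
})

test_that("a pure tone peaks at its own frequency bin", {
  rec <- tone_recording(10, fs = 256, duration = 20)
  ps <- welch_psd(rec)
  expect_equal(ps$freqs[which.max(ps$power[1, ])], 10)
  expect_error(welch_psd(tone_recording(10, fs = 256, duration = 2)),
               "window")
})

test_that("relative band powers tile the broadband range", {
  cfg <- tiny_config(n_subjects = 1)
  rec <- simulate_recording(cfg, 1, "sea")
  ps <- welch_psd(rec)
  total <- Reduce(`+`, lapply(eeg_bands(), function(b) {
    relative_band_power(ps, b)
  }))
  expect_equal(unname(total), rep(1, 8), tolerance = 1e-6)
  # rescaling the signal leaves relative power unchanged
  rec5 <- rec; rec5$data <- rec5$data * 5
  expect_equal(relative_band_power(welch_psd(rec5), c(8, 13)),
               relative_band_power(ps, c(8, 13)), tolerance = 1e-12)
})

test_that("band power matches flat- and line-spectrum expectations", {
  rec <- tone_recording(10, fs = 256, duration = 60, noise_sd = 1e-4)
  ps <- welch_psd(rec)
  expect_gte(relative_band_power(ps, c(8, 13))[[1]], 0.95)

  set.seed(9)
  psw <- welch_psd(matrix(rnorm(256 * 300), 1), fs = 256)
  for (b in eeg_bands()) {
    expect_equal(relative_band_power(psw, b)[[1]],
                 (b[2] - b[1]) / 29.5, tolerance = 0.05)
  }
  expect_error(relative_band_power(psw, c(20, 40)), "within")
})

test_that("a noiseless log-log line is parameterized exactly", {
  f <- seq(0.25, 45, by = 0.25)
  pw <- 10^(1 - 1.5 * log10(f))
  ft <- fit_aperiodic(f, pw)
  expect_equal(ft$exponent, 1.5, tolerance = 1e-6)
  expect_equal(ft$offset, 1, tolerance = 1e-6)
  expect_equal(nrow(ft$peaks), 0)
  expect_gt(ft$r_squared, 0.999999)
})

test_that("white noise fits a near-zero exponent", {
  x <- sim_aperiodic_noise(256 * 300, 256, 0, seed = 10)
  ps <- welch_psd(matrix(x, 1), fs = 256)
  ft <- fit_aperiodic(ps$freqs, ps$power[1, ])
  expect_lt(abs(ft$exponent), 0.05)
})

test_that("an oscillatory peak is removed and recovered", {
  res <- vapply(1:5, function(s) {
    x <- sim_aperiodic_noise(256 * 120, 256, 1, seed = 100 + s) +
      0.6 * sim_band_oscillation(256 * 120, 256, 10, 1.5, seed = 200 + s)
    ps <- welch_psd(matrix(x, 1), fs = 256)
    ft <- fit_aperiodic(ps$freqs, ps$power[1, ])
    c(ft$exponent, nrow(ft$peaks),
      ft$peaks$center[which.max(ft$peaks$height)])
  }, numeric(3))
  expect_lt(abs(mean(res[1, ]) - 1), 0.2)
  expect_true(all(res[2, ] >= 1))
  expect_true(all(abs(res[3, ] - 10) <= 1))
})

test_that("aperiodic fit rejects degenerate inputs", {
  f <- seq(4, 40, by = 8)
  expect_error(fit_aperiodic(f, rep(1, length(f))), "10 frequency bins")
  f2 <- seq(0.25, 45, 0.25)
  p2 <- 10^(-log10(f2)); p2[30] <- 0
  expect_error(fit_aperiodic(f2, p2), "positive")
})

test_that("channel-wise fitting returns one row per channel", {
  cfg <- tiny_config(n_subjects = 1, duration = 60)
  ps <- welch_psd(simulate_recording(cfg, 1, "sea"))
  tb <- fit_aperiodic_channels(ps)
  expect_equal(nrow(tb), 8)
  expect_true(all(is.finite(tb$exponent)))
  expect_true(all(tb$r_squared >= 0 & tb$r_squared <= 1))
})
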