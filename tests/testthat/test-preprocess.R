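test_that("Bessel band filter has unit passband gain and strong stopband", {
  rec <- tone_recording(c(10, 50), fs = 256, duration = 10)
  out <- eeg_bandpass(rec, 8, 13, design = "bessel3")
  mid <- 1000:1560
  expect_gt(max(abs(out$data[1, mid])), 0.95)    # 10 Hz inside alpha band
  expect_lt(stats::sd(out$data[2, mid]) / stats::sd(rec$data[2, mid]), 0.1)
})

test_that("DC is removed by a 0.5-30 Hz band-pass", {
  rec <- eeg_recording(matrix(1, 2, 2560), fs = 256)
  out <- eeg_bandpass(rec, 0.5, 30, design = "bessel3")
  expect_lt(max(abs(out$data[, 500:2000])), 1e-3)
  out_fir <- eeg_bandpass(rec, 0.5, 30, design = "fir")
  expect_lt(max(abs(out_fir$data[, 500:2000])), 1e-3)
})

test_that("filtering is zero-phase", {
  # narrowband input: cross-correlation with its filtered version peaks at 0
  x <- sim_band_oscillation(256 * 8, 256, 10, 1, seed = 4)
  rec <- eeg_recording(rbind(x, x), fs = 256)
  for (design in c("bessel3", "fir")) {
    y <- eeg_bandpass(rec, 8, 13, design = design)$data[1, ]
    cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("band edges are validated", {
  rec <- tone_recording(10, fs = 128, duration = 4)
  expect_error(eeg_bandpass(rec, 13, 8), "low < high")
  expect_error(eeg_bandpass(rec, 8, 70), "low < high")
})

test_that("resampling preserves duration and waveform", {
  rec <- tone_recording(10, fs = 4096, duration = 2)
  half <- eeg_resample(rec, 2048)
  expect_equal(half$fs, 2048)
  expect_lte(abs(ncol(half$data) - ncol(rec$data) / 2), 1)

  expect_identical(eeg_resample(rec, 4096), rec)   # identity
  expect_error(eeg_resample(rec, 8192), "upsampling")

  low <- eeg_resample(rec, 256)
  # closed-form sinusoid on the retained sample grid
  t_kept <- seq(1 / 4096, 2, by = 1 / 4096)[seq(1, 2 * 4096, by = 16)]
  ref <- sin(2 * pi * 10 * t_kept)
  mid <- 50:460
  expect_gt(stats::cor(low$data[1, mid], ref[mid]), 0.999)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(4 * 512), 4), fs = 128)
  ref <- average_reference(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-10 * stats::sd(rec$data))
  expect_equal(average_reference(ref)$data, ref$data)
  # two antisymmetric channels are already referenced
  x <- rnorm(512)
  rec2 <- eeg_recording(rbind(x, -x), fs = 128)
  expect_equal(average_reference(rec2)$data, rec2$data)
  expect_error(average_reference(eeg_recording(matrix(x, 1), 128)),
               "2 channels")
})

test_that("epoching follows the floor rule", {
  mk <- function(dur) tone_recording(5, fs = 128, duration = dur)
  expect_equal(epoch_recording(mk(120), 12)$n_epochs, 10)
  expect_equal(epoch_recording(mk(125), 12)$n_epochs, 10)
  expect_equal(epoch_recording(mk(12), 12)$n_epochs, 1)
  expect_error(epoch_recording(mk(10), 12), "shorter")
  ep <- epoch_recording(mk(30), 12)
  expect_equal(dim(ep$data), c(1, 12 * 128, 2))
})

test_that("the preprocessing chain applies stages in the fixed order", {
  cfg <- tiny_config(n_subjects = 1)
  rec <- simulate_recording(cfg, 1, "sea")
  pp <- preprocess_recording(rec)
  expect_named(pp$bands, c("delta", "theta", "alpha", "beta"))
  expect_equal(pp$log[1], sprintf("fir_bandpass 0.50-%.2f Hz",
                                  min(100, rec$fs / 2 * 0.95)))
  expect_equal(pp$log[2], "average_reference")
  expect_lt(max(abs(colMeans(pp$broadband$data))), 1e-8)
  # purity: running again gives identical output
  pp2 <- preprocess_recording(rec)
  expect_identical(pp$broadband$data, pp2$broadband$data)
})
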