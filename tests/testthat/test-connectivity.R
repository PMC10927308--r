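test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  n <- 512
  tp <- dpss_tapers(n, nw = 4, k = 7)
  expect_equal(crossprod(tp), diag(7), tolerance = 1e-10)
  pad <- 16 * n
  conc <- vapply(1:5, function(j) {
    P <- Mod(stats::fft(c(tp[, j], rep(0, pad - n))))^2
    f <- (0:(pad - 1)) / pad
    sum(P[f <= 4 / n | f >= 1 - 4 / n]) / sum(P)
  }, 0)
  expect_true(all(conc > 0.99))
})

test_that("cross-spectra are Hermitian with real auto-spectra", {
  set.seed(12)
  epoch <- matrix(rnorm(3 * 512), 3)
  cs <- multitaper_cross_spectra(epoch, fs = 128, band = c(8, 13))
  est <- cs$est
  for (k in 1:2) {
    for (b in 1:2) {
      S <- est[k, b, , ]
      expect_equal(S, Conj(t(S)))
      expect_lt(max(abs(Im(diag(S)))), 1e-12 * max(Mod(diag(S))))
      expect_true(all(Re(diag(S)) >= 0))
    }
  }
  expect_error(multitaper_cross_spectra(epoch, 128, c(8, 70)), "Nyquist")
  expect_error(multitaper_cross_spectra(epoch, 128, c(8, 13), n_tapers = 1),
               ">= 2")
})

test_that("a quarter-cycle lag gives consistently signed imaginary parts", {
  pair <- sim_coupled_pair(128, 4, 10, pi / 2, 1, seed = 14)
  cs <- multitaper_cross_spectra(pair, fs = 128, band = c(9, 11))
  signs <- sign(Im(cs$est[, , 1, 2]))
  expect_true(all(signs == signs[1]))
})

test_that("wPLI hits its boundary values", {
  # noiseless quarter-cycle shift: numerator equals denominator
  src <- sim_band_oscillation(256 * 600, 256, 10, 1.5, seed = 15)
  pair <- rbind(src, phase_rotate(src, pi / 2))
  expect_gt(band_wpli_of_pair(pair, 256, c(8, 13)), 0.999)
  # identical signals: imaginary part identically zero -> degenerate rule
  same <- rbind(src, src)
  expect_equal(band_wpli_of_pair(same, 256, c(8, 13)), 0)
})

test_that("zero-lag mixing (volume-conduction surrogate) yields near-zero wPLI", {
  set.seed(16)
  s1 <- sim_band_oscillation(128 * 120, 128, 10, 1.5)
  s2 <- sim_band_oscillation(128 * 120, 128, 10, 1.5)
  mix <- matrix(runif(16), 8, 2)          # instantaneous mixing, no lags
  data <- mix %*% rbind(s1, s2)
  ep <- epoch_recording(eeg_recording(data, 128), 12)
  W <- wpli_matrix(ep, c(8, 13))
  expect_lte(max(W), 0.15)
})

test_that("independent-noise wPLI is small and shrinks with more epochs", {
  set.seed(17)
  mk <- function(n_epochs) {
    data <- matrix(rnorm(8 * 128 * 2 * n_epochs), 8)
    ep <- epoch_recording(eeg_recording(data, 128), 2)
    W <- wpli_matrix(ep, c(8, 13), n_tapers = 5)
    mean(W[upper.tri(W)])
  }
  w50 <- mk(50)
  w200 <- mk(200)
  expect_lte(w50, 0.15)
  expect_lt(w200, w50)
})

test_that("wPLI is invariant to per-channel amplitude rescaling", {
  cfg <- tiny_config(n_subjects = 1)
  rec <- simulate_recording(cfg, 1, "sea")
  ep1 <- epoch_recording(rec, 12)
  rec2 <- rec
  rec2$data <- rec2$data * c(5, 0.1, 2, 1, 3, 0.5, 7, 1)
  ep2 <- epoch_recording(rec2, 12)
  expect_equal(unclass(wpli_matrix(ep1, c(4, 8))),
               unclass(wpli_matrix(ep2, c(4, 8))), tolerance = 1e-10)
})

test_that("wPLI stays within [0, 1] and pooling matches the op-level path", {
  cfg <- tiny_config(n_subjects = 1)
  ep <- epoch_recording(simulate_recording(cfg, 1, "sea"), 12)
  W <- wpli_matrix(ep, c(4, 8))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(unname(diag(W)), rep(0, 8))
  expect_equal(unclass(W), t(unclass(W)))
  # pooled wPLI from explicit per-epoch cross-spectra matches the streaming
  # implementation
  cs_list <- lapply(seq_len(ep$n_epochs), function(e) {
    multitaper_cross_spectra(ep$data[, , e], ep$fs, c(4, 8))
  })
  expect_equal(unclass(wpli(cs_list)), unclass(W), tolerance = 1e-10)
  # per-epoch variant is a valid connectivity matrix too
  Wpe <- wpli_matrix(ep, c(4, 8), per_epoch = TRUE)
  expect_true(all(Wpe >= 0 & Wpe <= 1))
})

test_that("grand averaging is the element-wise mean", {
  A <- matrix(0.2, 3, 3); diag(A) <- 0
  B <- matrix(0.4, 3, 3); diag(B) <- 0
  expect_equal(grand_average(list(A, A)), A)
  expect_equal(unclass(grand_average(list(A, B))),
               (A + B) / 2, ignore_attr = TRUE)
  expect_identical(grand_average(A), A)
  expect_error(grand_average(list(A, matrix(0, 2, 2))), "mismatch")
})

test_that("nodal strength equals row and column sums", {
  set.seed(18)
  m <- random_weights(6)
  expect_equal(unname(nodal_strength(m)), colSums(m))
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  expect_equal(unname(nodal_strength(ones)), rep(3, 4))
  expect_equal(unname(nodal_strength(matrix(0, 4, 4))), rep(0, 4))
  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(nodal_strength(asym), "symmetric")
})
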