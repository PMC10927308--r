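#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann tapers. The default 4-second
#' window gives a frequency resolution of 0.25 Hz. Power is one-sided
#' density (signal units squared per Hz), so the integral over (0, fs/2]
#' equals the signal variance.
#'
#' @param recording An [eeg_recording()], or a numeric matrix
#'   (channels x samples) together with `fs`.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param fs Sampling rate, required when `recording` is a bare matrix.
#' @return An `eeg_spectrum`: list with `freqs` (Hz), `power`
#'   (channels x frequencies density matrix), `fs`, `channel_labels`.
#' @export
welch_psd <- function(recording, window_s = 4, overlap = 0.5, fs = NULL) {
  if (inherits(recording, "eeg_recording")) {
    x <- recording$data
    fs <- recording$fs
    labels <- recording$channel_labels
  } else {
    x <- if (is.matrix(recording)) recording else matrix(recording, nrow = 1L)
    if (is.null(fs)) stop("`fs` required for matrix input", call. = FALSE)
    labels <- rownames(x)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(x)))
  }
  nw <- round(window_s * fs)
  if (ncol(x) < nw) {
    stop("recording shorter than one Welch window", call. = FALSE)
  }
  step <- max(1L, round(nw * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / nw)  # periodic Hann
  starts <- seq(1L, ncol(x) - nw + 1L, by = step)
  scale <- fs * sum(w^2)
  nb <- nw %/% 2L + 1L
  power <- matrix(0, nrow(x), nb)
  for (s in starts) {
    seg <- x[, s:(s + nw - 1L), drop = FALSE] * rep(w, each = nrow(x))
    X <- stats::mvfft(t(seg))[1:nb, , drop = FALSE]
    P <- Mod(X)^2 / scale
    P[2:(nb - 1L), ] <- 2 * P[2:(nb - 1L), ]
    power <- power + t(P)
  }
  power <- power / length(starts)
  rownames(power) <- labels
  structure(
    list(freqs = (0:(nb - 1L)) * fs / nw, power = power, fs = fs,
         channel_labels = labels, window_s = window_s, overlap = overlap),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d channels, %g-%g Hz (df = %g Hz)\n",
              nrow(x$power), min(x$freqs), max(x$freqs), x$freqs[2]))
  invisible(x)
}

#' Relative band power
#'
#' Trapezoidal integral of the PSD over `band` divided by the integral over
#' `broadband`, per channel. Both integrals include the band-edge bins. With
#' bands tiling the broadband range the per-channel relative powers sum to
#' one; the ratio is invariant to global signal rescaling.
#'
#' @param spectrum An `eeg_spectrum` from [welch_psd()].
#' @param band `c(low, high)` in Hz.
#' @param broadband Normalizing range, default 0.5-30 Hz.
#' @return Named numeric vector of per-channel relative power in `[0, 1]`.
#' @export
relative_band_power <- function(spectrum, band, broadband = c(0.5, 30)) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  f <- spectrum$freqs
  if (band[1] < broadband[1] - 1e-9 || band[2] > broadband[2] + 1e-9) {
    stop("`band` must lie within `broadband`", call. = FALSE)
  }
  if (broadband[1] < min(f) - 1e-9 || broadband[2] > max(f) + 1e-9) {
    stop("spectrum does not cover the requested range", call. = FALSE)
  }
  band_int <- function(rng) {
    sel <- which(f >= rng[1] - 1e-9 & f <= rng[2] + 1e-9)
    if (length(sel) < 2L) stop("band spans fewer than 2 bins", call. = FALSE)
    apply(spectrum$power[, sel, drop = FALSE], 1L,
          function(p) trapz(f[sel], p))
  }
  band_int(band) / band_int(broadband)
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Decomposes a PSD into an aperiodic 1/f component and Gaussian oscillatory
#' peaks, in the spirit of spectral parameterization ("specparam") models.
#' The procedure in log10-power versus log10-frequency space:
#'
#' 1. robust aperiodic line fit: ordinary least squares, then refit using
#'    only the points whose positive residual is at or below the 2.5th
#'    percentile of the clipped residual distribution (a lower-envelope fit
#'    that ignores oscillatory peaks);
#' 2. iteratively locate the largest residual maximum exceeding
#'    `peak_threshold` residual SDs (and `min_peak_height` absolute log10
#'    units), fit a Gaussian (in linear frequency, log power) by bounded
#'    least squares, subtract, and repeat up to `max_peaks` times;
#' 3. refit the aperiodic line on the peak-stripped spectrum.
#'
#' The exponent convention is chi >= 0 with PSD proportional to `f^-chi`;
#' the log-log slope is `-chi`, so a "flattened" spectrum corresponds to a
#' decrease in chi. Fitting is knee-free, appropriate for the 4-40 Hz range.
#'
#' @param freqs Frequency vector in Hz, or an `eeg_spectrum`.
#' @param power PSD values for one channel (ignored if `freqs` is a
#'   spectrum, in which case `channel` selects the row).
#' @param fit_range Frequency range of the fit in Hz.
#' @param max_peaks Maximum number of Gaussian peaks to extract.
#' @param peak_threshold Detection threshold in residual SDs.
#' @param min_peak_height Minimum peak height in log10 power units.
#' @param peak_width_limits Allowed Gaussian SD range in Hz.
#' @param channel Channel row used when a spectrum object is passed.
#' @return An `aperiodic_fit`: list with `offset`, `exponent`, `peaks`
#'   (data.frame center/height/width), `fit_range`, `r_squared`,
#'   `fit_error` (mean absolute log10 residual).
#' @export
fit_aperiodic <- function(freqs, power = NULL, fit_range = c(4, 40),
                          max_peaks = 6, peak_threshold = 2,
                          min_peak_height = 0.05,
                          peak_width_limits = c(0.5, 12), channel = 1L) {
  if (inherits(freqs, "eeg_spectrum")) {
    power <- freqs$power[channel, ]
    freqs <- freqs$freqs
  }
  sel <- which(freqs >= fit_range[1] & freqs <= fit_range[2] & freqs > 0)
  if (length(sel) < 10L) {
    stop("fewer than 10 frequency bins in fit range", call. = FALSE)
  }
  if (any(power[sel] <= 0)) {
    stop("power must be strictly positive within the fit range",
         call. = FALSE)
  }
  f <- freqs[sel]
  lf <- log10(f)
  lp <- log10(power[sel])

  ap_line <- function(y) {
    cf <- stats::lm.fit(cbind(1, lf), y)$coefficients
    resid <- y - (cf[1] + cf[2] * lf)
    resid[resid < 0] <- 0
    keep <- resid <= stats::quantile(resid, 0.025)
    if (sum(keep) < 3L) keep <- rep(TRUE, length(y))
    stats::lm.fit(cbind(1, lf[keep]), y[keep])$coefficients
  }
  gauss <- function(par) par[2] * exp(-(f - par[1])^2 / (2 * par[3]^2))

  cf <- ap_line(lp)
  resid <- lp - (cf[1] + cf[2] * lf)
  peaks <- list()
  for (i in seq_len(max_peaks)) {
    m <- which.max(resid)
    h <- resid[m]
    if (!(h > peak_threshold * stats::sd(resid)) || h < min_peak_height) break
    half <- h / 2
    ri <- m; while (ri < length(f) && resid[ri] > half) ri <- ri + 1L
    li <- m; while (li > 1L && resid[li] > half) li <- li - 1L
    wguess <- min(max((f[ri] - f[li]) / 2, peak_width_limits[1]),
                  peak_width_limits[2])
    opt <- stats::optim(
      c(f[m], h, wguess),
      function(p) sum((resid - gauss(p))^2),
      method = "L-BFGS-B",
      lower = c(fit_range[1], 0, peak_width_limits[1]),
      upper = c(fit_range[2], 2 * h + 1, peak_width_limits[2])
    )
    peaks[[length(peaks) + 1L]] <- opt$par
    resid <- resid - gauss(opt$par)
  }
  peak_sum <- Reduce(`+`, lapply(peaks, gauss), rep(0, length(f)))
  cf2 <- ap_line(lp - peak_sum)
  fitted <- cf2[1] + cf2[2] * lf + peak_sum
  pk <- if (length(peaks)) {
    data.frame(
      center = vapply(peaks, `[`, 0, 1L),
      height = vapply(peaks, `[`, 0, 2L),
      width = vapply(peaks, `[`, 0, 3L)
    )
  } else {
    data.frame(center = numeric(0), height = numeric(0), width = numeric(0))
  }
  ss_res <- sum((lp - fitted)^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(
    list(
      offset = unname(cf2[1]), exponent = unname(-cf2[2]), peaks = pk,
      fit_range = fit_range,
      r_squared = if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1,
      fit_error = mean(abs(lp - fitted))
    ),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "<aperiodic_fit> exponent = %.3f, offset = %.3f, %d peak(s), R2 = %.3f\n",
    x$exponent, x$offset, nrow(x$peaks), x$r_squared))
  invisible(x)
}

#' Aperiodic parameterization for every channel of a spectrum
#'
#' @param spectrum An `eeg_spectrum`.
#' @param ... Passed to [fit_aperiodic()].
#' @return Tibble with one row per channel: `channel`, `exponent`, `offset`,
#'   `r_squared`, `fit_error`, `n_peaks`, and the strongest peak's
#'   `peak_center` (NA when no peak was found).
#' @export
fit_aperiodic_channels <- function(spectrum, ...) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  rows <- lapply(seq_len(nrow(spectrum$power)), function(ch) {
    ft <- fit_aperiodic(spectrum, channel = ch, ...)
    top <- if (nrow(ft$peaks)) ft$peaks$center[which.max(ft$peaks$height)]
           else NA_real_
    tibble::tibble(
      channel = spectrum$channel_labels[ch],
      exponent = ft$exponent, offset = ft$offset,
      r_squared = ft$r_squared, fit_error = ft$fit_error,
      n_peaks = nrow(ft$peaks), peak_center = top
    )
  })
  dplyr::bind_rows(rows)
}
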