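#' Zero-phase band-pass filtering
#'
#' Filters every channel forward and backward (zero phase) with either a
#' linear-phase FIR design, used for broadband conditioning, or a 3rd-order
#' Bessel IIR design, used to separate the canonical EEG bands. Zero-phase
#' application matters because downstream connectivity is phase-based: any
#' phase distortion introduced here would contaminate the wPLI. The
#' forward-backward pass doubles the effective order and squares the
#' magnitude response, so band edges sit at the half-power point of the
#' combined response.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 <= low < high < fs/2`.
#' @param design `"fir"` (windowed-sinc, order chosen from the lower edge) or
#'   `"bessel3"` (3rd-order Bessel band-pass, maximally flat group delay).
#' @param fir_order Optional FIR order override.
#' @return Filtered recording, same shape and sampling rate.
#' @export
eeg_bandpass <- function(recording, low, high,
                         design = c("bessel3", "fir"), fir_order = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (!(low >= 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 <= low < high < fs/2", call. = FALSE)
  }
  out <- recording
  if (design == "bessel3") {
    flt <- design_bessel3_bandpass(low, high, fs)
    out$data <- filtfilt_refl_mat(flt$b, flt$a, out$data)
    rownames(out$data) <- out$channel_labels
  } else {
    b <- design_fir_bandpass(low, high, fs, order = fir_order)
    out$data <- fir_filtfilt_mat(b, out$data)
    rownames(out$data) <- out$channel_labels
  }
  out
}

# 3rd-order Bessel analog prototype (delay-normalized reverse Bessel
# polynomial s^3 + 6 s^2 + 15 s + 15, rescaled to unit -3 dB frequency),
# transformed to a digital band-pass via the low-pass-to-band-pass mapping
# and the bilinear transform with prewarped edges.
design_bessel3_bandpass <- function(low, high, fs) {
  p <- polyroot(c(15, 15, 6, 1))
  w3db <- 1.7556723    # -3 dB frequency of the delay-normalized prototype
  p <- p / w3db
  g <- Re(prod(-p))    # unity gain at DC
  T <- 2
  Wc <- c(low, high) / (fs / 2)
  W <- (2 / T) * tan(pi * Wc / T)
  zpg <- signal::Zpg(zero = complex(0), pole = p, gain = g)
  bp <- signal::sftrans(zpg, W = W, stop = FALSE)
  dz <- signal::bilinear(bp, T = T)
  arma <- signal::as.Arma(dz)
  list(b = Re(arma$b), a = Re(arma$a))
}

# windowed-sinc FIR band-pass; default order targets a transition width of
# about half the lower edge (capped for very low edges)
design_fir_bandpass <- function(low, high, fs, order = NULL) {
  if (is.null(order)) {
    trans <- max(low / 2, 0.25)
    order <- min(ceiling(3.3 * fs / trans), 4096L)
    order <- order + order %% 2L  # even order -> symmetric type-I FIR
  }
  w <- c(low, high) / (fs / 2)
  if (low <= 0) {
    signal::fir1(order, w[2], type = "low")
  } else {
    signal::fir1(order, w, type = "pass")
  }
}

# direct-form IIR filtering of a time x channel matrix (compiled kernel)
iir_filter <- function(b, a, x) {
  iir_filter_cpp(b / a[1L], a / a[1L], x)
}

# zero-phase IIR application (channels in rows) with odd reflection padding
# at both ends to suppress edge transients
filtfilt_refl_mat <- function(b, a, x) {
  n <- ncol(x)
  npad <- min(n - 1L, 3L * 32L * max(length(a), length(b)))
  pre <- 2 * x[, 1L] - x[, (npad + 1L):2L, drop = FALSE]
  post <- 2 * x[, n] - x[, (n - 1L):(n - npad), drop = FALSE]
  y <- iir_filter(b, a, t(cbind(pre, x, post)))
  y <- iir_filter(b, a, y[nrow(y):1L, , drop = FALSE])
  t(y[(nrow(y) - npad):(nrow(y) - npad - n + 1L), , drop = FALSE])
}

filtfilt_refl <- function(b, a, x) {
  filtfilt_refl_mat(b, a, matrix(x, nrow = 1L))[1L, ]
}

# zero-phase FIR application: forward-backward filtering with odd
# reflection padding, realized in a single FFT pass by multiplying the
# spectrum with |B(f)|^2 (equivalent to convolving with the kernel's
# autocorrelation, which is zero-phase by symmetry)
fir_filtfilt <- function(b, x) {
  fir_filtfilt_mat(b, matrix(x, nrow = 1L))[1L, ]
}

# matrix variant: filters every row (channel) in one batched FFT pass
fir_filtfilt_mat <- function(b, x) {
  n <- ncol(x)
  npad <- min(n - 1L, length(b))
  pre <- 2 * x[, 1L] - x[, (npad + 1L):2L, drop = FALSE]
  post <- 2 * x[, n] - x[, (n - 1L):(n - npad), drop = FALSE]
  xp <- t(cbind(pre, x, post))            # time x ch
  ntot <- nrow(xp)
  nfft <- stats::nextn(ntot + length(b) - 1L, 2L)
  H2 <- Mod(stats::fft(c(b, rep(0, nfft - length(b)))))^2
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - ntot, ncol(xp))))
  y <- Re(stats::mvfft(X * H2, inverse = TRUE)) / nfft
  t(y[(npad + 1L):(npad + n), , drop = FALSE])
}

#' Downsample a recording
#'
#' Decimates with anti-alias filtering. Integer ratios use FIR decimation;
#' non-integer ratios use rational polyphase resampling. Upsampling is not
#' supported.
#'
#' @param recording An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz, `<= fs`.
#' @return Recording at `target_fs`; duration preserved within one sample.
#' @export
eeg_resample <- function(recording, target_fs) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (target_fs > fs) {
    stop("upsampling is not supported (target_fs > fs)", call. = FALSE)
  }
  if (target_fs == fs) return(recording)
  n_in <- ncol(recording$data)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    # integer decimation: zero-phase FIR anti-alias then subsample
    q <- as.integer(round(ratio))
    b <- signal::fir1(max(64L, 16L * q), 0.9 / q, type = "low")
    out <- t(apply(recording$data, 1L, function(x) {
      fir_filtfilt(b, x)[seq(1L, length(x), by = q)]
    }))
  } else {
    fr <- as.integer(c(target_fs, fs) / gcd_int(target_fs, fs))
    out <- t(apply(recording$data, 1L, function(x) {
      signal::resample(x, fr[1L], fr[2L])
    }))
  }
  n_target <- floor(n_in * target_fs / fs)
  out <- out[, seq_len(min(ncol(out), n_target)), drop = FALSE]
  res <- recording
  res$data <- out
  rownames(res$data) <- recording$channel_labels
  res$fs <- target_fs
  res
}

gcd_int <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-timepoint channel mean is zero. Idempotent.
#'
#' @param recording An [eeg_recording()] with at least two channels.
#' @return Average-referenced recording.
#' @export
average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2L) {
    stop("average reference requires at least 2 channels", call. = FALSE)
  }
  out <- recording
  out$data <- sweep(out$data, 2L, colMeans(out$data))
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds; a trailing partial segment is discarded.
#' Non-overlapping epochs keep the connectivity expectation over epochs an
#' average of (approximately) independent estimates.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds.
#' @param band Optional band label carried along for bookkeeping.
#' @return An `eeg_epochs` object: array `[channel, time, epoch]` plus
#'   sampling metadata.
#' @export
epoch_recording <- function(recording, epoch_length_s, band = "broadband") {
  stopifnot(inherits(recording, "eeg_recording"))
  n_len <- round(epoch_length_s * recording$fs)
  n <- ncol(recording$data)
  n_epochs <- n %/% n_len
  if (n_epochs < 1L) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  arr <- array(
    recording$data[, seq_len(n_epochs * n_len), drop = FALSE],
    dim = c(nrow(recording$data), n_len, n_epochs),
    dimnames = list(recording$channel_labels, NULL, NULL)
  )
  structure(
    list(
      data = arr, fs = recording$fs, epoch_length_s = epoch_length_s,
      band = band, channel_labels = recording$channel_labels,
      n_epochs = n_epochs
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%s, %g Hz)\n",
              x$n_epochs, dim(x$data)[1L], dim(x$data)[2L], x$band, x$fs))
  invisible(x)
}

#' Standard preprocessing chain for one recording
#'
#' Applies the fixed pipeline order: broadband zero-phase FIR filter,
#' optional downsampling, average reference, then per-band 3rd-order Bessel
#' filtering. Artifact correction (ICA, visual rejection) is out of scope:
#' synthetic data contains no artifacts, and users with real recordings are
#' expected to supply pre-cleaned data (a `hook` function applied after the
#' average reference is provided for custom cleaning).
#'
#' @param recording An [eeg_recording()].
#' @param broadband Broadband filter edges in Hz.
#' @param resample_hz Optional target rate for downsampling (`NULL` keeps the
#'   native rate).
#' @param bands Named list of band edges; defaults to [eeg_bands()].
#' @param hook Optional function `recording -> recording` applied after
#'   re-referencing (e.g. for externally cleaned data).
#' @return List with elements `broadband` (conditioned recording) and
#'   `bands` (named list of band-filtered recordings), plus a `log`
#'   character vector recording the applied steps in order.
#' @export
preprocess_recording <- function(recording, broadband = c(0.5, 100),
                                 resample_hz = NULL, bands = eeg_bands(),
                                 hook = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  log <- character(0)
  bb_high <- min(broadband[2], recording$fs / 2 * 0.95)
  rec <- eeg_bandpass(recording, broadband[1], bb_high, design = "fir")
  log <- c(log, sprintf("fir_bandpass %.2f-%.2f Hz", broadband[1], bb_high))
  if (!is.null(resample_hz) && resample_hz < rec$fs) {
    rec <- eeg_resample(rec, resample_hz)
    log <- c(log, sprintf("resample -> %g Hz", resample_hz))
  }
  rec <- average_reference(rec)
  log <- c(log, "average_reference")
  if (!is.null(hook)) {
    rec <- hook(rec)
    log <- c(log, "user_hook")
  }
  band_recs <- lapply(names(bands), function(bn) {
    eeg_bandpass(rec, bands[[bn]][1], bands[[bn]][2], design = "bessel3")
  })
  names(band_recs) <- names(bands)
  log <- c(log, sprintf("bessel3_bandpass %s", names(bands)))
  list(broadband = rec, bands = band_recs, log = log)
}
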