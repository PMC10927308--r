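# cache for Slepian tapers keyed by (n, nw, k); computing them means a dense
# symmetric eigendecomposition, a few seconds at 12-s epochs, so memoize
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as eigenvectors of the standard symmetric tridiagonal
#' operator whose eigenvectors are the Slepian sequences. Tapers are
#' orthonormal, ordered by spectral concentration in `[-nw/n, nw/n]`, and
#' sign-fixed so each taper has a non-negative sum (even orders) or positive
#' initial slope. Results are cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1 = 7`).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  if (k < 1L || k > n) stop("`k` must be in [1, n]", call. = FALSE)
  W <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M <- diag(d)
  idx <- cbind(1:(n - 1), 2:n)
  M[idx] <- e
  M[idx[, 2:1]] <- e
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-12) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2L, j] - V[1L, j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  .taper_cache[[key]] <- V
  V
}

#' Multitaper cross-spectra of one epoch
#'
#' DPSS-tapered complex spectra per taper, with cross-spectra
#' `S_xy(f) = X(f) * Conj(Y(f))` formed per taper and frequency bin,
#' restricted to the requested band. Hermitian symmetry
#' `S_xy = Conj(S_yx)` holds exactly by construction and auto-spectra are
#' real and non-negative. Intended for modest channel counts; the study
#' pipeline pools the wPLI expectation without materializing this array via
#' [wpli_matrix()].
#'
#' @param epoch Numeric channels x time matrix.
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz; bins are selected half-open
#'   `[low, high)`.
#' @param n_tapers Number of DPSS tapers (time-bandwidth 4).
#' @return A `cross_spectra` object: complex array
#'   `[taper, bin, channel, channel]`, bin frequencies, band, and the number
#'   of estimates (tapers) it contributes.
#' @export
multitaper_cross_spectra <- function(epoch, fs, band, n_tapers = 7) {
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1L)
  n <- ncol(epoch)
  n_ch <- nrow(epoch)
  if (band[2] > fs / 2) stop("band extends above Nyquist", call. = FALSE)
  if (n < 4 * fs / max(band[1], 1e-6)) {
    stop("epoch shorter than 4 cycles of the band's low edge", call. = FALSE)
  }
  if (n_tapers < 2L) stop("`n_tapers` must be >= 2", call. = FALSE)
  tp <- dpss_tapers(n, k = n_tapers)
  freqs <- (0:(n %/% 2L)) * fs / n
  sel <- which(freqs >= band[1] & freqs < band[2])
  if (!length(sel)) stop("no frequency bins inside band", call. = FALSE)
  est <- array(complex(real = 0), c(n_tapers, length(sel), n_ch, n_ch))
  for (k in seq_len(n_tapers)) {
    X <- stats::mvfft(t(epoch) * tp[, k])[sel, , drop = FALSE]  # bin x ch
    for (b in seq_along(sel)) {
      est[k, b, , ] <- outer(X[b, ], Conj(X[b, ]))
    }
  }
  structure(
    list(est = est, freqs = freqs[sel], band = band,
         n_estimates = n_tapers,
         channel_labels = rownames(epoch)),
    class = "cross_spectra"
  )
}

#' Weighted phase lag index from cross-spectral estimates
#'
#' wPLI per channel pair: the magnitude of the mean imaginary cross-spectrum
#' divided by the mean absolute imaginary cross-spectrum, with the
#' expectation taken over all supplied estimates (tapers, and epochs when a
#' list of per-epoch cross-spectra is given), evaluated per frequency bin and
#' then averaged across the band's bins with equal weight. Pairs whose
#' denominator is (numerically) zero — e.g. identical or purely zero-lag
#' mixed signals — are set to 0 and counted.
#'
#' @param cs A `cross_spectra` object or a list of them (same band/bins).
#' @return A `conn_matrix`: symmetric wPLI matrix in `[0, 1]` with zero
#'   diagonal; attributes carry the band, the number of pooled estimates and
#'   the count of degenerate (zero-denominator) pairs.
#' @export
wpli <- function(cs) {
  if (inherits(cs, "cross_spectra")) cs <- list(cs)
  stopifnot(length(cs) >= 1L)
  dims <- dim(cs[[1L]]$est)
  n_bins <- dims[2L]
  n_ch <- dims[3L]
  sIm <- array(0, c(n_bins, n_ch, n_ch))
  sAbs <- array(0, c(n_bins, n_ch, n_ch))
  n_est <- 0L
  for (one in cs) {
    stopifnot(identical(dim(one$est)[-1L], dims[-1L]))
    im <- Im(one$est)
    sIm <- sIm + colSums(im)          # sum over tapers
    sAbs <- sAbs + colSums(abs(im))
    n_est <- n_est + dim(one$est)[1L]
  }
  if (n_est < 2L) stop("need at least 2 estimates", call. = FALSE)
  finalize_wpli(sIm, sAbs, cs[[1L]]$band, n_epochs = length(cs),
                labels = cs[[1L]]$channel_labels)
}

# ratio per bin with degenerate-denominator handling, then band average
finalize_wpli <- function(sIm, sAbs, band, n_epochs, labels = NULL) {
  tol <- 1e-10 * max(sAbs)
  ratio <- abs(sIm) / pmax(sAbs, .Machine$double.xmin)
  ratio[sAbs <= tol] <- 0
  W <- apply(ratio, c(2L, 3L), mean)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  degenerate <- sum(apply(sAbs <= tol, c(2L, 3L), all)[upper.tri(W)])
  if (!is.null(labels)) dimnames(W) <- list(labels, labels)
  structure(W, class = c("conn_matrix", "matrix"),
            band = band, n_epochs_used = n_epochs,
            degenerate_pairs = degenerate)
}

#' Band wPLI matrix of an epoched recording
#'
#' The workhorse connectivity estimator: streams over epochs and tapers,
#' accumulating the imaginary cross-spectrum sums without materializing the
#' full cross-spectral array. By default the wPLI expectation pools all
#' epoch-by-taper estimates in a single pass (the lower-variance estimator);
#' `per_epoch = TRUE` instead computes a wPLI matrix within each epoch (over
#' tapers) and grand-averages the per-epoch matrices.
#'
#' @param epochs An `eeg_epochs` object from [epoch_recording()].
#' @param band `c(low, high)` in Hz.
#' @param n_tapers Number of DPSS tapers.
#' @param per_epoch Compute per-epoch wPLI then average, instead of pooling
#'   the expectation over epochs and tapers.
#' @return A `conn_matrix` (see [wpli()]).
#' @export
wpli_matrix <- function(epochs, band, n_tapers = 7, per_epoch = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- dim(epochs$data)[2L]
  n_ch <- dim(epochs$data)[1L]
  fs <- epochs$fs
  if (band[2] > fs / 2) stop("band extends above Nyquist", call. = FALSE)
  tp <- dpss_tapers(n, k = n_tapers)
  freqs <- (0:(n %/% 2L)) * fs / n
  sel <- which(freqs >= band[1] & freqs < band[2])
  if (!length(sel)) stop("no frequency bins inside band", call. = FALSE)
  n_bins <- length(sel)

  pooled_im <- array(0, c(n_bins, n_ch, n_ch))
  pooled_abs <- array(0, c(n_bins, n_ch, n_ch))
  mats <- if (per_epoch) vector("list", epochs$n_epochs) else NULL

  A3 <- array(0, c(n_bins, n_ch, n_tapers))
  B3 <- array(0, c(n_bins, n_ch, n_tapers))
  for (e in seq_len(epochs$n_epochs)) {
    seg <- t(epochs$data[, , e])          # time x ch
    for (k in seq_len(n_tapers)) {
      X <- stats::mvfft(seg * tp[, k])[sel, , drop = FALSE]
      A3[, , k] <- Re(X)
      B3[, , k] <- Im(X)
    }
    sums <- wpli_epoch_sums(A3, B3, n_bins, n_ch, n_tapers)
    if (per_epoch) {
      mats[[e]] <- finalize_wpli(sums$im, sums$abs, band, 1L,
                                 epochs$channel_labels)
    } else {
      pooled_im <- pooled_im + sums$im
      pooled_abs <- pooled_abs + sums$abs
    }
  }
  if (per_epoch) {
    out <- grand_average(mats)
    attr(out, "band") <- band
    attr(out, "n_epochs_used") <- epochs$n_epochs
    return(out)
  }
  finalize_wpli(pooled_im, pooled_abs, band, epochs$n_epochs,
                epochs$channel_labels)
}

#' Element-wise mean of connectivity matrices
#'
#' Grand average across epochs (or any collection of same-shape symmetric
#' matrices).
#'
#' @param matrices List of matrices (or a single matrix, returned as is).
#' @return Matrix of the same shape; `conn_matrix` attributes are carried
#'   from the first element.
#' @export
grand_average <- function(matrices) {
  if (is.matrix(matrices)) return(matrices)
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  d <- dim(matrices[[1L]])
  for (m in matrices) {
    if (!identical(dim(m), d)) stop("shape mismatch", call. = FALSE)
  }
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  attributes(out) <- attributes(matrices[[1L]])
  out
}

#' Nodal strength (weighted degree)
#'
#' Row sums of a weighted connectivity matrix: the total connection weight of
#' each channel, computed on the non-thresholded matrix.
#'
#' @param matrix Symmetric weighted matrix with zero diagonal.
#' @param tol Symmetry tolerance relative to the largest entry.
#' @return Named numeric vector of per-channel strengths.
#' @export
nodal_strength <- function(matrix, tol = 1e-8) {
  m <- unclass(matrix)
  if (max(abs(m - t(m))) > tol * max(abs(m), 1e-300)) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  rowSums(m)
}

#' Overall functional connectivity
#'
#' The mean of all off-diagonal entries of a connectivity matrix — the
#' average FC strength of one subject in one band.
#'
#' @param matrix Symmetric connectivity matrix with zero diagonal.
#' @return Scalar mean off-diagonal connectivity.
#' @export
overall_fc <- function(matrix) {
  m <- unclass(matrix)
  n <- nrow(m)
  sum(m[upper.tri(m)]) / (n * (n - 1) / 2)
}
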