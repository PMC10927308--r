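#' Simulate aperiodic (1/f) background activity
#'
#' Generates a zero-mean, unit-variance signal whose population power
#' spectral density is proportional to `f^-exponent`. Synthesis is by
#' frequency-domain shaping: white Gaussian phases with amplitudes
#' `f^(-exponent/2)` (DC bin zero), inverse transformed to the time domain.
#' This gives the exact target exponent in expectation, which makes the
#' generator usable as a parameter-recovery oracle for the spectral fitter.
#'
#' @param n_samples Number of samples (at least `2 * fs`).
#' @param fs Sampling rate in Hz.
#' @param exponent Aperiodic exponent chi >= 0 (PSD proportional to
#'   `f^-chi`); 0 gives white noise.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of length `n_samples`.
#' @export
sim_aperiodic_noise <- function(n_samples, fs, exponent, seed = NULL) {
  if (!is.finite(exponent) || exponent < 0) {
    stop("`exponent` must be finite and non-negative", call. = FALSE)
  }
  if (n_samples < 2 * fs) {
    stop("`n_samples` must cover at least 2 seconds", call. = FALSE)
  }
  with_seed(seed, {
    n <- as.integer(n_samples)
    nf <- n %/% 2L
    f <- (1:nf) * fs / n
    amp <- f^(-exponent / 2)
    ph <- stats::runif(nf, 0, 2 * pi)
    shaped_ifft(amp, ph, n)
  })
}

#' Simulate a narrowband oscillation
#'
#' Band-limited Gaussian noise: white noise shaped in the frequency domain by
#' a Gaussian amplitude window centred at `center` with standard deviation
#' `bandwidth`. The resulting spectral peak is approximately Gaussian in
#' linear frequency, matching the peak model of the spectral
#' parameterization stage. Output is zero-mean with unit variance.
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate in Hz.
#' @param center Peak centre frequency in Hz (below Nyquist).
#' @param bandwidth Gaussian spectral width (SD) in Hz.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
sim_band_oscillation <- function(n_samples, fs, center, bandwidth,
                                 seed = NULL) {
  if (center <= 0 || center >= fs / 2) {
    stop("`center` must lie in (0, fs/2)", call. = FALSE)
  }
  with_seed(seed, {
    n <- as.integer(n_samples)
    nf <- n %/% 2L
    f <- (1:nf) * fs / n
    amp <- exp(-(f - center)^2 / (2 * bandwidth^2))
    ph <- stats::runif(nf, 0, 2 * pi)
    shaped_ifft(amp, ph, n)
  })
}

# fraction of total aperiodic variance falling inside `range`, on the
# discrete frequency grid of an n-sample recording; used to express
# oscillation amplitudes relative to the in-band background regardless of
# recording length (a bare f^-chi process hides most of its variance below
# the analysis range)
aperiodic_band_share <- function(exponent, n, fs, range = c(0.5, 30)) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  a2 <- f^(-exponent)
  sum(a2[f >= range[1] & f <= range[2]]) / sum(a2)
}

# assemble a real signal from one-sided amplitudes and phases
shaped_ifft <- function(amp, ph, n) {
  shaped_ifft_mat(amp, matrix(ph, ncol = 1L), n)[1L, ]
}

# batched variant: one column of phases per independent realization;
# returns realizations in rows, each zero-mean and unit-variance
shaped_ifft_mat <- function(amp, ph, n) {
  nf <- length(amp)
  m <- ncol(ph)
  spec <- matrix(complex(modulus = amp, argument = ph), nf, m)
  full <- matrix(complex(real = 0), n, m)
  full[2:(nf + 1L), ] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L, ] <- complex(real = amp[nf] * sign(cos(ph[nf, ])),
                               imaginary = 0)
    if (nf >= 2L) full[(nf + 2L):n, ] <- Conj(spec[(nf - 1L):1L, ,
                                                   drop = FALSE])
  } else {
    full[(nf + 2L):n, ] <- Conj(spec[nf:1L, , drop = FALSE])
  }
  x <- Re(stats::mvfft(full, inverse = TRUE))
  x <- sweep(x, 2L, colMeans(x))
  t(x) / apply(x, 2L, stats::sd)
}

# batched constant phase rotation (signals in rows, one shared phase)
phase_rotate_mat <- function(x, phase) {
  n <- ncol(x)
  X <- stats::mvfft(t(x))
  nf <- n %/% 2L
  X[2:(nf + 1L), ] <- X[2:(nf + 1L), ] * exp(-1i * phase)
  if (n %% 2L == 0L) {
    if (nf >= 2L) X[(nf + 2L):n, ] <- Conj(X[nf:2L, , drop = FALSE])
  } else {
    X[(nf + 2L):n, ] <- Conj(X[(nf + 1L):2L, , drop = FALSE])
  }
  t(Re(stats::mvfft(X, inverse = TRUE) / n))
}

# batched narrowband realizations (rows) sharing one spectral profile
sim_oscillation_mat <- function(n, fs, center, bandwidth, m) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  amp <- exp(-(f - center)^2 / (2 * bandwidth^2))
  ph <- matrix(stats::runif(nf * m, 0, 2 * pi), nf, m)
  shaped_ifft_mat(amp, ph, n)
}

#' Apply a constant phase rotation to all positive frequencies
#'
#' Rotates the positive-frequency spectrum of a real signal by `phase`
#' radians (negative frequencies by the conjugate), i.e. a
#' frequency-independent phase lag. For a narrowband signal this realizes a
#' pure phase shift of the oscillation without any group delay, which keeps
#' the lag identical across the band.
#'
#' @param x Numeric signal.
#' @param phase Rotation in radians; positive values lag the signal.
#' @return Rotated signal of the same length.
#' @export
phase_rotate <- function(x, phase) {
  n <- length(x)
  X <- stats::fft(x)
  nf <- n %/% 2L
  X[2:(nf + 1L)] <- X[2:(nf + 1L)] * exp(-1i * phase)
  if (n %% 2L == 0L) {
    if (nf >= 2L) X[(nf + 2L):n] <- Conj(X[nf:2L])
  } else {
    X[(nf + 2L):n] <- Conj(X[(nf + 1L):2L])
  }
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Simulate a phase-lagged coupled channel pair
#'
#' Channel 1 is a narrowband source; channel 2 mixes a phase-rotated copy of
#' that source (weight `coupling`) with independent narrowband noise of the
#' same spectral profile (weight `1 - coupling`). With a quarter-cycle lag
#' and strong coupling the pair has a consistently signed imaginary
#' cross-spectrum, the ground truth the wPLI stage is validated against;
#' zero-lag coupling leaves the imaginary cross-spectrum at zero by
#' construction.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @param center_freq Oscillation centre frequency in Hz.
#' @param phase_lag Phase lag in radians; values outside `(-pi, pi]` are
#'   wrapped with a warning.
#' @param coupling Mixing weight in `[0, 1]`.
#' @param bandwidth Spectral width (SD) of the narrowband source in Hz.
#' @param seed Optional integer seed.
#' @return Numeric matrix with 2 rows (channels) and `fs * duration` columns.
#' @export
sim_coupled_pair <- function(fs, duration, center_freq, phase_lag, coupling,
                             bandwidth = 1.5, seed = NULL) {
  if (coupling < 0 || coupling > 1) {
    stop("`coupling` must lie in [0, 1]", call. = FALSE)
  }
  if (center_freq <= 0 || center_freq >= fs / 2) {
    stop("`center_freq` must lie in (0, fs/2)", call. = FALSE)
  }
  if (phase_lag <= -pi || phase_lag > pi) {
    warning("`phase_lag` wrapped into (-pi, pi]")
    phase_lag <- ((phase_lag + pi) %% (2 * pi)) - pi
    if (phase_lag == -pi) phase_lag <- pi
  }
  with_seed(seed, {
    n <- round(fs * duration)
    src <- sim_band_oscillation(n, fs, center_freq, bandwidth)
    noise <- sim_band_oscillation(n, fs, center_freq, bandwidth)
    ch2 <- coupling * phase_rotate(src, phase_lag) + (1 - coupling) * noise
    rbind(src, ch2, deparse.level = 0)
  })
}

#' Default phase-coupling layout for the 64-channel montage
#'
#' One row per coupled channel pair. The layout is deterministic and
#' stylized: delta-band pairs link frontocentral with centroparietal and
#' temporal sensors (carrying the slow-oscillation connectivity effect),
#' theta-band coupling combines short within-region chains with weak
#' spokes radiating from four midline hubs (FCz, Cz, CPz, Pz) whose
#' condition-dependent boost shifts the binarized theta network toward
#' integration, and alpha-band pairs sit over posterior sensors.
#'
#' @param labels Channel labels; defaults to [biosemi64_labels()].
#' @param region_map Channel-to-region map; defaults to
#'   [default_region_map()].
#' @return Tibble with columns `band`, `chan_i`, `chan_j`, `lag`, `strength`.
#' @export
default_coupling_spec <- function(labels = biosemi64_labels(),
                                  region_map = default_region_map(labels)) {
  by_region <- split(names(region_map), region_map)
  fc <- by_region[["frontocentral"]]
  cp <- by_region[["centroparietal"]]
  tp <- by_region[["temporal"]]
  fr <- by_region[["frontal"]]
  op <- by_region[["occipitoparietal"]]

  chain <- function(ch) {
    if (length(ch) < 2L) return(NULL)
    k <- seq(1L, length(ch) - 1L, by = 2L)
    cbind(ch[k], ch[k + 1L])
  }
  rows <- list()
  add <- function(band, prs, lag, strength) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      band = band, chan_i = prs[, 1L], chan_j = prs[, 2L],
      lag = lag, strength = strength
    )
  }
  # delta: frontocentral <-> centroparietal / temporal long pairs
  nd <- min(length(fc), length(cp))
  add("delta", cbind(fc[seq_len(nd)], cp[seq_len(nd)]), pi / 2, 0.50)
  add("delta", cbind(tp, fc[seq_along(tp)]), pi / 2, 0.50)
  # theta: local chains plus weak hub spokes
  add("theta", rbind(chain(fr), chain(op)), pi / 2, 0.50)
  hubs <- c("FCz", "Cz", "CPz", "Pz")
  hubs <- hubs[hubs %in% labels]
  others <- setdiff(labels, hubs)
  spokes <- do.call(rbind, lapply(seq_along(hubs), function(h) {
    idx <- seq(h, length(others), by = length(hubs))[1:12]
    cbind(rep(hubs[h], 12L), others[idx])
  }))
  add("theta", spokes, pi / 2, 0.22)
  # alpha: posterior pairs
  add("alpha", rbind(chain(op), chain(cp[1:8])), pi / 2, 0.40)
  dplyr::bind_rows(rows)
}

#' Configuration for a synthetic two-condition EEG study
#'
#' Defines the generative model for a paired design in which every subject is
#' recorded in two conditions (`"sea"` and `"altitude"`). Each channel is a
#' sum of aperiodic 1/f background, band-limited oscillations, and shared
#' phase-lagged narrowband sources injected into coupled channel pairs. The
#' aperiodic exponent declines linearly with age and, at altitude, shifts by
#' `exponent_delta`; altitude also rescales delta/alpha oscillatory power and
#' multiplies delta/theta coupling strengths.
#'
#' Defaults are desk-scale study conditions: 16 subjects, 64 channels,
#' 300 s at 256 Hz, ages uniform in 19-45 years, baseline exponent 1.5 at
#' the youngest age declining by 0.01 per year, and altitude effects
#' (exponent -0.2, alpha power x0.7, delta power x1.4, delta coupling x1.6,
#' theta coupling x2.5) chosen to mirror the qualitative within-subject
#' effects of acute high-altitude hypoxia at effect sizes recoverable from
#' recordings of this length.
#'
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate in Hz.
#' @param duration Recording duration per condition in seconds.
#' @param n_channels Number of channels (64 uses the standard montage).
#' @param age_range Two-element numeric, min and max age in years.
#' @param exponent_base Aperiodic exponent at the youngest age.
#' @param exponent_age_slope Decline in exponent per year of age (positive
#'   values mean older subjects have flatter spectra).
#' @param exponent_sd Between-subject SD of the exponent.
#' @param condition_effects Named list with elements `exponent_delta`,
#'   `alpha_power_scale`, `delta_power_scale`, `theta_coupling_boost`,
#'   `delta_coupling_boost`.
#' @param band_oscillations Tibble with columns `band`, `center`, `bandwidth`
#'   (Hz) and `amplitude` (RMS relative to the aperiodic background, whose
#'   0.5-30 Hz RMS is normalized to 1).
#' @param coupling_spec Tibble of coupled pairs as produced by
#'   [default_coupling_spec()], or `NULL` for no coupling.
#' @param noise_sd RMS of additional white sensor noise.
#' @param seed Integer master seed governing all randomness.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 16,
                         fs = 256,
                         duration = 300,
                         n_channels = 64,
                         age_range = c(19, 45),
                         exponent_base = 1.5,
                         exponent_age_slope = 0.01,
                         exponent_sd = 0.05,
                         condition_effects = list(
                           exponent_delta = -0.2,
                           alpha_power_scale = 0.7,
                           delta_power_scale = 1.4,
                           theta_coupling_boost = 2.5,
                           delta_coupling_boost = 1.6
                         ),
                         band_oscillations = tibble::tibble(
                           band = c("delta", "theta", "alpha", "beta"),
                           center = c(2, 6, 10, 20),
                           bandwidth = c(0.6, 1.0, 1.2, 2.5),
                           amplitude = c(0.35, 0.30, 0.50, 0.20)
                         ),
                         coupling_spec = NULL,
                         noise_sd = 0.05,
                         seed = 1L) {
  if (n_channels == 64) {
    labels <- biosemi64_labels()
  } else {
    labels <- sprintf("ch%02d", seq_len(n_channels))
  }
  region_map <- default_region_map(labels)
  if (is.null(coupling_spec) && n_channels == 64) {
    coupling_spec <- default_coupling_spec(labels, region_map)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
    n_channels = as.integer(n_channels), age_range = age_range,
    exponent_base = exponent_base, exponent_age_slope = exponent_age_slope,
    exponent_sd = exponent_sd, condition_effects = condition_effects,
    band_oscillations = band_oscillations, coupling_spec = coupling_spec,
    noise_sd = noise_sd, seed = as.integer(seed),
    channel_labels = labels, region_map = region_map
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$fs <= 2 * max(cfg$band_oscillations$center)) {
    stop("`fs` must exceed twice the highest oscillation centre frequency",
         call. = FALSE)
  }
  if (cfg$exponent_base <= 0) stop("`exponent_base` must be > 0", call. = FALSE)
  if (diff(cfg$age_range) < 0 || cfg$age_range[1] < 18 ||
      cfg$age_range[2] > 90) {
    stop("`age_range` must be an increasing pair within a plausible adult span",
         call. = FALSE)
  }
  need <- c("exponent_delta", "alpha_power_scale", "delta_power_scale",
            "theta_coupling_boost", "delta_coupling_boost")
  missing_eff <- setdiff(need, names(cfg$condition_effects))
  if (length(missing_eff)) {
    stop("condition_effects missing: ", paste(missing_eff, collapse = ", "),
         call. = FALSE)
  }
  cs <- cfg$coupling_spec
  if (!is.null(cs)) {
    if (any(cs$strength < 0 | cs$strength > 1)) {
      stop("coupling strengths must lie in [0, 1]", call. = FALSE)
    }
    if (any(cs$lag <= -pi | cs$lag > pi)) {
      stop("coupling lags must lie in (-pi, pi]", call. = FALSE)
    }
    bad <- setdiff(unique(c(cs$chan_i, cs$chan_j)), cfg$channel_labels)
    if (length(bad)) {
      stop("coupling_spec refers to unknown channels: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

# Per-subject design: ages and subject-level exponent jitter, all derived
# from the master seed so the plan is identical no matter which recordings
# are generated or in which order.
study_plan <- function(config) {
  with_seed(config$seed, {
    ages <- stats::runif(config$n_subjects, config$age_range[1],
                         config$age_range[2])
    jit <- stats::rnorm(config$n_subjects, 0, config$exponent_sd)
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
      age = ages,
      exponent_jitter = jit
    )
  })
}

# condition-adjusted coupling table (strengths boosted, capped at 0.95)
condition_coupling <- function(config, condition) {
  cs <- config$coupling_spec
  if (is.null(cs) || nrow(cs) == 0L) return(cs)
  if (condition == "altitude") {
    eff <- config$condition_effects
    cs$strength <- cs$strength * ifelse(
      cs$band == "theta", eff$theta_coupling_boost,
      ifelse(cs$band == "delta", eff$delta_coupling_boost, 1)
    )
  }
  cs$strength <- pmin(cs$strength, 0.95)
  cs
}

#' Simulate one subject-condition recording
#'
#' Generates a single multichannel recording under the model of
#' [synth_config()]. Deterministic given `(config, subject_index,
#' condition)`: all randomness is derived from the config's master seed.
#'
#' @param config A `synth_config`.
#' @param subject_index Subject number (1-based row of the study plan).
#' @param condition `"sea"` or `"altitude"`.
#' @param plan Optional precomputed study plan (internal reuse).
#' @return An [eeg_recording()] with the subject's id, condition and the
#'   montage's region map.
#' @export
simulate_recording <- function(config, subject_index,
                               condition = c("sea", "altitude"),
                               plan = NULL) {
  condition <- match.arg(condition)
  if (is.null(plan)) plan <- study_plan(config)
  stopifnot(subject_index >= 1, subject_index <= nrow(plan))
  sub <- plan[subject_index, ]
  eff <- config$condition_effects
  exponent <- config$exponent_base -
    config$exponent_age_slope * (sub$age - config$age_range[1]) +
    sub$exponent_jitter +
    if (condition == "altitude") eff$exponent_delta else 0
  exponent <- max(exponent, 0.05)

  n <- round(config$fs * config$duration)
  n_ch <- config$n_channels
  labels <- config$channel_labels
  osc <- config$band_oscillations
  amp <- stats::setNames(osc$amplitude, osc$band)
  if (condition == "altitude") {
    amp["alpha"] <- amp["alpha"] * eff$alpha_power_scale
    amp["delta"] <- amp["delta"] * eff$delta_power_scale
  }
  cs <- condition_coupling(config, condition)

  rec_seed <- child_seed(config$seed, subject_index,
                         if (condition == "altitude") 2L else 1L)
  with_seed(rec_seed, {
    # per-channel residual coupling weight per band: independent oscillation
    # is scaled by (1 - total shared strength) so band power stays comparable
    shared_w <- matrix(0, n_ch, nrow(osc),
                       dimnames = list(labels, osc$band))
    if (!is.null(cs) && nrow(cs)) {
      for (r in seq_len(nrow(cs))) {
        shared_w[cs$chan_i[r], cs$band[r]] <-
          shared_w[cs$chan_i[r], cs$band[r]] + cs$strength[r]
        shared_w[cs$chan_j[r], cs$band[r]] <-
          shared_w[cs$chan_j[r], cs$band[r]] + cs$strength[r]
      }
      shared_w <- pmin(shared_w, 0.95)
    }
    # oscillation amplitudes are defined relative to the 0.5-30 Hz RMS of
    # the aperiodic background; all per-channel realizations of one
    # component are synthesized in a single batched inverse FFT
    ap_scale <- 1 / sqrt(aperiodic_band_share(exponent, n, config$fs))
    nf <- n %/% 2L
    fgrid <- (1:nf) * config$fs / n
    ap_amp <- fgrid^(-exponent / 2)
    data <- ap_scale *
      shaped_ifft_mat(ap_amp, matrix(stats::runif(nf * n_ch, 0, 2 * pi),
                                     nf, n_ch), n)
    dimnames(data) <- list(labels, NULL)
    for (b in seq_len(nrow(osc))) {
      a_ch <- amp[[osc$band[b]]] * (1 - shared_w[, osc$band[b]])
      data <- data + a_ch * sim_oscillation_mat(n, config$fs, osc$center[b],
                                                osc$bandwidth[b], n_ch)
    }
    # inject shared phase-lagged sources per coupled pair; amplitudes are
    # scaled to the band's total background RMS (in-band aperiodic power
    # plus the band oscillation), so `strength` is a band signal-to-noise
    # fraction rather than a fraction of the oscillation alone
    if (!is.null(cs) && nrow(cs)) {
      bands <- eeg_bands()
      a2 <- fgrid^(-exponent)
      in_bb <- fgrid >= 0.5 & fgrid <= 30
      for (b in unique(cs$band)) {
        rows <- which(cs$band == b)
        prm <- osc[osc$band == b, ]
        edges <- bands[[b]]
        p_ap <- sum(a2[fgrid >= edges[1] & fgrid < edges[2]]) / sum(a2[in_bb])
        bg_rms <- sqrt(p_ap + amp[[b]]^2)
        src <- sim_oscillation_mat(n, config$fs, prm$center, prm$bandwidth,
                                   length(rows))
        rot <- matrix(0, length(rows), n)
        for (lg in unique(cs$lag[rows])) {
          sel_l <- which(cs$lag[rows] == lg)
          rot[sel_l, ] <- phase_rotate_mat(src[sel_l, , drop = FALSE], lg)
        }
        for (ri in seq_along(rows)) {
          r <- rows[ri]
          a <- bg_rms * cs$strength[r]
          data[cs$chan_i[r], ] <- data[cs$chan_i[r], ] + a * src[ri, ]
          data[cs$chan_j[r], ] <- data[cs$chan_j[r], ] + a * rot[ri, ]
        }
      }
    }
    if (config$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(n_ch * n, 0, config$noise_sd),
                            n_ch, n)
    }
    rec <- eeg_recording(data, config$fs, labels, config$region_map,
                         subject_id = sub$subject_id, condition = condition)
    attr(rec, "true_exponent") <- exponent
    rec
  })
}

#' Simulate a complete two-condition study
#'
#' Materializes every subject-condition recording together with the ground
#' truth used by parameter-recovery tests. For the full 64-channel,
#' 300-second default this holds roughly 1.3 GB in memory; the study
#' pipeline instead streams recordings one at a time via
#' [simulate_recording()].
#'
#' @param config A `synth_config`.
#' @return List with `recordings` (list keyed `"<subject>_<condition>"`),
#'   `ground_truth` (tibble with one row per recording: subject, condition,
#'   age, true exponent, band amplitudes) , `subjects` (tibble with
#'   subject_id, age_years, condition rows) and `coupling` (the per-condition
#'   coupling tables).
#' @export
simulate_study <- function(config) {
  plan <- study_plan(config)
  conditions <- c("sea", "altitude")
  recordings <- list()
  gt <- list()
  for (s in seq_len(config$n_subjects)) {
    for (cond in conditions) {
      rec <- simulate_recording(config, s, cond, plan = plan)
      key <- paste(plan$subject_id[s], cond, sep = "_")
      recordings[[key]] <- rec
      eff <- config$condition_effects
      amp <- stats::setNames(config$band_oscillations$amplitude,
                             config$band_oscillations$band)
      if (cond == "altitude") {
        amp["alpha"] <- amp["alpha"] * eff$alpha_power_scale
        amp["delta"] <- amp["delta"] * eff$delta_power_scale
      }
      gt[[key]] <- tibble::tibble(
        subject_id = plan$subject_id[s], condition = cond,
        age = plan$age[s],
        exponent = attr(rec, "true_exponent"),
        band = names(amp), amplitude = unname(amp)
      )
    }
  }
  subjects <- tidyr::expand_grid(
    plan[, c("subject_id", "age")], condition = conditions
  )
  names(subjects)[names(subjects) == "age"] <- "age_years"
  list(
    recordings = recordings,
    ground_truth = dplyr::bind_rows(gt),
    subjects = subjects,
    coupling = list(sea = condition_coupling(config, "sea"),
                    altitude = condition_coupling(config, "altitude"))
  )
}
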