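#' Read an EDF or BDF recording
#'
#' Minimal reader for continuous European Data Format files: 16-bit EDF and
#' 24-bit Biosemi BDF, uniform sampling rate across channels, no
#' annotations. Digital values are mapped to physical units with the
#' per-channel gain and offset from the header.
#'
#' @param path Path to an `.edf` or `.bdf` file.
#' @param subject_id,condition Optional metadata attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NA, condition = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  bdf <- magic[1L] == as.raw(255L)
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  invisible(rd_str(80L + 80L + 8L + 8L))       # patient/recording/date/time
  invisible(rd_str(8L))                         # header length
  invisible(rd_str(44L))                        # reserved
  n_rec <- as.integer(rd_str(8L))
  rec_dur <- as.numeric(rd_str(8L))
  ns <- as.integer(rd_str(4L))
  labels <- vapply(seq_len(ns), function(i) rd_str(16L), "")
  invisible(rd_str(80L * ns))                   # transducer
  invisible(rd_str(8L * ns))                    # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8L), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8L), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8L), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8L), ""))
  invisible(rd_str(80L * ns))                   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd_str(8L), ""))
  invisible(rd_str(32L * ns))                   # reserved
  if (length(unique(spr)) != 1L) {
    stop("channels with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      if (bdf) {
        b <- readBin(con, "raw", 3L * spr[ch])
        m <- matrix(as.integer(b), nrow = 3L)
        v <- m[1L, ] + m[2L, ] * 256L + m[3L, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      }
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      data[ch, cols] <- gain[ch] * v + offset[ch]
    }
  }
  eeg_recording(data, fs, labels, subject_id = subject_id,
                condition = condition)
}

#' Write a recording to EDF
#'
#' 16-bit EDF export with one data record per second (requires an integer
#' sampling rate). Each channel is scaled to its own physical range, so
#' round-trip quantization error is bounded by `range/2^16` per channel.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  data <- recording$data
  ns <- nrow(data)
  n_rec <- ncol(data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one second", call. = FALSE)
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  pad <- pmax_ == pmin_
  pmax_[pad] <- pmin_[pad] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (pmax_ - pmin_) / (dmax - dmin)

  fixed <- function(x, n) {
    s <- formatC(as.character(x), width = -n)
    substr(paste0(s, strrep(" ", n)), 1L, n)
  }
  num8 <- function(x) fixed(formatC(x, format = "g", digits = 7), 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_len <- 256L + 256L * ns
  writeChar(paste0(
    fixed("0", 8L), fixed("X X X X", 80L), fixed("synthetic EEG", 80L),
    fixed("01.01.00", 8L), fixed("00.00.00", 8L), fixed(hdr_len, 8L),
    fixed("", 44L), fixed(n_rec, 8L), fixed(1, 8L), fixed(ns, 4L),
    paste(vapply(recording$channel_labels, fixed, "", n = 16L),
          collapse = ""),
    strrep(fixed("", 80L), ns),            # transducer
    strrep(fixed("uV", 8L), ns),
    paste(vapply(pmin_, num8, ""), collapse = ""),
    paste(vapply(pmax_, num8, ""), collapse = ""),
    paste(rep(fixed(dmin, 8L), ns), collapse = ""),
    paste(rep(fixed(dmax, 8L), ns), collapse = ""),
    strrep(fixed("", 80L), ns),            # prefiltering
    paste(rep(fixed(fs, 8L), ns), collapse = ""),
    strrep(fixed("", 32L), ns)
  ), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - pmin_[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

# real-data mode: a directory with subjects.csv (subject_id, age_years,
# condition) and one file <subject_id>_<condition>.edf (or .bdf) each
read_edf_study <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "subjects.csv"),
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "condition")
  if (!all(need %in% names(tab))) {
    stop("subjects.csv must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  plan <- dplyr::distinct(tibble::as_tibble(tab[, c("subject_id",
                                                    "age_years")]))
  names(plan) <- c("subject_id", "age")
  reader <- function(subject_id, condition) {
    base <- file.path(dir, paste0(subject_id, "_", condition))
    path <- if (file.exists(paste0(base, ".edf"))) paste0(base, ".edf")
            else paste0(base, ".bdf")
    read_edf(path, subject_id = subject_id, condition = condition)
  }
  list(plan = plan, reader = reader)
}
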