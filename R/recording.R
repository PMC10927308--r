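#' Construct a multichannel EEG recording
#'
#' The basic data container: a channel-by-time numeric matrix with its
#' sampling rate, channel labels, an optional channel-to-region map, and
#' subject/condition metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per row of
#'   `data`. Defaults to `ch01`, `ch02`, ...
#' @param region_map Named character vector mapping channel labels to scalp
#'   regions; defaults to [default_region_map()] restricted to
#'   `channel_labels`.
#' @param subject_id Subject identifier (any scalar).
#' @param condition Condition label, conventionally `"sea"` or `"altitude"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, region_map = NULL,
                          subject_id = NA, condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channel x time matrix", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate in Hz", call. = FALSE)
  }
  n_ch <- nrow(data)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(n_ch))
  }
  if (length(channel_labels) != n_ch || anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be unique, one per channel", call. = FALSE)
  }
  if (is.null(region_map)) {
    region_map <- default_region_map(channel_labels)
  }
  if (!all(channel_labels %in% names(region_map))) {
    stop("`region_map` must cover every channel label", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      fs = fs,
      channel_labels = channel_labels,
      region_map = region_map[channel_labels],
      subject_id = subject_id,
      condition = condition
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
    nrow(x$data), ncol(x$data), dur, x$fs
  ))
  if (!is.na(x$subject_id) || !is.na(x$condition)) {
    cat(sprintf("  subject: %s  condition: %s\n",
                as.character(x$subject_id), as.character(x$condition)))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  ncol(recording$data) / recording$fs
}
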