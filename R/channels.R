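#' Standard 64-channel montage labels
#'
#' Returns the 64 extended 10-20 electrode labels of the Biosemi ActiveTwo
#' 64-channel cap (A1-A32/B1-B32 positions expressed as 10-10 names), the
#' layout used for high-density resting-state recordings.
#'
#' @return Character vector of 64 unique channel labels.
#' @export
biosemi64_labels <- function() {
  c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7",
    "FC5", "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7",
    "CP5", "CP3", "CP1", "P1", "P3", "P5", "P7", "P9",
    "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz",
    "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4", "CP2",
    "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
}

#' Default scalp-region partition of the 64-channel montage
#'
#' Assigns every montage channel to one of five topographic regions used for
#' regional summaries: frontal, frontocentral, centroparietal, temporal and
#' occipitoparietal. Channel-to-region membership for head-map statistics is
#' a package convention (montage vendors do not define one); it can be
#' overridden wherever a `region_map` argument is accepted.
#'
#' @param labels Channel labels to map. Defaults to [biosemi64_labels()].
#' @return Named character vector: `names` are channel labels, values are
#'   region names.
#' @export
default_region_map <- function(labels = biosemi64_labels()) {
  regions <- list(
    frontal = c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
                "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    frontocentral = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                      "FC6", "FT8", "C1", "C3", "C5", "Cz", "C2", "C4", "C6"),
    temporal = c("T7", "T8", "TP7", "TP8", "P9", "P10"),
    centroparietal = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                       "P1", "P3", "P5", "Pz", "P2", "P4", "P6"),
    occipitoparietal = c("P7", "P8", "PO7", "PO3", "POz", "PO4", "PO8",
                         "O1", "Oz", "O2", "Iz")
  )
  map <- rep(NA_character_, length(labels))
  names(map) <- labels
  for (rg in names(regions)) {
    hit <- labels %in% regions[[rg]]
    map[hit] <- rg
  }
  if (anyNA(map)) {
    # channels outside the canonical montage fall back to a generic region
    map[is.na(map)] <- "other"
  }
  map
}

#' Region names used by the default partition
#' @return Character vector of the five region names.
#' @export
eeg_regions <- function() {
  c("frontal", "frontocentral", "centroparietal", "temporal",
    "occipitoparietal")
}

#' Canonical EEG frequency bands
#'
#' Band edges follow the common clinical convention: delta 0.5-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz. Bands are half-open `[low, high)` so that the
#' shared boundary frequencies belong to the lower band's upper edge exactly
#' once and the four bands tile the 0.5-30 Hz broadband range.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 13),
    beta  = c(13, 30)
  )
}
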