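#' Configuration for a full study run
#'
#' Bundles every stage parameter of the end-to-end analysis. All parameters
#' are validated up front so a misconfigured run fails before any
#' computation starts.
#'
#' @param synth A [synth_config()] (synthetic mode), or `NULL` when reading
#'   real data from `edf_dir`.
#' @param edf_dir Directory of EDF/BDF files plus a `subjects.csv` table
#'   (columns subject_id, age_years, condition) for real-data mode.
#' @param bands Named list of band edges.
#' @param broadband Broadband conditioning filter edges in Hz.
#' @param power_range Normalizing range for relative power in Hz.
#' @param fit_range Aperiodic fit range in Hz.
#' @param epoch_length_s Connectivity epoch length in seconds.
#' @param n_tapers DPSS tapers per epoch.
#' @param thresholds Proportional-threshold sweep.
#' @param resample_hz Optional downsampling target.
#' @param n_perm Permutations per statistical test.
#' @param seed Master seed for generation and inference.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            edf_dir = NULL,
                            bands = eeg_bands(),
                            broadband = c(0.5, 100),
                            power_range = c(0.5, 30),
                            fit_range = c(4, 40),
                            epoch_length_s = 12,
                            n_tapers = 7,
                            thresholds = seq(0.05, 0.40, by = 0.01),
                            resample_hz = NULL,
                            n_perm = 10000,
                            seed = 1L) {
  if (is.null(synth) && is.null(edf_dir)) {
    stop("either `synth` or `edf_dir` must be given", call. = FALSE)
  }
  stopifnot(epoch_length_s > 0, n_perm >= 100, length(thresholds) >= 2)
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  fs <- if (!is.null(synth)) synth$fs else NA_real_
  if (!is.null(synth)) {
    hi <- max(vapply(bands, `[`, 0, 2L))
    if (hi >= fs / 2) stop("band edges incompatible with fs", call. = FALSE)
    if (synth$duration < epoch_length_s) {
      stop("recordings shorter than one epoch", call. = FALSE)
    }
  }
  structure(
    list(synth = synth, edf_dir = edf_dir, bands = bands,
         broadband = broadband, power_range = power_range,
         fit_range = fit_range, epoch_length_s = epoch_length_s,
         n_tapers = n_tapers, thresholds = thresholds,
         resample_hz = resample_hz, n_perm = n_perm,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# region means of a named per-channel vector, as scope -> value rows
region_summaries <- function(values, region_map) {
  regions <- split(names(region_map), region_map)
  out <- c(global = mean(values))
  for (rg in names(regions)) {
    out[paste0("region:", rg)] <- mean(values[regions[[rg]]])
  }
  out
}

# feature extraction for one preprocessed recording -> study-table rows
extract_features <- function(pp, config, subject_id, age, condition) {
  rec <- pp$broadband
  region_map <- rec$region_map
  rows <- list()
  add <- function(metric, band, scoped_values) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      subject_id = subject_id, age = age, condition = condition,
      band = band, scope = names(scoped_values), metric = metric,
      value = unname(scoped_values)
    )
  }

  spec <- welch_psd(rec)
  for (bn in names(config$bands)) {
    rp <- relative_band_power(spec, config$bands[[bn]], config$power_range)
    add("relative_power", bn, region_summaries(rp, region_map))
  }
  fits <- fit_aperiodic_channels(spec, fit_range = config$fit_range)
  expo <- stats::setNames(fits$exponent, fits$channel)
  add("exponent", "broadband", region_summaries(expo, region_map))

  for (bn in names(config$bands)) {
    ep <- epoch_recording(pp$bands[[bn]], config$epoch_length_s, band = bn)
    W <- wpli_matrix(ep, config$bands[[bn]], n_tapers = config$n_tapers)
    add("overall_fc", bn, c(global = overall_fc(W)))
    add("strength", bn, region_summaries(nodal_strength(W), region_map))
    sw <- threshold_sweep(W, config$thresholds)
    auc <- sweep_auc(sw)
    add("global_efficiency_auc", bn,
        c(global = auc$global$global_efficiency))
    add("transitivity_auc", bn, c(global = auc$global$transitivity))
    eff_reg <- region_summaries(auc$nodal$nodal_efficiency, region_map)
    add("nodal_efficiency_auc", bn,
        eff_reg[names(eff_reg) != "global"])
    clu_reg <- region_summaries(auc$nodal$nodal_clustering, region_map)
    add("nodal_clustering_auc", bn,
        clu_reg[names(clu_reg) != "global"])
  }
  dplyr::bind_rows(rows)
}

#' Run the complete study analysis
#'
#' Orchestrates the full pipeline: data generation (or EDF ingestion),
#' preprocessing, spectral and aperiodic parameterization, band-wise wPLI
#' connectivity, threshold-swept graph topology, and the statistics layer.
#' Recordings are processed one at a time, so memory stays flat regardless
#' of study size. Output tables:
#'
#' * `study_table` — long-format per-subject metric values;
#' * `contrasts` — permutation/FDR condition contrasts;
#' * `contrasts_age_adjusted` — the same after residualizing age;
#' * `age_correlations` — Pearson age correlations of the four headline
#'   metrics (alpha relative power, broadband exponent, delta overall FC,
#'   theta global-efficiency AUC), pooled over conditions;
#' * `manifest` — machine-readable record of every parameter and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a JSON manifest.
#' @param progress Print per-recording progress.
#' @return List with the elements above (class `study_results`).
#' @export
run_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$synth)) {
    input <- read_edf_study(config$edf_dir)
    plan <- input$plan
  } else {
    plan <- study_plan(config$synth)
  }
  conditions <- c("sea", "altitude")
  feature_rows <- vector("list", nrow(plan) * 2L)
  i <- 0L
  for (s in seq_len(nrow(plan))) {
    for (cond in conditions) {
      rec <- if (is.null(config$synth)) {
        input$reader(plan$subject_id[s], cond)
      } else {
        simulate_recording(config$synth, s, cond, plan = plan)
      }
      pp <- preprocess_recording(rec, broadband = config$broadband,
                                 resample_hz = config$resample_hz,
                                 bands = config$bands)
      i <- i + 1L
      feature_rows[[i]] <- extract_features(pp, config, plan$subject_id[s],
                                            plan$age[s], cond)
      if (progress) {
        message(sprintf("processed %s / %s", plan$subject_id[s], cond))
      }
    }
  }
  study_table <- dplyr::bind_rows(feature_rows)

  contrasts <- run_contrasts(study_table, n_perm = config$n_perm,
                             seed = child_seed(config$seed, 1L))
  contrasts_age <- run_contrasts(study_table, n_perm = config$n_perm,
                                 seed = child_seed(config$seed, 2L),
                                 residualize_age = TRUE)

  headline <- list(
    c(metric = "relative_power", band = "alpha"),
    c(metric = "exponent", band = "broadband"),
    c(metric = "overall_fc", band = "delta"),
    c(metric = "global_efficiency_auc", band = "theta")
  )
  age_rows <- lapply(headline, function(h) {
    sub <- study_table[study_table$metric == h[["metric"]] &
                         study_table$band == h[["band"]] &
                         study_table$scope == "global", ]
    ac <- age_correlation(sub$value, sub$age)
    tibble::tibble(metric = h[["metric"]], band = h[["band"]],
                   r = ac$r, p_value = ac$p_value, n = ac$n)
  })
  age_correlations <- dplyr::bind_rows(age_rows)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hypoxeeg")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_perm = config$n_perm,
    epoch_length_s = config$epoch_length_s,
    n_tapers = config$n_tapers,
    thresholds = range(config$thresholds),
    bands = config$bands,
    fit_range = config$fit_range,
    power_range = config$power_range,
    mode = if (is.null(config$synth)) "edf_dir" else "synthetic",
    synth = if (!is.null(config$synth)) {
      config$synth[c("n_subjects", "fs", "duration", "n_channels",
                     "age_range", "exponent_base", "exponent_age_slope",
                     "exponent_sd", "condition_effects", "noise_sd", "seed")]
    }
  )

  results <- structure(
    list(study_table = study_table, contrasts = contrasts,
         contrasts_age_adjusted = contrasts_age,
         age_correlations = age_correlations, manifest = manifest),
    class = "study_results"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(study_table, file.path(out_dir, "study_table.csv"),
                     row.names = FALSE)
    utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(contrasts_age,
                     file.path(out_dir, "contrasts_age_adjusted.csv"),
                     row.names = FALSE)
    utils::write.csv(age_correlations,
                     file.path(out_dir, "age_correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' @export
print.study_results <- function(x, ...) {
  ns <- length(unique(x$study_table$subject_id))
  cat(sprintf("<study_results> %d subjects, %d metric cells, %d contrasts\n",
              ns, nrow(dplyr::distinct(x$study_table, .data$metric,
                                       .data$band, .data$scope)),
              nrow(x$contrasts)))
  invisible(x)
}
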