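#' Paired (sign-flip) permutation test
#'
#' Nonparametric test of a within-subject condition difference. The observed
#' statistic is the mean paired difference (altitude minus sea level, by
#' convention). The null distribution is built by randomly exchanging each
#' subject's two condition labels — equivalently, flipping the sign of each
#' paired difference — either over `n_perm` random sign patterns or, with
#' `exact = TRUE`, over all `2^n` patterns. Two-sided p-values use the
#' add-one rule `(1 + #{|null| >= |obs|}) / (1 + n_perm)` for the Monte
#' Carlo variant (never exactly zero), and the exact proportion
#' `#{|null| >= |obs|} / 2^n` (which includes the identity pattern, hence is
#' positive) for the exhaustive variant. An unpaired variant that reshuffles
#' all 2n values across the two groups is available for sensitivity
#' analysis.
#'
#' @param sea Per-subject values in the reference condition.
#' @param altitude Per-subject values in the test condition, paired by
#'   position.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Optional integer seed for reproducible surrogates.
#' @param exact Enumerate all sign patterns (requires `n <= 20`).
#' @param scheme `"paired"` (sign flips) or `"unpaired"` (full reshuffle).
#' @return A `perm_test` list: `observed_diff`, `p_value`, `cohens_d`,
#'   `n_subjects`, `n_permutations`, `scheme`, `seed`.
#' @export
permutation_test <- function(sea, altitude, n_perm = 10000, seed = NULL,
                             exact = FALSE,
                             scheme = c("paired", "unpaired")) {
  scheme <- match.arg(scheme)
  if (length(sea) != length(altitude)) {
    stop("conditions must have the same subjects (paired design)",
         call. = FALSE)
  }
  if (anyNA(sea) || anyNA(altitude)) {
    stop("missing condition values: every subject needs both conditions",
         call. = FALSE)
  }
  n <- length(sea)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (!exact && n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  d <- altitude - sea
  obs <- mean(d)
  tol <- 1e-12 * max(abs(d), 1)

  if (scheme == "paired") {
    if (exact) {
      if (n > 20L) stop("exact enumeration limited to n <= 20", call. = FALSE)
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null <- as.vector(signs %*% d) / n
      p <- mean(abs(null) >= abs(obs) - tol)
      n_used <- nrow(signs)
    } else {
      null <- with_seed(seed, {
        S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
        as.vector(S %*% d) / n
      })
      p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (1 + n_perm)
      n_used <- n_perm
    }
  } else {
    pool <- c(sea, altitude)
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(2L * n, n)
        mean(pool[idx]) - mean(pool[-idx])
      }, 0)
    })
    p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(
    list(
      observed_diff = obs, p_value = p,
      cohens_d = tryCatch(cohens_d(sea, altitude), error = function(e) NA_real_),
      n_subjects = n, n_permutations = n_used, scheme = scheme,
      exact = exact, seed = seed
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test %s%s> diff = %.4g, p = %.4g, d = %.3f (n = %d, %d perms)\n",
    x$scheme, if (x$exact) "/exact" else "", x$observed_diff, x$p_value,
    x$cohens_d, x$n_subjects, x$n_permutations))
  invisible(x)
}

#' Cohen's D effect size
#'
#' Standardized mean difference, altitude minus sea level, divided by the
#' pooled standard deviation of the two condition samples. The pooled
#' two-sample form (not the paired `dz`) is the default because it matches
#' the regime of small D alongside significant paired p-values typical of
#' within-subject designs with correlated conditions; `form = "dz"` divides
#' the mean paired difference by the SD of the differences instead.
#'
#' @param sea,altitude Condition samples (paired by position for `dz`).
#' @param form `"pooled"` or `"dz"`.
#' @return Scalar effect size; its sign matches the sign of
#'   `mean(altitude) - mean(sea)`.
#' @export
cohens_d <- function(sea, altitude, form = c("pooled", "dz")) {
  form <- match.arg(form)
  if (length(sea) < 2L || length(altitude) < 2L) {
    stop("need at least 2 values per condition", call. = FALSE)
  }
  if (form == "pooled") {
    n1 <- length(sea); n2 <- length(altitude)
    sp2 <- ((n1 - 1) * stats::var(sea) + (n2 - 1) * stats::var(altitude)) /
      (n1 + n2 - 2)
    if (sp2 <= 0) stop("zero pooled variance: effect size undefined",
                       call. = FALSE)
    (mean(altitude) - mean(sea)) / sqrt(sp2)
  } else {
    d <- altitude - sea
    sdd <- stats::sd(d)
    if (sdd <= 0) stop("zero variance of differences", call. = FALSE)
    mean(d) / sdd
  }
}

#' Pearson correlation with age
#'
#' Product-moment correlation between a metric and subject age, with the
#' usual two-sided t-test p-value. Observations from both conditions are
#' conventionally pooled by the caller.
#'
#' @param values Metric values.
#' @param ages Ages in years, same length.
#' @return List with `r`, `p_value`, `n`.
#' @export
age_correlation <- function(values, ages) {
  if (length(values) != length(ages) || length(values) < 4L) {
    stop("need >= 4 paired observations", call. = FALSE)
  }
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(values, ages, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(values))
}

#' Residualize a metric on age
#'
#' Ordinary least-squares residuals of `values ~ age`, computed on the
#' pooled (both-condition) observations. Residuals have zero mean and zero
#' correlation with age; re-paired by subject they feed the permutation test
#' for age-adjusted condition contrasts.
#'
#' @param values Metric values (pooled across conditions).
#' @param ages Ages in years, same length.
#' @return Numeric residual vector in the input order.
#' @export
regress_out_age <- function(values, ages) {
  if (length(values) != length(ages) || length(values) < 3L) {
    stop("need >= 3 observations", call. = FALSE)
  }
  if (stats::sd(ages) == 0) {
    stop("constant ages: regression degenerate", call. = FALSE)
  }
  unname(stats::resid(stats::lm(values ~ ages)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: sorted ascending,
#' `p_adj(i) = min_{j >= i} p(j) * m / j`, capped at 1, returned in the
#' original order. Wraps the standard step-up implementation after input
#' validation.
#'
#' @param p Raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Condition contrasts over a study table
#'
#' Runs the full inferential layer over a long-format study table (one row
#' per subject x condition x band x scope x metric): a paired sign-flip
#' permutation test and Cohen's D per cell, with Benjamini-Hochberg
#' correction applied within each analysis family (a family is one metric at
#' one scope level, e.g. all bands of global relative power, or all region x
#' band cells of nodal strength — mirroring per-figure reporting).
#' Optionally each cell's values are first residualized on age (pooled over
#' conditions, then re-paired by subject).
#'
#' @param study_table Tibble with columns `subject_id`, `age`, `condition`
#'   (`"sea"`/`"altitude"`), `band`, `scope`, `metric`, `value`.
#' @param n_perm Permutations per test.
#' @param seed Master seed; each cell uses a derived child seed so results
#'   do not depend on evaluation order.
#' @param residualize_age Adjust for age before testing.
#' @param scheme Permutation scheme, see [permutation_test()].
#' @return Tibble with one row per tested cell: family, metric, band, scope,
#'   observed_diff, cohens_d, p_raw, p_fdr, n_subjects, n_perm.
#' @export
run_contrasts <- function(study_table, n_perm = 10000, seed = NULL,
                          residualize_age = FALSE,
                          scheme = c("paired", "unpaired")) {
  scheme <- match.arg(scheme)
  needed <- c("subject_id", "age", "condition", "band", "scope", "metric",
              "value")
  if (!all(needed %in% names(study_table))) {
    stop("study_table missing columns: ",
         paste(setdiff(needed, names(study_table)), collapse = ", "),
         call. = FALSE)
  }
  tbl <- study_table
  tbl$scope_level <- ifelse(tbl$scope == "global", "global", "region")
  tbl$family <- paste(tbl$metric, tbl$scope_level, sep = "_")
  cells <- dplyr::distinct(tbl, .data$family, .data$metric, .data$band,
                           .data$scope)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- tbl[tbl$metric == cell$metric & tbl$band == cell$band &
                 tbl$scope == cell$scope, ]
    wide <- tidyr::pivot_wider(sub[, c("subject_id", "age", "condition",
                                       "value")],
                               names_from = "condition",
                               values_from = "value")
    if (!all(c("sea", "altitude") %in% names(wide)) ||
        anyNA(wide$sea) || anyNA(wide$altitude)) {
      stop("incomplete pairs for ", cell$metric, "/", cell$band, "/",
           cell$scope, call. = FALSE)
    }
    sea <- wide$sea
    alt <- wide$altitude
    if (residualize_age) {
      res <- regress_out_age(c(sea, alt), c(wide$age, wide$age))
      sea <- res[seq_along(sea)]
      alt <- res[seq_along(alt) + length(sea)]
    }
    cell_seed <- if (is.null(seed)) NULL else child_seed(seed, i)
    pt <- permutation_test(sea, alt, n_perm = n_perm, seed = cell_seed,
                           scheme = scheme)
    tibble::tibble(
      family = cell$family, metric = cell$metric, band = cell$band,
      scope = cell$scope, observed_diff = pt$observed_diff,
      cohens_d = pt$cohens_d, p_raw = pt$p_value,
      n_subjects = pt$n_subjects, n_perm = pt$n_permutations
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$family)
  out <- dplyr::mutate(out, p_fdr = bh_fdr(.data$p_raw))
  dplyr::ungroup(out)
}
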