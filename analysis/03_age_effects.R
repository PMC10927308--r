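#!/usr/bin/env Rscript
# Stage 3 — age analyses: Pearson correlations between age and the four
# headline metrics (pooling both conditions), and the condition contrasts
# repeated on age-residualized values.

suppressMessages(library(hypoxeeg))
suppressMessages(library(dplyr))

st <- tibble::as_tibble(utils::read.csv("results/study/study_table.csv"))

headline <- list(c("relative_power", "alpha"), c("exponent", "broadband"),
                 c("overall_fc", "delta"), c("global_efficiency_auc", "theta"))
age_tab <- dplyr::bind_rows(lapply(headline, function(h) {
  sub <- st |> filter(metric == h[1], band == h[2], scope == "global")
  ac <- age_correlation(sub$value, sub$age)
  tibble::tibble(metric = h[1], band = h[2], r = ac$r, p = ac$p_value)
}))
utils::write.csv(age_tab, "results/age_correlations_stage3.csv",
                 row.names = FALSE)
message("Age correlations (both conditions pooled, n = 32):")
print(as.data.frame(age_tab), digits = 3)

adj <- run_contrasts(st, n_perm = 10000, seed = 44, residualize_age = TRUE)
utils::write.csv(adj, "results/contrasts_age_adjusted_stage3.csv",
                 row.names = FALSE)
adj_hl <- adj |>
  filter(scope == "global",
         (metric == "relative_power" & band == "alpha") |
           metric == "exponent" |
           (metric == "overall_fc" & band == "delta") |
           (metric == "global_efficiency_auc" & band == "theta"))
message("Age-adjusted headline contrasts:")
print(as.data.frame(adj_hl |>
  select(metric, band, observed_diff, cohens_d, p_fdr)), digits = 3)
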