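#!/usr/bin/env Rscript
# Stage 2 — condition contrasts (altitude minus sea level) over the study
# table produced by 01_run_study.R: paired sign-flip permutation tests with
# Cohen's D and within-family Benjamini-Hochberg correction, plus a compact
# summary of the headline cells.

suppressMessages(library(hypoxeeg))
suppressMessages(library(dplyr))

st <- tibble::as_tibble(utils::read.csv("results/study/study_table.csv"))
contrasts <- run_contrasts(st, n_perm = 10000, seed = 43)
utils::write.csv(contrasts, "results/contrasts_stage2.csv",
                 row.names = FALSE)

headline <- contrasts |>
  filter(scope == "global",
         (metric == "relative_power" & band %in% c("delta", "alpha")) |
           metric == "exponent" |
           (metric == "overall_fc" & band == "delta") |
           (metric == "global_efficiency_auc" & band == "theta")) |>
  select(metric, band, observed_diff, cohens_d, p_raw, p_fdr)

message("Headline condition contrasts (altitude minus sea level):")
print(as.data.frame(headline), digits = 3)

sig <- sum(contrasts$p_fdr < 0.05)
message(sprintf("%d of %d cells FDR-significant at 0.05", sig,
                nrow(contrasts)))
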