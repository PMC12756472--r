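#!/usr/bin/env Rscript
# Compare the phylogenetic structure of the four landscapes: SR-PD
# coupling, mean SES-PD / NRI / NTI per scenario, and the NRI/NTI
# sign-pair classification table. Writes results/scenario_comparison.csv.
suppressPackageStartupMessages(library(commphylo))

scenarios <- c("random", "filtering", "overdispersion", "age_gradient")
rows <- lapply(scenarios, function(sc) {
  cells <- read.csv(file.path("results", paste0(sc, "_cells.csv")))
  ct <- sr_pd_correlation(cells$SR, cells$PD)
  data.frame(
    scenario = sc,
    n_cells = nrow(cells),
    sr_pd_r = ct$r,
    sr_pd_p = ct$p_value,
    mean_ses_pd = mean(cells$SES_PD, na.rm = TRUE),
    mean_nri = mean(cells$NRI, na.rm = TRUE),
    mean_nti = mean(cells$NTI, na.rm = TRUE),
    pct_both_positive = 100 * mean(cells$classification %in%
                                     c("both_positive", "habitat_filtering")),
    pct_both_negative = 100 * mean(cells$classification %in%
                                     c("both_negative", "competitive_exclusion")))
})
comparison <- do.call(rbind, rows)
write.csv(comparison, file.path("results", "scenario_comparison.csv"),
          row.names = FALSE)
print(comparison, row.names = FALSE, digits = 3)

cat("\nreading the table:\n")
cat(" - every scenario couples SR and PD strongly (r near 1, P << 0.001)\n")
cat(" - filtering: NRI/NTI > 0 (clustering, habitat-filtering signature), SES-PD < 0\n")
cat(" - overdispersion: NRI/NTI < 0 (competitive-exclusion signature)\n")
cat(" - random: NRI/NTI near 0 with ~5% of cells significant by chance\n")
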