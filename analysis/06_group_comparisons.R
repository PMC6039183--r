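#!/usr/bin/env Rscript
# Group statistics: allele-wise one-way ANOVA with Tukey follow-up on the
# donor-level ABC values (per subset), Welch's t for the headline
# B*08:01-vs-B7-supertype contrast, and ANOVA on donor half-lives.

suppressMessages({
  library(hlabquant)
  library(dplyr)
})

donor_abc <- read.delim("results/abc.tsv", check.names = FALSE) |>
  filter(antibody != "W6/32")
hl <- read.delim("results/halflife.tsv", check.names = FALSE)

rows <- list()
for (ss in unique(donor_abc$subset)) {
  d <- donor_abc[donor_abc$subset == ss, ]
  a <- one_way_anova(d$mean_abc, d$allele, posthoc = "tukey")
  cat(sprintf("\n%s ABC ~ allele: F = %.2f, p = %.2g %s\n",
              ss, a$f, a$p, a$tier))
  print(as.data.frame(a$group_means), row.names = FALSE)
  sig <- a$pairwise |> filter(tier != "ns")
  cat(sprintf("  Tukey: %d of %d pairs significant\n",
              nrow(sig), nrow(a$pairwise)))
  rows[[ss]] <- tibble(analysis = paste0("abc_", ss), f = a$f, p = a$p,
                       tier = a$tier)
}

b7 <- c("B*07:02", "B*35:01", "B*51:01")
ly <- donor_abc[donor_abc$subset == "CD4T", ]
w <- welch_t(ly$mean_abc[ly$allele == "B*08:01"],
             ly$mean_abc[ly$allele %in% b7])
cat(sprintf("\nCD4T B*08:01 vs B7-supertype (Welch): t = %.2f, p = %.2g %s\n",
            w$t, w$p, w$tier))
rows$welch <- tibble(analysis = "abc_CD4T_b0801_vs_b7", f = NA, p = w$p,
                     tier = w$tier)

hq <- hl |> filter(qc_pass)
ah <- one_way_anova(hq$mean_t_half, hq$allele, posthoc = "none")
cat(sprintf("\nHalf-life ~ allele (QC-passing donors): F = %.2f, p = %.2g %s\n",
            ah$f, ah$p, ah$tier))
rows$hl <- tibble(analysis = "halflife", f = ah$f, p = ah$p, tier = ah$tier)

## illustrative ratio summaries on the ratio operations
cat(sprintf("\nHC10 receptivity example (specific 500 / control 250): %.1f\n",
            hc10_ratio(500, 250)))
cat(sprintf("Surface fraction example (fixed 300 / fixed+perm 600): %.2f\n",
            surface_fraction(300, 600)))
cat(sprintf("2^-dCt example (Ct 21 vs 20): %.2f\n", expr_2dct(21, 20)))

comparisons <- bind_rows(rows)
write.table(comparisons, "results/comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWrote results/comparisons.tsv\n")
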