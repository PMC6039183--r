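#!/usr/bin/env Rscript
# Surface stability: fit one-phase decay (plateau = 0) per donor and
# experiment, average across experiments, and apply the QC rule
# (n >= 2 and SEM/mean < 0.33).

suppressMessages({
  library(hlabquant)
  library(dplyr)
})

decay <- read.delim("results/synthetic/decay.tsv", check.names = FALSE)
fits <- fit_decay_table(decay,
                        group_cols = c("donor", "allele", "draw", "subset",
                                       "antibody"))
cat(sprintf("Fitted %d series; %d converged, %d non-decaying\n",
            nrow(fits), sum(fits$fit_ok), sum(fits$non_decaying)))

hl <- aggregate_halflives(fits) |>
  left_join(distinct(decay[, c("donor", "allele")]), by = "donor")
write.table(hl, "results/halflife.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

per_allele <- hl |>
  filter(qc_pass) |>
  group_by(allele) |>
  summarise(mean_h = mean(mean_t_half), sem = sd(mean_t_half) / sqrt(n()),
            n_donors = n(), .groups = "drop")
cat("\nDonor-averaged surface half-lives (QC-passing donors):\n")
print(as.data.frame(per_allele), row.names = FALSE)
cat(sprintf("\nQC: %d of %d donors pass (SEM/mean < 0.33, n >= 2)\n",
            sum(hl$qc_pass), nrow(hl)))
truth <- decay |> distinct(donor, true_half_life)
rec <- hl |> left_join(truth, by = "donor")
cat(sprintf("Median |t_half - truth|/truth: %.3f\n",
            median(abs(rec$mean_t_half - rec$true_half_life) /
                     rec$true_half_life)))
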