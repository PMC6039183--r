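#!/usr/bin/env Rscript
# Peptidome diversity: filter to standard 9-mers, remove overlaps between
# motif-incompatible alleles, and compute per-position frequency matrices
# and Shannon entropy profiles.

suppressMessages({
  library(hlabquant)
  library(dplyr)
})

peps_raw <- read.delim("results/synthetic/peptides.tsv", check.names = FALSE)
design <- read.delim("results/synthetic/peptidome_design.tsv",
                     check.names = FALSE)

peps <- filter_peptides(peps_raw, length = 9)
drops <- attr(peps, "dropped")
cat(sprintf("Kept %d of %d peptides after 9-mer/standard-residue filtering\n",
            sum(drops$kept), nrow(peps_raw)))

# B*07:02 and B*35:01 share the P2-proline-type motif; B*08:01 does not
compat <- tibble(allele_a = "B*07:02", allele_b = "B*35:01")
peps <- exclusive_assignment_filter(peps, compat)

etab <- entropy_table(peps, n_datasets = 1L)
write.table(etab, "results/entropy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fm <- bind_rows(lapply(unique(peps$allele), function(al) {
  q <- frequency_matrix(peps$peptide[peps$allele == al])
  tibble(allele = al,
         position = rep(seq_len(ncol(q)), each = 20),
         residue = rep(rownames(q), ncol(q)),
         frequency = as.vector(q))
}))
write.table(fm, "results/freq_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

chk <- etab |>
  left_join(design, by = c("allele", "position")) |>
  mutate(err = abs(entropy_bits - design_entropy_bits))
cat(sprintf("Max |entropy - design| = %.3f bits across %d allele-positions\n",
            max(chk$err), nrow(chk)))
anchors <- etab |> filter(entropy_bits < 2)
cat("Restricted (anchor-like) positions, entropy < 2 bits:\n")
print(as.data.frame(anchors[, c("allele", "position", "entropy_bits")]),
      row.names = FALSE)
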