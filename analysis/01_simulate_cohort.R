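#!/usr/bin/env Rscript
# Simulate the full synthetic study: bead standards, a donor cohort with a
# designed allele/cell-type expression hierarchy (B*08:01 high on
# lymphocytes, B7-supertype alleles high on monocytes), BFA decay series,
# a Luminex single-antigen panel and allele-assigned peptidomes.
# Everything downstream (02-06) reads only the TSVs written here.

suppressMessages({
  library(hlabquant)
  library(dplyr)
})

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, name) {
  write.table(x, file.path(out, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

## bead standards: power-law curve spanning 1e2-1e6 ABC
beads <- simulate_bead_standards(1, 0, 10^(2:6), noise_cv = 0.02, seed = seed)
tsv(beads, "beads.tsv")

## donor cohort: 4 alleles x 8 donors x 4 draws, CD4T + monocyte,
## 2 Bw6-homozygous donors in the B*07:02 group
alleles <- c("B*08:01" = "Bw6", "B*07:02" = "Bw6",
             "B*35:01" = "Bw6", "B*51:01" = "Bw4")
mean_abc <- tidyr::crossing(allele = names(alleles),
                            subset = c("CD4T", "monocyte")) |>
  mutate(abc = case_when(
    subset == "CD4T" & allele == "B*08:01" ~ 60000,
    subset == "CD4T" ~ 40000,
    subset == "monocyte" & allele == "B*08:01" ~ 40000,
    TRUE ~ 60000))
des <- cohort_design(alleles = alleles, cell_subsets = c("CD4T", "monocyte"),
                     mean_abc = mean_abc, donor_cv = 0.2, replicate_cv = 0.1,
                     n_donors_per_allele = 8, n_draws = 4,
                     n_homozygous_per_allele = 2, seed = seed)
sim <- simulate_cohort(des)
tsv(sim$stains, "stains.tsv")
tsv(sim$genotypes, "genotypes.tsv")
tsv(sim$truth, "truth.tsv")
tsv(mean_abc, "design_mean_abc.tsv")

## decay series: B*08:01 long-lived (11 h), B7-supertype short (6 h),
## 3 independent experiments per donor on the CD4T subset
decay <- bind_rows(lapply(seq_along(alleles), function(i) {
  al <- names(alleles)[i]
  th <- if (al == "B*08:01") 11 else 6
  donors <- sim$genotypes$donor[sim$genotypes$allele == al][1:4]
  bind_rows(lapply(seq_along(donors), function(j) {
    simulate_decay(th, y0 = 100, time_points = c(0, 2, 4, 8, 24),
                   noise_cv = 0.1, n_series = 3,
                   seed = seed + 100 * i + j) |>
      mutate(donor = donors[j], allele = al, subset = "CD4T",
             antibody = "anti-Bw6", draw = series)
  }))
}))
tsv(decay, "decay.tsv")

## Luminex panel: HLA-B Bw6 alleles recognized, some HLA-C cross-reactive,
## HLA-A and Bw4 negative for the anti-Bw6 antibody
panel_truth <- tibble(
  allele = c("B*07:02", "B*08:01", "B*35:01", "B*40:01",   # Bw6: bind
             "B*51:01", "B*57:01",                          # Bw4: no binding
             "A*01:01", "A*02:01",                          # HLA-A: none
             "C*07:02", "C*12:03",                          # Bw6-like HLA-C
             "C*04:01", "C*06:02"),                         # altered motif
  ratio = c(1.0, 1.05, 0.95, 1.0, 0, 0, 0, 0, 0.9, 0.85, 0, 0))
panel <- simulate_luminex_panel(panel_truth, n_replicates = 2, seed = seed)
tsv(panel, "luminex.tsv")
tsv(panel_truth, "luminex_truth.tsv")

## heavy-chain sequences (synthetic backbones carrying the real epitope
## windows at positions 77-83) for the motif scan
set.seed(seed)
backbone <- function() paste(sample(amino_acids(), 120, TRUE), collapse = "")
win <- c("B*07:02" = "SLRNLRG", "B*08:01" = "SLRNLRG", "B*35:01" = "SLRNLRG",
         "B*40:01" = "SLRNLRG", "B*51:01" = "NLRIALR", "B*57:01" = "NLRTLLR",
         "A*01:01" = "DLRSWTA", "A*02:01" = "DLRSWTA",
         "C*07:02" = "SLRNLRG", "C*12:03" = "SLRNLRG",
         "C*04:01" = "SLRKLRG", "C*06:02" = "ALRNLRG")
seqs <- tibble(allele = names(win),
               sequence = vapply(win, function(w) {
                 b <- backbone()
                 paste0(substr(b, 1, 76), w, substr(b, 84, 120))
               }, character(1)))
tsv(seqs, "heavy_chains_synthetic.tsv")

## peptidomes: anchor-restricted at P2 and P9 for all alleles; B*08:01
## additionally restricted at P3 and P5 (extra anchors)
prof <- list(
  "B*07:02" = c(3.8, 1.0, 3.6, 4.0, 3.7, 3.9, 3.6, 3.4, 0.8),
  "B*08:01" = c(3.8, 1.0, 1.8, 4.0, 1.5, 3.9, 3.6, 3.4, 0.8),
  "B*35:01" = c(3.8, 1.2, 3.6, 4.0, 3.7, 3.9, 3.6, 3.4, 0.9))
pfms <- lapply(prof, function(bits) {
  m <- vapply(seq_along(bits),
              function(i) pfm_column_with_entropy(bits[i], top_residue = i),
              numeric(20))
  rownames(m) <- amino_acids()
  m
})
peps <- simulate_peptidome(pfms, n_peptides = 20000, seed = seed)
tsv(peps, "peptides.tsv")
tsv(tibble(allele = rep(names(prof), each = 9),
           position = rep(1:9, length(prof)),
           design_entropy_bits = unlist(prof)), "peptidome_design.tsv")

cat("Synthetic study written to", out, "\n")
cat(sprintf("  %d stain records, %d donors, %d decay series, %d peptides\n",
            nrow(sim$stains), nrow(sim$genotypes),
            length(unique(paste(decay$donor, decay$draw))), nrow(peps)))
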