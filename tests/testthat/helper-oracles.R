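# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed-form OLS, grid search for the decay fit,
# explicit loops for motif matching and entropy.

# closed-form simple OLS of y on x
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# grid search over (y0, k) minimizing linear-scale SSE, with refinement
grid_decay_oracle <- function(time_h, mfi, k_range = c(1e-3, 2),
                              y0_range = NULL, n_grid = 60, n_refine = 4) {
  if (is.null(y0_range)) y0_range <- c(max(mfi) * 0.2, max(mfi) * 3)
  best <- c(y0 = NA, k = NA, sse = Inf)
  for (r in seq_len(n_refine)) {
    y0s <- seq(y0_range[1], y0_range[2], length.out = n_grid)
    ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
    for (y0 in y0s) {
      pred <- outer(ks, time_h, function(k, t) y0 * exp(-k * t))
      sse <- rowSums(sweep(pred, 2, mfi)^2)
      i <- which.min(sse)
      if (sse[i] < best["sse"]) best <- c(y0 = y0, k = ks[i], sse = sse[i])
    }
    dy <- diff(y0_range) / n_grid
    y0_range <- c(max(1e-9, best["y0"] - 2 * dy), best["y0"] + 2 * dy)
    lk <- diff(log(k_range)) / n_grid
    k_range <- exp(c(log(best["k"]) - 2 * lk, log(best["k"]) + 2 * lk))
  }
  best
}

# brute-force motif matcher: explicit per-position loop
brute_motif_call <- function(sequence, motifs, offset = 0L) {
  for (m in unique(motifs$motif)) {
    rows <- motifs[motifs$motif == m, ]
    ok <- TRUE
    for (j in seq_len(nrow(rows))) {
      res <- substr(sequence, rows$position[j] + offset,
                    rows$position[j] + offset)
      allowed <- strsplit(rows$residues[j], "")[[1]]
      if (!(res %in% allowed)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(m)
  }
  "none"
}

# brute-force entropy: explicit loop over the 20-letter alphabet
brute_entropy <- function(peptides, position) {
  aa <- amino_acids()
  n <- length(peptides)
  e <- 0
  for (a in aa) {
    cnt <- 0
    for (p in peptides) if (substr(p, position, position) == a) cnt <- cnt + 1
    q <- cnt / n
    if (q > 0) e <- e - q * log2(q)
  }
  e
}

# random protein sequence over the standard alphabet
random_protein <- function(n, len = 100) {
  vapply(seq_len(n), function(i) {
    paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
  }, character(1))
}

# a small standard design used by several end-to-end tests
small_cohort_design <- function(seed = 1, donor_cv = 0.2, replicate_cv = 0.1,
                                n_donors = 8, n_draws = 4, n_hom = 0) {
  alleles <- c("B*08:01" = "Bw6", "B*07:02" = "Bw6", "B*35:01" = "Bw6")
  mean_abc <- tidyr::crossing(allele = names(alleles),
                              subset = c("CD4T", "monocyte")) |>
    dplyr::mutate(abc = dplyr::case_when(
      subset == "CD4T" & allele == "B*08:01" ~ 60000,
      subset == "CD4T" ~ 40000,
      subset == "monocyte" & allele == "B*08:01" ~ 40000,
      TRUE ~ 60000
    ))
  cohort_design(alleles = alleles, cell_subsets = c("CD4T", "monocyte"),
                mean_abc = mean_abc, donor_cv = donor_cv,
                replicate_cv = replicate_cv,
                n_donors_per_allele = n_donors, n_draws = n_draws,
                n_homozygous_per_allele = n_hom, seed = seed)
}
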