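# hlabquant

Allele- and cell-type-resolved quantitation of HLA-B cell-surface
expression from flow-cytometry summaries, with the downstream analyses
that turn calibrated values into immunology: surface half-life
estimation, antibody-specificity screening, immunopeptidome diversity
and group statistics.

## The problem

HLA-B allotypes differ in how efficiently they load peptides in the ER
and how stable their surface complexes are; allotypes that prefer
proline at peptide position 2 (the B7 supertype) are disfavoured by the
TAP transporter and show distinctive expression and stability
behaviour, which differs again between lymphocytes and monocytes.
Measuring this across donors requires converting fluorescence to an
absolute scale and stripping out everything that is not expression.
`hlabquant` implements that pipeline:

- **ABC calibration** — beads with known antibody binding capacity
  (ABC) give a standard curve `log A = β₀ + β₁ log M` (or linear-linear);
  cell geometric MFIs are isotype-subtracted, interpolated, corrected
  ×0.5 for Bw6-homozygous donors whose HLA-C alleles also carry the
  epitope, and aggregated per donor (mean, SEM, N over draws).
- **Antibody specificity** — single-antigen bead panels normalized to
  the pan-class-I antibody W6/32; Bw4/Bw6 epitope motif scanning on
  heavy-chain residues 77–83 from an editable motif table;
  cross-reactivity flagging; regression of cell-derived ABC on bead
  binding ratios with "majority below the line" flags.
- **Surface stability** — after a Brefeldin-A traffic block, surface
  signal decays as `y(t) = y₀·e^(−kt)` with plateau fixed at zero;
  `t½ = ln2/k` is fitted per experiment by bounded nonlinear least
  squares, averaged per donor, and filtered by the inclusion rule
  N ≥ 2 and SEM/mean < 0.33.
- **Peptidome entropy** — allele-assigned 9-mers are tabulated into
  raw per-position frequencies and summarised as Shannon entropy
  `E(i) = −Σ q log₂ q` (0 bits = fixed anchor, log₂20 ≈ 4.32 = fully
  diverse).
- **Group statistics** — one-way ANOVA with Tukey (or Bonferroni)
  follow-up, Welch's t, Pearson/OLS, star tiers, and the ratio
  summaries used for peptide receptivity (HC10), intracellular pools,
  tapasin levels and 2^−ΔCt transcripts.
- **Synthetic cohorts** — every input (beads, stains, genotypes,
  decay series, bead panels, peptidomes) can be generated with known
  ground truth, so the whole pipeline is testable end to end without
  donor material.

## Worked example

Simulate a two-allele cohort in which B\*08:01 is designed 1.5× above
B\*07:02 on CD4 T cells, calibrate it, and test the difference:

```r
library(hlabquant)
library(dplyr)

beads <- simulate_bead_standards(curve_slope = 1, curve_intercept = 0,
                                 abc_levels = 10^(2:6), noise_cv = 0.02,
                                 seed = 1)
curve <- fit_standard_curve(beads, "log-log")
curve
#> <calibration_curve> mode=log-log slope=0.997102 intercept=0.0243094
#>   r2=0.999981 range=[98.74, 1.006e+06]

des <- cohort_design(
  alleles  = c("B*08:01" = "Bw6", "B*07:02" = "Bw6"),
  cell_subsets = c("CD4T", "monocyte"),
  mean_abc = tidyr::crossing(allele = c("B*08:01", "B*07:02"),
                             subset = c("CD4T", "monocyte")) |>
    mutate(abc = if_else(allele == "B*08:01" & subset == "CD4T",
                         60000, 40000)),
  n_donors_per_allele = 8, n_draws = 4, seed = 1)
sim <- simulate_cohort(des)

donor_abc <- compute_abc(sim$stains, curve, sim$genotypes) |>
  aggregate_donor() |>
  left_join(sim$genotypes[, c("donor", "allele")], by = "donor")

cd4 <- filter(donor_abc, antibody == "anti-Bw6", subset == "CD4T")
cmp <- one_way_anova(cd4$mean_abc, cd4$allele)
cmp$group_means
#>   group     mean     n
#> 1 B*07:02 39603.     8
#> 2 B*08:01 60236.     8
sprintf("F = %.2f, p = %.2g %s", cmp$f, cmp$p, cmp$tier)
#> "F = 19.58, p = 0.00058 ***"
```

The recovered group means sit on the designed 40,000 / 60,000
molecules-per-cell truth, and the allele difference is detected at
p < 0.001. Half-lives work the same way — simulate decay at a true
t½ = 8 h with 10% noise, fit, aggregate, QC:

```r
t <- c(0, 2, 4, 8, 24)
series <- simulate_decay(8, y0 = 100, time_points = t, noise_cv = 0.1,
                         n_series = 3, seed = 2)
fits <- fit_decay_table(series)
round(fits$t_half, 2)
#> [1] 8.73 8.95 7.06
aggregate_halflives(fits |> mutate(donor = "D001"))
#>   donor mean_t_half   sem     n qc_pass
#> 1 D001         8.25 0.596     3 TRUE
```

## The analysis workflow

`analysis/` contains the study as numbered drivers over the package:

1. `01_simulate_cohort.R` — generates the full synthetic study
   (bead standards, 4-allele × 2-subset cohort with the designed
   lymphocyte/monocyte hierarchy reversal, decay series, Luminex
   panel, heavy chains, peptidomes) under `results/synthetic/`.
2. `02_calibrate_abc.R` — standard curve, ABC table, homozygote
   corrections, epitope/pan and monocyte-normalized ratios.
3. `03_luminex_specificity.R` — bead normalization, motif calls,
   cross-reactivity flags, bead-vs-cell regression.
4. `04_decay_halflife.R` — per-experiment decay fits, donor averages,
   QC filter, recovery against truth.
5. `05_peptidome_entropy.R` — 9-mer filtering, exclusive-assignment
   filter, frequency matrices and entropy profiles.
6. `06_group_comparisons.R` — per-subset ANOVA with Tukey follow-up,
   the Welch contrast, half-life ANOVA, ratio examples.

Run them in order from the repository root
(`Rscript analysis/01_simulate_cohort.R` …); each prints what it found
and writes its tables under `results/`.

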