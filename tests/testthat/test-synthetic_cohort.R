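test_that("bead simulator follows the configured log-linear curve", {
  # identity curve, no noise
  b <- simulate_bead_standards(1, 0, c(1e3, 1e4), noise_cv = 0)
  expect_equal(b$mfi, c(1e3, 1e4))
  # closed form for a non-trivial curve
  b2 <- simulate_bead_standards(0.9, 1, c(1e3, 1e4), noise_cv = 0)
  expect_equal(b2$mfi[2], exp(1 + 0.9 * log(1e4)))
  # noise magnitude matches the design on the log scale
  b3 <- simulate_bead_standards(1, 0, c(1e3, 1e4), noise_cv = 0.05,
                                seed = 42, n_per_level = 200)
  sd_log <- sd(log(b3$mfi[b3$abc == 1e3]))
  expect_lt(abs(sd_log - sqrt(log(1 + 0.05^2))) / sqrt(log(1 + 0.05^2)), 0.2)
  # invalid designs rejected
  expect_error(simulate_bead_standards(1, 0, c(-1, 10)), "positive")
  expect_error(simulate_bead_standards(1, 0, c(10, 10)), "increasing")
})

test_that("zero-noise cohort round-trips through calibration exactly", {
  des <- small_cohort_design(seed = 3, donor_cv = 0, replicate_cv = 0,
                             n_donors = 2, n_draws = 2)
  sim <- simulate_cohort(des)
  beads <- simulate_bead_standards(1, 0, 10^(2:6), noise_cv = 0)
  curve <- fit_standard_curve(beads, "log-log")
  abc <- compute_abc(sim$stains, curve, sim$genotypes)
  chk <- abc |>
    dplyr::filter(antibody != "W6/32") |>
    dplyr::left_join(sim$truth, by = c("donor", "subset"))
  expect_lt(max(abs(chk$abc - chk$true_abc) / chk$true_abc), 1e-9)
  # pan channel round-trips to the pan truth as well
  pan <- abc |>
    dplyr::filter(antibody == "W6/32") |>
    dplyr::left_join(sim$truth, by = c("donor", "subset"))
  expect_lt(max(abs(pan$abc - pan$true_pan_abc) / pan$true_pan_abc), 1e-9)
})

test_that("cohort effect sizes are recovered at realistic noise", {
  des <- small_cohort_design(seed = 11)
  sim <- simulate_cohort(des)
  beads <- simulate_bead_standards(1, 0, 10^(2:6), noise_cv = 0)
  curve <- fit_standard_curve(beads, "log-log")
  donor <- compute_abc(sim$stains, curve, sim$genotypes) |>
    aggregate_donor() |>
    dplyr::filter(antibody == "anti-Bw6", subset == "CD4T") |>
    dplyr::left_join(sim$genotypes[, c("donor", "allele")], by = "donor")
  m <- tapply(donor$mean_abc, donor$allele, mean)
  # designed CD4T ratio 60000/40000 = 1.5, donor CV 0.2 over 8 donors
  expect_lt(abs(m[["B*08:01"]] / m[["B*07:02"]] - 1.5), 0.35)
})

test_that("homozygous donors have doubled epitope but unchanged pan signal", {
  des <- small_cohort_design(seed = 5, donor_cv = 0, replicate_cv = 0,
                             n_donors = 2, n_draws = 1, n_hom = 1)
  sim <- simulate_cohort(des)
  g <- sim$genotypes
  hom <- g$donor[g$hla_b_bw6_homozygous & g$allele == "B*08:01"]
  het <- g$donor[!g$hla_b_bw6_homozygous & g$allele == "B*08:01"]
  s <- sim$stains |> dplyr::filter(subset == "CD4T")
  epi_mfi <- function(d) s$mfi[s$donor == d & s$antibody == "anti-Bw6"] -
    s$isotype_mfi[s$donor == d & s$antibody == "anti-Bw6"]
  pan_mfi <- function(d) s$mfi[s$donor == d & s$antibody == "W6/32"] -
    s$isotype_mfi[s$donor == d & s$antibody == "W6/32"]
  expect_equal(unname(epi_mfi(hom) / epi_mfi(het)), 2, tolerance = 1e-12)
  expect_equal(unname(pan_mfi(hom) / pan_mfi(het)), 1, tolerance = 1e-12)
})

test_that("simulated cohorts are seed-deterministic", {
  a <- simulate_cohort(small_cohort_design(seed = 9, n_donors = 3, n_draws = 2))
  b <- simulate_cohort(small_cohort_design(seed = 9, n_donors = 3, n_draws = 2))
  expect_identical(a$stains, b$stains)
  expect_identical(a$genotypes, b$genotypes)
  c <- simulate_cohort(small_cohort_design(seed = 10, n_donors = 3, n_draws = 2))
  expect_false(identical(a$stains$mfi, c$stains$mfi))
})

test_that("decay simulator matches the closed form and validates input", {
  d <- simulate_decay(6, y0 = 100, time_points = c(0, 6, 12), noise_cv = 0)
  expect_equal(d$mfi, c(100, 50, 25))
  expect_error(simulate_decay(Inf), "finite")
  expect_error(simulate_decay(-2), "finite and positive")
  expect_error(simulate_decay(6, time_points = c(2, 4)), "include 0")
})

test_that("peptidome simulator converges to the design frequencies", {
  aa <- amino_acids()
  # degenerate matrix -> identical peptides
  q_deg <- matrix(0, 20, 9, dimnames = list(aa, NULL))
  q_deg[match(c("A", "C", "D", "E", "F", "G", "H", "I", "K"), aa) +
          (0:8) * 20] <- 1
  pep <- simulate_peptidome(list(X = q_deg), n_peptides = 50)
  expect_true(all(pep$peptide == "ACDEFGHIK"))
  # convergence at two n values, ~ 1/sqrt(n)
  q_uni <- matrix(1 / 20, 20, 9, dimnames = list(aa, NULL))
  dev_at <- function(n, seed) {
    p <- simulate_peptidome(list(X = q_uni), n_peptides = n, seed = seed)
    max(abs(frequency_matrix(p$peptide) - 1 / 20))
  }
  d_small <- dev_at(400, 21)
  d_large <- dev_at(40000, 22)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.01)
})

test_that("entropy-targeted frequency columns hit their target", {
  for (bits in c(0, 0.5, 1, 2, 4, log2(20))) {
    q <- pfm_column_with_entropy(bits)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_equal(shannon_entropy(q), bits, tolerance = 1e-9)
  }
  expect_error(pfm_column_with_entropy(5), "log2")
})
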