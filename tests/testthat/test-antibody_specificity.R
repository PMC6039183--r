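test_that("panel normalization forms per-allele W6/32 ratios", {
  panel <- tibble::tibble(
    bead = c("b1", "b2", "b2", "b3", "b3", "b3"),
    allele = c("A*02:01", "B*07:02", "B*07:02", "B*08:01", "B*08:01", "B*08:01"),
    test_mfi = c(0, 5000, 5000, 4000, 5000, 6000),
    ref_mfi = c(12000, 5000, 5000, 5000, 5000, 5000)
  )
  bp <- normalize_panel(panel)
  expect_equal(bp$ratio[bp$allele == "A*02:01"], 0)   # no HLA-A binding
  expect_equal(bp$ratio[bp$allele == "B*07:02"], 1)
  expect_equal(bp$ratio[bp$allele == "B*08:01"], 1)
  expect_equal(bp$sd[bp$allele == "B*08:01"], sd(c(0.8, 1.0, 1.2)))
  # scale invariance: coupling efficiency cancels
  panel2 <- panel
  panel2$test_mfi <- panel2$test_mfi * 3.7
  panel2$ref_mfi <- panel2$ref_mfi * 3.7
  expect_equal(normalize_panel(panel2)$ratio, bp$ratio)
  # zero reference excluded with a warning
  panel3 <- panel
  panel3$ref_mfi[1] <- 0
  expect_warning(bp3 <- normalize_panel(panel3), "excluded")
  expect_false("A*02:01" %in% bp3$allele)
})

test_that("motif scan matches canonical windows and rejects near-misses", {
  motifs <- bw_epitope_motifs()
  pad <- function(win) paste0(strrep("A", 76), win, strrep("A", 10))
  expect_equal(scan_epitope_motif(pad("SLRNLRG"), motifs), "Bw6")
  expect_equal(scan_epitope_motif(pad("NLRIALR"), motifs), "Bw4")
  expect_equal(scan_epitope_motif(pad("DLRTLLR"), motifs), "Bw4")
  # violate only position 80 (N -> K): no call
  expect_equal(scan_epitope_motif(pad("SLRKLRG"), motifs), "none")
  # precursor numbering via offset
  prec <- paste0(strrep("M", 24), pad("SLRNLRG"))
  expect_equal(scan_epitope_motif(prec, motifs, offset = 24L), "Bw6")
  # guards
  expect_error(scan_epitope_motif("SHORT", motifs), "shorter")
  expect_error(scan_epitope_motif(pad("SLRNLRX"), motifs), "non-standard")
})

test_that("motif scan agrees with the brute-force matcher on random input", {
  motifs <- bw_epitope_motifs()
  set.seed(19)
  n <- 2000
  seqs <- random_protein(n)
  # enrich with planted motif windows so both classes occur
  planted <- vapply(sample(c("SLRNLRG", "NLRTLLR", "SLRTALR"), 300, TRUE),
                    function(w) paste0(strrep("A", 76), w, strrep("G", 17)),
                    character(1))
  seqs <- c(seqs, unname(planted))
  calls <- scan_epitope_motif(seqs, motifs)
  ref <- vapply(seqs, brute_motif_call, character(1), motifs = motifs,
                USE.NAMES = FALSE)
  expect_identical(calls, ref)
  expect_true(all(c("Bw4", "Bw6", "none") %in% unique(calls)))
})

test_that("cross-reactivity classification is inclusive at the threshold", {
  binding <- tibble::tibble(allele = c("A*01:01", "A*02:01", "A*24:02"),
                            ratio = c(0, 0.2, 0.5), sd = 0, n = 2L)
  cls <- classify_cross_reactivity(c("A*01:01", "A*02:01", "A*24:02",
                                     "A*99:99"), binding, threshold = 0.2)
  expect_equal(cls$status,
               c("negative", "cross_reactive", "cross_reactive", "unknown"))
  # designed panel: exactly the designed positives are flagged
  set.seed(8)
  truth <- tibble::tibble(
    allele = sprintf("A*%02d:01", 1:20),
    ratio = c(runif(5, 0.4, 1.2), rep(0, 15)))
  panel <- simulate_luminex_panel(truth, noise_cv = 0.05, seed = 8)
  bp <- normalize_panel(panel)
  cls2 <- classify_cross_reactivity(truth$allele, bp, threshold = 0.2)
  expect_setequal(cls2$allele[cls2$status == "cross_reactive"],
                  truth$allele[truth$ratio > 0])
})

test_that("bead-vs-cell regression flags alleles below the affinity line", {
  set.seed(55)
  binding <- tibble::tibble(
    allele = c("B*07:02", "B*08:01", "B*15:01", "B*18:01", "B*51:01"),
    ratio = c(0.9, 1.0, 1.1, 0.95, 1.05))
  # perfectly proportional: r = 1, nothing flagged
  donors <- tidyr::crossing(binding, donor_i = 1:6) |>
    dplyr::mutate(donor = paste0(allele, "-", donor_i), subset = "CD4T",
                  mean_abc = 40000 * ratio)
  res <- bead_vs_cell_regression(binding, donors)
  expect_equal(res$model$r, 1, tolerance = 1e-12)
  expect_false(any(res$allele_flags$below_line))
  # shift one allele 40% down with donor noise: that allele (and only it)
  # has a majority of points below the fitted line
  donors2 <- donors |>
    dplyr::mutate(mean_abc = mean_abc *
                    ifelse(allele == "B*51:01", 0.6, 1) *
                    exp(rnorm(dplyr::n(), 0, 0.05)))
  res2 <- bead_vs_cell_regression(binding, donors2)
  flagged <- res2$allele_flags$allele[res2$allele_flags$below_line]
  expect_true("B*51:01" %in% flagged)
  expect_gt(res2$model$r, 0)
  # slope/intercept equal the closed-form OLS oracle
  o <- ols_oracle(res2$points$ratio, res2$points$mean_abc)
  expect_equal(res2$model$slope, o$slope, tolerance = 1e-9)
  expect_equal(res2$model$intercept, o$intercept, tolerance = 1e-9)
  # flags invariant under row reordering
  perm <- donors2[sample(nrow(donors2)), ]
  res3 <- bead_vs_cell_regression(binding, perm)
  expect_equal(dplyr::arrange(res3$allele_flags, allele),
               dplyr::arrange(res2$allele_flags, allele))
  expect_error(bead_vs_cell_regression(binding[1:2, ], donors), "3 alleles")
})
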