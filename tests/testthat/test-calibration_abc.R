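test_that("standard-curve fitting matches closed-form OLS in both modes", {
  # identity log-log
  beads <- tibble::tibble(mfi = c(10, 100, 1000), abc = c(10, 100, 1000))
  cv <- fit_standard_curve(beads, "log-log")
  expect_equal(cv$slope, 1, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # exact proportional line, linear-linear
  beads2 <- tibble::tibble(mfi = c(10, 20, 40, 80), abc = 5 * c(10, 20, 40, 80))
  cv2 <- fit_standard_curve(beads2, "linear-linear")
  expect_equal(cv2$slope, 5, tolerance = 1e-12)
  expect_equal(cv2$intercept, 0, tolerance = 1e-10)
  # noisy beads against the closed-form OLS oracle, both modes
  set.seed(31)
  beads3 <- tibble::tibble(abc = c(1e3, 1e4, 1e5, 1e6))
  beads3$mfi <- beads3$abc * exp(rnorm(4, 0, 0.1))
  o_log <- ols_oracle(log(beads3$mfi), log(beads3$abc))
  cv3 <- fit_standard_curve(beads3, "log-log")
  expect_equal(cv3$slope, o_log$slope, tolerance = 1e-12)
  expect_equal(cv3$intercept, o_log$intercept, tolerance = 1e-12)
  o_lin <- ols_oracle(beads3$mfi, beads3$abc)
  cv4 <- fit_standard_curve(beads3, "linear-linear")
  expect_equal(cv4$slope, o_lin$slope, tolerance = 1e-12)
  expect_equal(cv4$intercept, o_lin$intercept, tolerance = 1e-12)
  # guards
  expect_error(fit_standard_curve(beads[1:2, ], "log-log"), "at least 3")
  expect_error(
    fit_standard_curve(tibble::tibble(mfi = c(0, 1, 2), abc = c(1, 2, 3)),
                       "log-log"),
    "positive MFI")
})

test_that("isotype subtraction floors and flags", {
  expect_equal(subtract_isotype(500, 100)$mfi, 400)
  r <- subtract_isotype(80, 100)
  expect_equal(r$mfi, 0)
  expect_true(r$floored)
  expect_equal(subtract_isotype(500, 0)$mfi, 500)
  expect_error(subtract_isotype(-1, 0), "non-negative")
})

test_that("ABC interpolation inverts the standards and is monotone", {
  beads <- tibble::tibble(mfi = c(10, 100, 1000), abc = c(10, 100, 1000))
  cv <- fit_standard_curve(beads, "log-log")
  expect_equal(interpolate_abc(cv, 250), 250, tolerance = 1e-12)
  # round trip through every bead standard, both modes, noise free
  set.seed(7)
  beads2 <- tibble::tibble(abc = c(2e3, 1e4, 8e4, 5e5))
  beads2$mfi <- exp(0.3 + 0.95 * log(beads2$abc))
  for (mode in c("log-log", "linear-linear")) {
    cvm <- fit_standard_curve(beads2, mode)
    if (mode == "log-log") {
      expect_equal(interpolate_abc(cvm, beads2$mfi), beads2$abc,
                   tolerance = 1e-9)
    }
    # monotone on a dense grid
    grid <- seq(min(beads2$mfi), max(beads2$mfi), length.out = 101)
    vals <- interpolate_abc(cvm, grid)
    expect_true(all(diff(vals) >= 0))
  }
  # dual-route check on a noisy curve: direct formula vs interpolate_abc
  beads3 <- beads2
  beads3$mfi <- beads3$mfi * exp(rnorm(4, 0, 0.05))
  cv3 <- fit_standard_curve(beads3, "log-log")
  mid <- sqrt(beads3$mfi[2] * beads3$mfi[3])
  o <- ols_oracle(log(beads3$mfi), log(beads3$abc))
  expect_equal(interpolate_abc(cv3, mid),
               exp(o$intercept + o$slope * log(mid)), tolerance = 1e-12)
  cv4 <- fit_standard_curve(beads3, "linear-linear")
  o2 <- ols_oracle(beads3$mfi, beads3$abc)
  expect_equal(interpolate_abc(cv4, mid),
               o2$intercept + o2$slope * mid, tolerance = 1e-10)
  # out-of-range policies
  expect_warning(lo <- interpolate_abc(cv, 5), "clamped")
  expect_equal(lo, 10, tolerance = 1e-12)
  expect_error(interpolate_abc(cv, 5000, out_of_range = "error"), "outside")
  expect_equal(interpolate_abc(cv, 5000, out_of_range = "extrapolate"), 5000,
               tolerance = 1e-9)
})

test_that("homozygote correction halves epitope ABC only", {
  beads <- tibble::tibble(mfi = 10^(1:5), abc = 10^(1:5))
  cv <- fit_standard_curve(beads, "log-log")
  stains <- tibble::tibble(
    donor = rep(c("hom", "het"), each = 2),
    draw = 1L,
    subset = "CD4T",
    antibody = rep(c("anti-Bw6", "W6/32"), 2),
    mfi = 40000, isotype_mfi = 0
  )
  geno <- tibble::tibble(
    donor = c("hom", "het"),
    hla_b_bw6_homozygous = c(TRUE, FALSE),
    both_hla_c_epitope = c(TRUE, FALSE)
  )
  out <- compute_abc(stains, cv, geno)
  get <- function(d, ab) out$abc[out$donor == d & out$antibody == ab]
  expect_equal(get("hom", "anti-Bw6"), 20000, tolerance = 1e-9)
  expect_equal(get("het", "anti-Bw6"), 40000, tolerance = 1e-9)
  expect_equal(get("hom", "W6/32"), 40000, tolerance = 1e-9)
  expect_identical(out$corrected,
                   out$antibody == "anti-Bw6" & out$donor == "hom")
  # homozygous at HLA-B but without both HLA-C epitope-bearing: no correction
  geno2 <- geno
  geno2$both_hla_c_epitope <- FALSE
  out2 <- compute_abc(stains, cv, geno2)
  expect_false(any(out2$corrected))
})

test_that("donor aggregation reports mean, SEM and N", {
  tab <- tibble::tibble(donor = "D1", subset = "CD4T", antibody = "anti-Bw6",
                        abc = c(10, 20, 30))
  agg <- aggregate_donor(tab)
  expect_equal(agg$mean_abc, 20)
  expect_equal(agg$sem, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(agg$n, 3L)
  single <- aggregate_donor(tab[1, ])
  expect_equal(single$sem, 0)
  expect_true(single$single_draw)
  # MC: SEM estimates sigma/sqrt(N) for lognormal draws
  set.seed(77)
  x <- rlnorm(1000, 10, 0.3)
  big <- aggregate_donor(tibble::tibble(donor = "D", subset = "s",
                                        antibody = "a", abc = x))
  expect_equal(big$sem, sd(x) / sqrt(1000), tolerance = 1e-12)
})

test_that("epitope/pan ratio and reference-subset normalization", {
  donor_abc <- tibble::tibble(
    donor = rep(c("D1", "D2"), each = 4),
    subset = rep(rep(c("CD4T", "monocyte"), each = 2), 2),
    antibody = rep(c("anti-Bw6", "W6/32"), 4),
    mean_abc = c(20000, 40000, 20000, 20000,
                 5000, 10000, 20000, 20000),
    sem = 0, n = 2L, single_draw = FALSE, corrected = FALSE
  )
  er <- epitope_ratio(donor_abc)
  expect_equal(er$ratio[er$donor == "D1" & er$subset == "CD4T"], 0.5)
  expect_equal(er$ratio[er$donor == "D2" & er$subset == "monocyte"], 1)
  norm <- suppressWarnings(normalize_to_reference_subset(donor_abc, "monocyte"))
  ref_rows <- norm$subset == "monocyte"
  expect_true(all(norm$rel_abc[ref_rows] == 1))
  expect_equal(
    norm$rel_abc[norm$donor == "D2" & norm$subset == "CD4T" &
                   norm$antibody == "anti-Bw6"], 0.25)
  # missing reference flagged, not dropped
  miss <- suppressWarnings(
    normalize_to_reference_subset(donor_abc[donor_abc$subset == "CD4T", ],
                                  "monocyte"))
  expect_true(all(miss$missing_reference))
  expect_equal(nrow(miss), 4)
})
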