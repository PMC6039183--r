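# Synthetic data: every input the pipeline consumes, generated with known
# ground truth so that calibration, kinetics, specificity and statistics can
# be exercised end to end without donor samples. The measurement model is
# multiplicative lognormal noise on MFI (flow intensities are positive and
# approximately log-normal, matching the geometric-mean summaries the
# pipeline ingests).

# lognormal factor with unit mean and coefficient of variation cv
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

.curve_mfi <- function(abc, slope, intercept) exp(intercept + slope * log(abc))

#' Simulate a bead calibration standard set
#'
#' Generates bead populations with known ABC whose measured MFI follows
#' the log-linear standard curve `ln(MFI) = intercept + slope * ln(ABC)`
#' times multiplicative lognormal noise.
#'
#' @param curve_slope,curve_intercept True standard-curve parameters on
#'   the log-log scale.
#' @param abc_levels Strictly increasing, positive ABC levels
#'   (antibodies/cell), one bead population per level.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   factor (0 for noise-free standards).
#' @param seed Integer seed.
#' @param n_per_level Beads drawn per level (replicate acquisitions).
#' @return A tibble with `population`, `abc` (known ground truth),
#'   `mfi`, `replicate`.
#' @export
simulate_bead_standards <- function(curve_slope = 1, curve_intercept = 0,
                                    abc_levels = 10^(3:6), noise_cv = 0,
                                    seed = 1L, n_per_level = 1L) {
  if (any(abc_levels <= 0)) {
    stop("ABC levels must be positive", call. = FALSE)
  }
  if (is.unsorted(abc_levels, strictly = TRUE)) {
    stop("ABC levels must be strictly increasing", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(level = seq_along(abc_levels),
                      replicate = seq_len(n_per_level))
  abc <- abc_levels[grid$level]
  tibble::tibble(
    population = paste0("bead", grid$level),
    abc = abc,
    mfi = .curve_mfi(abc, curve_slope, curve_intercept) *
      .lnoise(length(abc), noise_cv),
    replicate = grid$replicate
  )
}

#' Define a synthetic donor cohort
#'
#' Collects the ground-truth structure of a simulated cohort: the allele
#' panel with serologic epitope classes, the gated cell subsets, the true
#' mean ABC per (allele, subset), between-donor and between-draw
#' coefficients of variation, cohort sizes, and the measurement-model
#' constants (configured calibration curve, epitope/pan ABC ratio,
#' isotype background fraction).
#'
#' @param alleles Named character vector: names are allele labels, values
#'   their epitope class (`"Bw4"`, `"Bw6"` or `"none"`).
#' @param cell_subsets Character vector of subset labels.
#' @param mean_abc Data frame with columns `allele`, `subset`, `abc`
#'   covering every allele x subset pair (true epitope-antibody ABC).
#' @param donor_cv,replicate_cv CVs across donors and repeat draws.
#' @param n_donors_per_allele,n_draws Cohort sizes.
#' @param n_homozygous_per_allele Donors per allele flagged HLA-B
#'   Bw6-homozygous with both HLA-C alleles epitope-bearing; their
#'   generated epitope MFI is doubled (the generator inverts the 0.5x
#'   reporting correction).
#' @param epitope_to_pan_ratio True epitope ABC / pan-class-I ABC.
#' @param isotype_fraction Isotype MFI as a fraction of the pan signal.
#' @param curve_slope,curve_intercept Configured calibration curve used
#'   to invert ABC into MFI.
#' @param seed Integer seed.
#' @return A `cohort_design` list, validated.
#' @export
cohort_design <- function(alleles,
                          cell_subsets = c("CD4T", "CD8T", "B", "NK"),
                          mean_abc,
                          donor_cv = 0.2, replicate_cv = 0.1,
                          n_donors_per_allele = 8L, n_draws = 4L,
                          n_homozygous_per_allele = 0L,
                          epitope_to_pan_ratio = 0.5,
                          isotype_fraction = 0.02,
                          curve_slope = 1, curve_intercept = 0,
                          seed = 1L) {
  stopifnot(is.character(alleles), !is.null(names(alleles)))
  if (!all(alleles %in% c("Bw4", "Bw6", "none"))) {
    stop("epitope classes must be Bw4, Bw6 or none", call. = FALSE)
  }
  if (donor_cv < 0 || replicate_cv < 0) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  stopifnot(is.data.frame(mean_abc),
            all(c("allele", "subset", "abc") %in% names(mean_abc)))
  if (any(mean_abc$abc <= 0)) {
    stop("all true mean ABC values must be positive", call. = FALSE)
  }
  want <- expand.grid(allele = names(alleles), subset = cell_subsets,
                      stringsAsFactors = FALSE)
  have <- paste(mean_abc$allele, mean_abc$subset)
  if (!all(paste(want$allele, want$subset) %in% have)) {
    stop("mean_abc must cover every allele x subset pair", call. = FALSE)
  }
  if (n_homozygous_per_allele > n_donors_per_allele) {
    stop("more homozygous donors than donors per allele", call. = FALSE)
  }
  structure(list(
    alleles = alleles, cell_subsets = cell_subsets,
    mean_abc = tibble::as_tibble(mean_abc),
    donor_cv = donor_cv, replicate_cv = replicate_cv,
    n_donors_per_allele = as.integer(n_donors_per_allele),
    n_draws = as.integer(n_draws),
    n_homozygous_per_allele = as.integer(n_homozygous_per_allele),
    epitope_to_pan_ratio = epitope_to_pan_ratio,
    isotype_fraction = isotype_fraction,
    curve_slope = curve_slope, curve_intercept = curve_intercept,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Simulate a donor cohort of gated stain records
#'
#' Per donor, draw and subset, emits geometric-MFI records for the
#' epitope antibody (anti-Bw6 or anti-Bw4 by allele class), the
#' pan-class-I antibody W6/32, paired with an isotype background MFI.
#' True per-allele ABC is perturbed lognormally at the donor level
#' (`donor_cv`) and again per draw (`replicate_cv`), converted to MFI by
#' the design's calibration curve, and offset by the isotype background
#' so that isotype subtraction plus curve interpolation recovers the
#' truth exactly when all CVs are zero.
#'
#' @param design A [cohort_design()].
#' @return A list of tibbles: `stains` (donor, draw, subset, antibody,
#'   mfi, isotype_mfi), `genotypes` (donor, allele, epitope_class,
#'   hla_b_bw6_homozygous, both_hla_c_epitope, cross_reactive_hla_a) and
#'   `truth` (the sidecar ground-truth ABC per donor/subset).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  alleles <- names(design$alleles)
  donors <- tibble::tibble(
    donor = sprintf("D%03d", seq_len(length(alleles) * design$n_donors_per_allele)),
    allele = rep(alleles, each = design$n_donors_per_allele),
    idx_in_allele = rep(seq_len(design$n_donors_per_allele), length(alleles))
  )
  donors$epitope_class <- unname(design$alleles[donors$allele])
  donors$hla_b_bw6_homozygous <-
    donors$idx_in_allele <= design$n_homozygous_per_allele
  # in the simulated genotypes homozygous donors always carry two
  # epitope-bearing HLA-C alleles, so the reporting correction applies
  donors$both_hla_c_epitope <- donors$hla_b_bw6_homozygous
  donors$cross_reactive_hla_a <- FALSE

  epi_ab <- ifelse(donors$epitope_class == "Bw4", "anti-Bw4", "anti-Bw6")
  ab_key <- stats::setNames(epi_ab, donors$donor)

  grid <- donors |>
    dplyr::select("donor", "allele") |>
    tidyr::crossing(subset = design$cell_subsets) |>
    dplyr::left_join(design$mean_abc, by = c("allele", "subset"))

  # donor-level lognormal effect shared by all subsets and draws
  donor_eff <- stats::setNames(.lnoise(nrow(donors), design$donor_cv),
                               donors$donor)
  grid$true_abc <- grid$abc * donor_eff[grid$donor]
  grid$true_pan_abc <- grid$true_abc / design$epitope_to_pan_ratio

  draws <- tidyr::crossing(grid, draw = seq_len(design$n_draws))
  n <- nrow(draws)
  rep_eff_epi <- .lnoise(n, design$replicate_cv)
  rep_eff_pan <- .lnoise(n, design$replicate_cv)
  rep_eff_iso <- .lnoise(n, design$replicate_cv)

  hom <- stats::setNames(donors$hla_b_bw6_homozygous, donors$donor)
  epi_scale <- ifelse(hom[draws$donor], 2, 1)

  pan_mfi_clean <- .curve_mfi(draws$true_pan_abc,
                              design$curve_slope, design$curve_intercept)
  iso_mfi <- design$isotype_fraction * pan_mfi_clean * rep_eff_iso
  epi_mfi <- .curve_mfi(draws$true_abc * epi_scale,
                        design$curve_slope, design$curve_intercept) *
    rep_eff_epi + iso_mfi
  pan_mfi <- pan_mfi_clean * rep_eff_pan + iso_mfi

  stains <- dplyr::bind_rows(
    tibble::tibble(donor = draws$donor, draw = draws$draw,
                   subset = draws$subset,
                   antibody = unname(ab_key[draws$donor]),
                   mfi = epi_mfi, isotype_mfi = iso_mfi),
    tibble::tibble(donor = draws$donor, draw = draws$draw,
                   subset = draws$subset, antibody = "W6/32",
                   mfi = pan_mfi, isotype_mfi = iso_mfi)
  ) |>
    dplyr::arrange(.data$donor, .data$draw, .data$subset, .data$antibody)

  truth <- grid |>
    dplyr::select("donor", "allele", "subset", "true_abc", "true_pan_abc") |>
    tibble::as_tibble()

  list(
    stains = stains,
    genotypes = donors |>
      dplyr::select("donor", "allele", "epitope_class",
                    "hla_b_bw6_homozygous", "both_hla_c_epitope",
                    "cross_reactive_hla_a"),
    truth = truth
  )
}

#' Simulate Brefeldin-A decay time courses
#'
#' Surface epitope signal after a block of ER-to-Golgi traffic decays as
#' `y(t) = y0 * exp(-ln(2) * t / t_half)`; measurements carry
#' multiplicative lognormal noise.
#'
#' @param true_half_life Half-life in hours (finite, > 0); recycled over
#'   series.
#' @param y0 Initial MFI at t = 0.
#' @param time_points Hours; non-negative, strictly increasing, must
#'   include 0.
#' @param noise_cv CV of the multiplicative measurement noise.
#' @param n_series Number of replicate series to generate.
#' @param seed Integer seed.
#' @return A tibble with `series`, `time_h`, `mfi`, and the sidecar
#'   truth columns `true_half_life`, `true_y0`.
#' @export
simulate_decay <- function(true_half_life, y0 = 100,
                           time_points = c(0, 2, 4, 8, 24),
                           noise_cv = 0, n_series = 1L, seed = 1L) {
  if (any(!is.finite(true_half_life)) || any(true_half_life <= 0)) {
    stop("half-lives must be finite and positive", call. = FALSE)
  }
  if (any(time_points < 0) || is.unsorted(time_points, strictly = TRUE) ||
      time_points[1] != 0) {
    stop("time points must be non-negative, strictly increasing, include 0",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed)
  th <- rep_len(true_half_life, n_series)
  y00 <- rep_len(y0, n_series)
  out <- tidyr::crossing(series = seq_len(n_series),
                         time_h = time_points)
  out$true_half_life <- th[out$series]
  out$true_y0 <- y00[out$series]
  clean <- out$true_y0 * exp(-log(2) * out$time_h / out$true_half_life)
  out$mfi <- clean * .lnoise(nrow(out), noise_cv)
  out
}

#' Build a position frequency column with a target Shannon entropy
#'
#' Two-level distributions (one favoured residue, the remaining 19
#' sharing the rest uniformly) sweep entropy continuously from 0 bits
#' (degenerate) to log2(20) bits (uniform); the favoured-residue weight
#' matching `bits` is found by root-finding.
#'
#' @param bits Target entropy in bits, in `[0, log2(20)]`.
#' @param top_residue Which residue (index 1..20 into [amino_acids()])
#'   receives the excess mass.
#' @return A length-20 probability vector over [amino_acids()].
#' @export
pfm_column_with_entropy <- function(bits, top_residue = 1L) {
  max_bits <- log2(20)
  if (bits < 0 || bits > max_bits + 1e-12) {
    stop("target entropy must lie in [0, log2(20)] bits", call. = FALSE)
  }
  ent <- function(p) {
    q <- c(p, rep((1 - p) / 19, 19))
    -sum(ifelse(q > 0, q * log2(q), 0))
  }
  if (bits >= max_bits - 1e-12) {
    p <- 1 / 20
  } else if (bits == 0) {
    p <- 1
  } else {
    p <- stats::uniroot(function(p) ent(p) - bits,
                        lower = 1 / 20, upper = 1 - 1e-12,
                        tol = 1e-12)$root
  }
  q <- rep((1 - p) / 19, 20)
  q[top_residue] <- p
  stats::setNames(q, amino_acids())
}

#' Simulate an allele-assigned peptidome from position frequency matrices
#'
#' Draws 9-mer peptides with independent positions from per-allele
#' position frequency matrices, emulating allele-assigned eluted-ligand
#' datasets.
#'
#' @param pfms Named list (by allele) of 20 x 9 matrices; rows are the 20
#'   standard amino acids in [amino_acids()] order, columns positions
#'   1..9, each column summing to 1.
#' @param n_peptides Peptides per allele.
#' @param seed Integer seed.
#' @return A tibble with columns `allele`, `peptide`.
#' @export
simulate_peptidome <- function(pfms, n_peptides = 1000L, seed = 1L) {
  stopifnot(is.list(pfms), !is.null(names(pfms)))
  aa <- amino_acids()
  for (al in names(pfms)) {
    q <- pfms[[al]]
    if (!is.matrix(q) || nrow(q) != 20) {
      stop("each PFM must be a 20-row matrix", call. = FALSE)
    }
    if (any(q < 0) || any(abs(colSums(q) - 1) > 1e-9)) {
      stop("PFM columns must be non-negative and sum to 1", call. = FALSE)
    }
  }
  set.seed(seed)
  out <- lapply(names(pfms), function(al) {
    q <- pfms[[al]]
    cols <- vapply(seq_len(ncol(q)), function(i) {
      sample(aa, n_peptides, replace = TRUE, prob = q[, i])
    }, character(n_peptides))
    tibble::tibble(allele = al,
                   peptide = apply(cols, 1L, paste0, collapse = ""))
  })
  dplyr::bind_rows(out)
}

#' Simulate a Luminex single-antigen bead panel
#'
#' One bead per allele; the test-antibody MFI is the design binding ratio
#' times a per-bead coupling efficiency (shared with the pan-class-I
#' reference channel, so normalization cancels it) times lognormal noise.
#'
#' @param binding Data frame with columns `allele`, `ratio` (true
#'   test/pan binding ratio, 0 for non-recognized allotypes).
#' @param ref_mfi Mean pan-class-I reference MFI per bead.
#' @param coupling_cv CV of per-bead HLA coupling efficiency.
#' @param noise_cv CV of per-replicate measurement noise.
#' @param n_replicates Replicate measurements per bead.
#' @param seed Integer seed.
#' @return A tibble with `bead`, `allele`, `test_mfi`, `ref_mfi`,
#'   `dilution`, `replicate`.
#' @export
simulate_luminex_panel <- function(binding, ref_mfi = 15000,
                                   coupling_cv = 0.3, noise_cv = 0.05,
                                   n_replicates = 2L, seed = 1L) {
  stopifnot(all(c("allele", "ratio") %in% names(binding)),
            all(binding$ratio >= 0))
  set.seed(seed)
  coupling <- .lnoise(nrow(binding), coupling_cv)
  out <- tidyr::crossing(
    tibble::tibble(bead = sprintf("bead%02d", seq_len(nrow(binding))),
                   allele = binding$allele, ratio = binding$ratio,
                   coupling = coupling),
    replicate = seq_len(n_replicates)
  )
  n <- nrow(out)
  out$ref_mfi <- ref_mfi * out$coupling * .lnoise(n, noise_cv)
  out$test_mfi <- out$ratio * ref_mfi * out$coupling * .lnoise(n, noise_cv)
  out$dilution <- "1:50"
  out |>
    dplyr::select("bead", "allele", "test_mfi", "ref_mfi",
                  "dilution", "replicate")
}
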