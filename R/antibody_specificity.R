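# Antibody specificity assessment: Luminex single-antigen bead
# normalization, Bw4/Bw6 epitope motif scanning on heavy-chain sequences,
# cross-reactivity flagging, and the bead-vs-cell regression used to spot
# allotypes whose cellular signal falls below the antibody-affinity
# expectation.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order; the row order of all position
#' frequency matrices in this package.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
}

#' Default Bw4/Bw6 serologic epitope motifs (heavy-chain residues 77-83)
#'
#' The Bw4 and Bw6 epitopes of HLA-B (and Bw4-like HLA-A, Bw6-like
#' HLA-C) are determined by residues 77 and 80-83 of the mature heavy
#' chain. Motifs are data, not code: this returns the editable default
#' table (long format, one row per motif/position with the allowed
#' residue set), which mirrors `inst/extdata/motifs.tsv`.
#'
#' @return A tibble with columns `motif`, `position` (77..83, 1-based
#'   mature-protein numbering) and `residues` (allowed one-letter codes,
#'   concatenated).
#' @export
bw_epitope_motifs <- function() {
  tibble::tribble(
    ~motif, ~position, ~residues,
    "Bw4", 77L, "NDS",
    "Bw4", 78L, "L",
    "Bw4", 79L, "R",
    "Bw4", 80L, "IT",
    "Bw4", 81L, "AL",
    "Bw4", 82L, "L",
    "Bw4", 83L, "R",
    "Bw6", 77L, "S",
    "Bw6", 78L, "L",
    "Bw6", 79L, "R",
    "Bw6", 80L, "N",
    "Bw6", 81L, "L",
    "Bw6", 82L, "R",
    "Bw6", 83L, "G"
  )
}

#' Normalize a Luminex single-antigen bead panel
#'
#' Each bead carries a single recombinant HLA allotype; the test
#' antibody's MFI is divided by the pan-class-I (W6/32) MFI on the same
#' bead to correct for differences in HLA coupling to beads. Ratios are
#' then averaged per allele across replicates (and, if requested, across
#' dilutions within a window).
#'
#' @param panel Data frame with columns `bead`, `allele`, `test_mfi`,
#'   `ref_mfi` and optionally `dilution`, `replicate`.
#' @param dilutions Optional character vector restricting which dilution
#'   labels enter the average (default: all present).
#' @return A tibble with `allele`, `ratio` (mean test/ref), `sd`, `n`.
#'   Beads with a zero or negative reference MFI are excluded with a
#'   warning.
#' @export
normalize_panel <- function(panel, dilutions = NULL) {
  stopifnot(all(c("allele", "test_mfi", "ref_mfi") %in% names(panel)))
  if (!is.null(dilutions) && "dilution" %in% names(panel)) {
    panel <- panel[panel$dilution %in% dilutions, , drop = FALSE]
  }
  bad <- panel$ref_mfi <= 0
  if (any(bad)) {
    warning(sprintf("%d bead record(s) with non-positive reference MFI excluded",
                    sum(bad)), call. = FALSE)
    panel <- panel[!bad, , drop = FALSE]
  }
  panel |>
    tibble::as_tibble() |>
    dplyr::mutate(bead_ratio = .data$test_mfi / .data$ref_mfi) |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(
      ratio = mean(.data$bead_ratio),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$bead_ratio), 0),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Scan a heavy-chain sequence for a Bw4/Bw6-like epitope motif
#'
#' Tests the residues at mature-protein positions 77-83 against each
#' motif's allowed residue sets, in table order, returning the first
#' motif whose constraints all hold, or `"none"`. FASTA inputs that
#' retain the signal peptide can be handled with `offset` (e.g. 24 for
#' HLA class I precursors).
#'
#' @param sequence One protein sequence (character scalar, one-letter
#'   codes) or a character vector of sequences.
#' @param motifs Motif table as returned by [bw_epitope_motifs()].
#' @param offset Added to motif positions to index into `sequence`
#'   (default 0, mature numbering).
#' @return Character vector of motif calls, one per sequence.
#' @export
scan_epitope_motif <- function(sequence, motifs = bw_epitope_motifs(),
                               offset = 0L) {
  stopifnot(all(c("motif", "position", "residues") %in% names(motifs)))
  positions <- sort(unique(motifs$position)) + offset
  need_len <- max(positions)
  motif_names <- unique(motifs$motif)
  vapply(sequence, function(s) {
    if (!is.character(s) || nchar(s) < need_len) {
      stop("sequence shorter than the motif window", call. = FALSE)
    }
    window <- substring(s, positions, positions)
    if (!all(window %in% amino_acids())) {
      stop("non-standard residue in the motif window", call. = FALSE)
    }
    for (m in motif_names) {
      rows <- motifs[motifs$motif == m, ]
      rows <- rows[order(rows$position), ]
      allowed <- strsplit(rows$residues, "")
      win <- substring(s, rows$position + offset, rows$position + offset)
      if (all(mapply(function(res, ok) res %in% ok, win, allowed))) {
        return(m)
      }
    }
    "none"
  }, character(1), USE.NAMES = FALSE)
}

#' Flag cross-reactive alleles from normalized bead binding
#'
#' Alleles of non-target loci whose normalized binding ratio reaches the
#' threshold (inclusive) are flagged cross-reactive; donors carrying
#' them are typically excluded from epitope-antibody quantitation.
#' Alleles absent from the panel are flagged `"unknown"`, never assumed
#' negative.
#'
#' @param alleles Character vector of allele labels to classify.
#' @param binding Output of [normalize_panel()].
#' @param threshold Ratio at or above which an allele is cross-reactive.
#' @return Tibble with `allele`, `ratio`, `status`
#'   (`"cross_reactive"`, `"negative"` or `"unknown"`).
#' @export
classify_cross_reactivity <- function(alleles, binding, threshold = 0.2) {
  stopifnot(threshold > 0)
  idx <- match(alleles, binding$allele)
  ratio <- binding$ratio[idx]
  tibble::tibble(
    allele = alleles,
    ratio = ratio,
    status = dplyr::case_when(
      is.na(ratio) ~ "unknown",
      ratio >= threshold ~ "cross_reactive",
      TRUE ~ "negative"
    )
  )
}

#' Regress cell-derived ABC on bead-normalized antibody binding
#'
#' If donor-to-donor ABC differences merely reflect antibody affinity
#' for each allotype, cell-derived ABC should be proportional to the
#' bead ratio. This fits OLS of ABC on the allele's bead ratio over
#' per-donor points, reports Pearson r and its two-sided p, and flags
#' alleles for which the majority (> 50%) of donor points fall below the
#' regression line — expression genuinely lower than antibody affinity
#' predicts.
#'
#' @param binding Output of [normalize_panel()].
#' @param donor_abc Donor-level table with columns `donor`, `allele`,
#'   `subset`, `mean_abc` (e.g. [aggregate_donor()] joined to
#'   genotypes).
#' @param subset Cell subset to analyse.
#' @return A list with `model` (slope, intercept, r, p, n), `points`
#'   (per-donor residuals) and `allele_flags` (fraction of points below
#'   the line and the `below_line` flag).
#' @export
bead_vs_cell_regression <- function(binding, donor_abc, subset = "CD4T") {
  pts <- donor_abc |>
    dplyr::filter(.data$subset == !!subset) |>
    dplyr::select("donor", "allele", "subset", "mean_abc") |>
    dplyr::inner_join(binding[, c("allele", "ratio")], by = "allele")
  if (length(unique(pts$allele)) < 3) {
    stop("at least 3 alleles with both bead and cell values are required",
         call. = FALSE)
  }
  fit <- stats::lm(mean_abc ~ ratio, data = pts)
  ct <- stats::cor.test(pts$ratio, pts$mean_abc, method = "pearson")
  pts$residual <- stats::resid(fit)
  # strictly-below with a tolerance so exact fits do not flag on rounding
  tol <- 1e-8 * mean(abs(pts$mean_abc))
  flags <- pts |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(
      frac_below = mean(.data$residual < -tol),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(below_line = .data$frac_below > 0.5)
  list(
    model = tibble::tibble(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r = unname(ct$estimate),
      p = ct$p.value,
      n = nrow(pts)
    ),
    points = tibble::as_tibble(pts),
    allele_flags = flags
  )
}
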