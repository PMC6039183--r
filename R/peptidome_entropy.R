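# Positional Shannon entropy of allele-assigned peptidomes.
# Peptides are length-filtered to 9-mers, optionally de-overlapped
# between alleles that do not share binding motifs, tabulated into
# per-position amino-acid frequency matrices (raw frequencies, no
# pseudocounts or sequence weighting), and summarised as entropy in bits:
# 0 = fully restricted anchor position, log2(20) ~ 4.32 = uniform usage.

#' Filter an allele-assigned peptide table to fixed-length peptides
#'
#' Keeps peptides of exactly `length` residues drawn from the 20
#' standard amino acids; everything else is dropped and counted.
#' Alleles left without any peptide are omitted with a warning.
#'
#' @param peptides Data frame with columns `allele`, `peptide`.
#' @param length Peptide length to retain (default 9).
#' @return The filtered tibble, with a `dropped` attribute giving
#'   per-allele kept/dropped counts.
#' @export
filter_peptides <- function(peptides, length = 9L) {
  stopifnot(all(c("allele", "peptide") %in% names(peptides)), length >= 1)
  pep <- toupper(peptides$peptide)
  std <- paste0("^[", paste(amino_acids(), collapse = ""), "]+$")
  keep <- nchar(pep) == length & grepl(std, pep)
  counts <- tibble::tibble(allele = peptides$allele, keep = keep) |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(kept = sum(.data$keep), dropped = sum(!.data$keep),
                     .groups = "drop")
  empty <- counts$allele[counts$kept == 0]
  if (length(empty) > 0) {
    warning(sprintf("allele(s) omitted, no peptides left after filtering: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(allele = peptides$allele[keep], peptide = pep[keep])
  attr(out, "dropped") <- counts
  out
}

#' Remove peptides shared between motif-incompatible alleles
#'
#' Eluted-ligand datasets can assign one peptide to several alleles. A
#' peptide listed under two alleles that do NOT share binding motifs is
#' ambiguous and removed from both; peptides shared between declared
#' motif-compatible alleles are retained.
#'
#' @param peptides Data frame with columns `allele`, `peptide`.
#' @param compatible Data frame with columns `allele_a`, `allele_b`
#'   listing unordered motif-compatible pairs (possibly empty).
#' @return Filtered tibble.
#' @export
exclusive_assignment_filter <- function(peptides,
                                        compatible = tibble::tibble(
                                          allele_a = character(),
                                          allele_b = character())) {
  stopifnot(all(c("allele", "peptide") %in% names(peptides)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ok_pairs <- key(compatible$allele_a, compatible$allele_b)
  by_pep <- split(peptides$allele, peptides$peptide)
  # an (allele, peptide) entry is removed when that allele is part of at
  # least one motif-incompatible pair sharing the peptide
  banned <- lapply(by_pep, function(als) {
    als <- unique(als)
    if (length(als) < 2) return(character(0))
    pairs <- utils::combn(sort(als), 2)
    bad <- !(key(pairs[1, ], pairs[2, ]) %in% ok_pairs)
    unique(c(pairs[1, bad], pairs[2, bad]))
  })
  drop <- vapply(seq_len(nrow(peptides)), function(i) {
    peptides$allele[i] %in% banned[[peptides$peptide[i]]]
  }, logical(1))
  tibble::as_tibble(peptides[!drop, , drop = FALSE])
}

#' Per-position amino-acid frequency matrix
#'
#' Raw frequencies `q(a, i) = count(residue a at position i) / n`; no
#' pseudocounts, so every column sums to exactly 1.
#'
#' @param peptides Character vector of equal-length peptides over the
#'   standard alphabet.
#' @return A 20 x L matrix, rows named by [amino_acids()].
#' @export
frequency_matrix <- function(peptides) {
  if (length(peptides) == 0) {
    stop("cannot build a frequency matrix from an empty peptide set",
         call. = FALSE)
  }
  L <- unique(nchar(peptides))
  if (length(L) != 1) {
    stop("peptides must all have the same length", call. = FALSE)
  }
  aa <- amino_acids()
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = L, byrow = TRUE)
  q <- vapply(seq_len(L), function(i) {
    tab <- table(factor(chars[, i], levels = aa))
    as.numeric(tab) / length(peptides)
  }, numeric(20))
  rownames(q) <- aa
  colnames(q) <- seq_len(L)
  q
}

#' Shannon entropy of a frequency column, in bits
#'
#' `E = -sum(q * log2(q))` with the convention `0 * log2(0) = 0`;
#' bounded by 0 (degenerate) and `log2(length(q))` (uniform).
#'
#' @param q Non-negative frequency vector summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(q) {
  if (any(q < 0) || abs(sum(q) - 1) > 1e-9) {
    stop("q must be non-negative and sum to 1", call. = FALSE)
  }
  pos <- q > 0
  -sum(q[pos] * log2(q[pos]))
}

#' Positional entropy profile of an allele's peptidome
#'
#' Applies [frequency_matrix()] and [shannon_entropy()] at each peptide
#' position. Operates on a filtered fixed-length table (see
#' [filter_peptides()]); by default the peptides of all datasets are
#' pooled before tabulation.
#'
#' @param peptides Data frame with columns `allele`, `peptide`
#'   (all the same length), or a character vector of peptides.
#' @param allele Allele to profile when `peptides` is a data frame.
#' @param n_datasets Number of source datasets pooled (bookkeeping only).
#' @return A list with `allele`, `entropy` (named numeric, one value per
#'   position, bits), `q` (the frequency matrix), `n_peptides`,
#'   `n_datasets`.
#' @export
entropy_profile <- function(peptides, allele = NULL, n_datasets = 1L) {
  if (is.data.frame(peptides)) {
    stopifnot(!is.null(allele))
    pep <- peptides$peptide[peptides$allele == allele]
  } else {
    pep <- peptides
  }
  if (length(pep) == 0) {
    stop("no peptides for the requested allele", call. = FALSE)
  }
  q <- frequency_matrix(pep)
  e <- apply(q, 2L, shannon_entropy)
  list(allele = if (is.null(allele)) NA_character_ else allele,
       entropy = e, q = q,
       n_peptides = length(pep), n_datasets = n_datasets)
}

#' Entropy profiles for every allele in a peptide table
#'
#' @param peptides Data frame with columns `allele`, `peptide`.
#' @param n_datasets Bookkeeping, recorded per allele.
#' @return A tibble with `allele`, `position`, `entropy_bits`,
#'   `n_peptides`, `n_datasets` (long format, ready for `entropy.tsv`).
#' @export
entropy_table <- function(peptides, n_datasets = 1L) {
  profs <- lapply(unique(peptides$allele), function(al) {
    p <- entropy_profile(peptides, al, n_datasets = n_datasets)
    tibble::tibble(allele = al,
                   position = seq_along(p$entropy),
                   entropy_bits = unname(p$entropy),
                   n_peptides = p$n_peptides,
                   n_datasets = n_datasets)
  })
  dplyr::bind_rows(profs)
}
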