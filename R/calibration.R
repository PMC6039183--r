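#' Fit a bead standard curve
#'
#' Quantitative flow cytometry converts geometric mean fluorescence
#' intensities (MFI) into antibody binding capacities (ABC,
#' antibodies/cell) by reference to beads bearing known numbers of
#' antibody capture sites. This fits an ordinary least-squares standard
#' curve of ABC on MFI, either on the raw scales (`"linear-linear"`) or
#' with both axes log-transformed (`"log-log"`, the default elsewhere in
#' the pipeline because bead standards typically span several decades).
#'
#' @param beads A data frame with columns `abc` (known antibodies/cell,
#'   all positive and distinct) and `mfi` (measured geometric MFI). At
#'   least three bead populations are required.
#' @param mode `"log-log"` or `"linear-linear"`.
#' @return An object of class `calibration_curve`: a list with `mode`,
#'   `slope`, `intercept`, `r_squared` and `mfi_range` (the span of the
#'   standards, used by [interpolate_abc()]'s out-of-range policy).
#' @examples
#' beads <- tibble::tibble(abc = c(1e3, 1e4, 1e5, 1e6),
#'                         mfi = c(1e3, 1e4, 1e5, 1e6))
#' fit_standard_curve(beads, "log-log")
#' @seealso [interpolate_abc()], [compute_abc()]
#' @export
fit_standard_curve <- function(beads, mode = c("log-log", "linear-linear")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(beads), all(c("abc", "mfi") %in% names(beads)))
  beads <- beads[is.finite(beads$abc) & is.finite(beads$mfi), , drop = FALSE]
  if (nrow(beads) < 3 || length(unique(beads$abc)) < 3) {
    stop("at least 3 bead populations with distinct known ABC are required",
         call. = FALSE)
  }
  if (any(beads$abc <= 0)) {
    stop("known bead ABC values must be positive", call. = FALSE)
  }
  if (mode == "log-log") {
    if (any(beads$mfi <= 0)) {
      stop("log-log fit requires strictly positive MFI values", call. = FALSE)
    }
    fit <- stats::lm(log(abc) ~ log(mfi), data = beads)
  } else {
    fit <- stats::lm(abc ~ mfi, data = beads)
  }
  co <- stats::coef(fit)
  slope <- unname(co[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("standard curve slope must be positive (signal increasing with ABC)",
         call. = FALSE)
  }
  structure(
    list(
      mode = mode,
      slope = slope,
      intercept = unname(co[1L]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      mfi_range = range(beads$mfi)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> mode=%s slope=%.6g intercept=%.6g r2=%.6g range=[%.4g, %.4g]\n",
    x$mode, x$slope, x$intercept, x$r_squared, x$mfi_range[1], x$mfi_range[2]
  ))
  invisible(x)
}

#' Subtract isotype-control background from a specific MFI
#'
#' Background fluorescence measured with the matched isotype control is
#' subtracted from the specific antibody signal. Results below `floor`
#' are set to `floor` (ABC cannot be negative) and flagged.
#'
#' @param specific_mfi,isotype_mfi Non-negative geometric MFI values
#'   (vectorised).
#' @param floor Lower bound applied after subtraction (default 0).
#' @return A tibble with columns `mfi` (the background-subtracted value)
#'   and `floored` (logical, `TRUE` where the floor was applied).
#' @export
subtract_isotype <- function(specific_mfi, isotype_mfi, floor = 0) {
  if (any(!is.finite(specific_mfi)) || any(!is.finite(isotype_mfi))) {
    stop("MFI inputs must be finite", call. = FALSE)
  }
  if (any(specific_mfi < 0) || any(isotype_mfi < 0)) {
    stop("MFI inputs must be non-negative", call. = FALSE)
  }
  raw <- specific_mfi - isotype_mfi
  tibble::tibble(mfi = pmax(raw, floor), floored = raw < floor)
}

#' Interpolate ABC values from a fitted standard curve
#'
#' Maps background-subtracted MFI values onto the ABC scale through a
#' [fit_standard_curve()] result. The mapping is monotone increasing in
#' MFI for any curve with positive slope. MFI values outside the span of
#' the bead standards are handled per `out_of_range`:
#' `"clamp"` (default) pins them to the nearest standard with a warning,
#' `"extrapolate"` extends the fitted line, `"error"` aborts.
#'
#' @param curve A `calibration_curve`.
#' @param mfi Numeric vector of non-negative MFI values.
#' @param out_of_range Out-of-range policy.
#' @return Numeric vector of ABC values (antibodies/cell).
#' @export
interpolate_abc <- function(curve, mfi,
                            out_of_range = c("clamp", "extrapolate", "error")) {
  stopifnot(inherits(curve, "calibration_curve"))
  out_of_range <- match.arg(out_of_range)
  if (any(!is.finite(mfi)) || any(mfi < 0)) {
    stop("mfi must be finite and non-negative", call. = FALSE)
  }
  lo <- curve$mfi_range[1]
  hi <- curve$mfi_range[2]
  outside <- mfi < lo | mfi > hi
  if (any(outside)) {
    if (out_of_range == "error") {
      stop(sprintf("%d MFI value(s) outside the standard-curve range [%g, %g]",
                   sum(outside), lo, hi), call. = FALSE)
    }
    if (out_of_range == "clamp") {
      warning(sprintf("%d MFI value(s) clamped to the standard-curve range",
                      sum(outside)), call. = FALSE)
      mfi <- pmin(pmax(mfi, lo), hi)
    }
  }
  if (curve$mode == "log-log") {
    # zero MFI maps to zero ABC rather than -Inf on the log scale
    abc <- ifelse(mfi == 0, 0,
                  exp(curve$intercept + curve$slope * log(mfi)))
  } else {
    abc <- curve$intercept + curve$slope * mfi
  }
  abc
}

#' Calibrate a stain table into per-draw ABC values
#'
#' Chains [subtract_isotype()] and [interpolate_abc()] over a table of
#' gated-subset stain records and applies the genotype-driven homozygote
#' correction: for donors flagged HLA-B Bw6-homozygous whose two HLA-C
#' alleles both carry the epitope motif, the epitope-antibody signal
#' reports both HLA-B copies (plus cross-reactive HLA-C), so the derived
#' ABC is halved. Pan-class-I (W6/32) values are never halved.
#'
#' @param stains Data frame with columns `donor`, `draw`, `subset`,
#'   `antibody`, `mfi`, `isotype_mfi`.
#' @param curve A `calibration_curve`.
#' @param genotypes Data frame with columns `donor`,
#'   `hla_b_bw6_homozygous` and `both_hla_c_epitope` (logical flags).
#' @param epitope_antibodies Antibody labels subject to the correction.
#' @param out_of_range Passed to [interpolate_abc()].
#' @param floor Passed to [subtract_isotype()].
#' @return A tibble, one row per stain record, adding `abc` and the
#'   logical flags `corrected` and `floored`.
#' @export
compute_abc <- function(stains, curve, genotypes,
                        epitope_antibodies = c("anti-Bw6", "anti-Bw4"),
                        out_of_range = "clamp", floor = 0) {
  needed <- c("donor", "draw", "subset", "antibody", "mfi", "isotype_mfi")
  stopifnot(is.data.frame(stains), all(needed %in% names(stains)))
  if (anyNA(stains$isotype_mfi)) {
    stop("every specific record needs a paired isotype MFI", call. = FALSE)
  }
  sub <- subtract_isotype(stains$mfi, stains$isotype_mfi, floor = floor)
  abc <- interpolate_abc(curve, sub$mfi, out_of_range = out_of_range)

  flags <- genotypes |>
    dplyr::distinct(.data$donor, .data$hla_b_bw6_homozygous,
                    .data$both_hla_c_epitope)
  out <- stains |>
    tibble::as_tibble() |>
    dplyr::mutate(abc = abc, floored = sub$floored) |>
    dplyr::left_join(flags, by = "donor") |>
    dplyr::mutate(
      corrected = .data$antibody %in% epitope_antibodies &
        dplyr::coalesce(.data$hla_b_bw6_homozygous, FALSE) &
        dplyr::coalesce(.data$both_hla_c_epitope, FALSE),
      abc = ifelse(.data$corrected, 0.5 * .data$abc, .data$abc)
    ) |>
    dplyr::select(-dplyr::any_of(c("hla_b_bw6_homozygous",
                                   "both_hla_c_epitope")))
  out
}

#' Aggregate per-draw ABC values into donor-level summaries
#'
#' One row per donor/subset/antibody with the mean ABC over independent
#' blood draws, SEM = sd/sqrt(N) (0 and flagged when N = 1), and N.
#'
#' @param abc_table Output of [compute_abc()] (or any table with `donor`,
#'   `subset`, `antibody`, `abc`).
#' @return A tibble with `mean_abc`, `sem`, `n`, `single_draw` and
#'   `corrected` (any draw corrected) per donor/subset/antibody.
#' @export
aggregate_donor <- function(abc_table) {
  stopifnot(nrow(abc_table) >= 1)
  if (!"corrected" %in% names(abc_table)) abc_table$corrected <- FALSE
  abc_table |>
    dplyr::group_by(.data$donor, .data$subset, .data$antibody) |>
    dplyr::summarise(
      mean_abc = mean(.data$abc),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$abc) / sqrt(dplyr::n()), 0),
      n = dplyr::n(),
      single_draw = dplyr::n() == 1L,
      corrected = any(.data$corrected),
      .groups = "drop"
    )
}

#' Epitope / pan-class-I ABC ratio
#'
#' Per donor and subset, the ratio of the epitope-antibody ABC (anti-Bw6
#' or anti-Bw4) to the pan-class-I (W6/32) ABC; computed on per-donor
#' means (ratio of averages).
#'
#' @param donor_abc Output of [aggregate_donor()].
#' @param epitope_antibody,pan_antibody Antibody labels to ratio.
#' @return A tibble with `donor`, `subset`, `epitope_abc`, `pan_abc`,
#'   `ratio`.
#' @export
epitope_ratio <- function(donor_abc, epitope_antibody = "anti-Bw6",
                          pan_antibody = "W6/32") {
  wide <- donor_abc |>
    dplyr::filter(.data$antibody %in% c(epitope_antibody, pan_antibody)) |>
    dplyr::select("donor", "subset", "antibody", "mean_abc") |>
    tidyr::pivot_wider(names_from = "antibody", values_from = "mean_abc")
  if (!all(c(epitope_antibody, pan_antibody) %in% names(wide))) {
    stop("both epitope and pan antibodies must be present", call. = FALSE)
  }
  pan <- wide[[pan_antibody]]
  if (any(!is.na(pan) & pan <= 0)) {
    stop("pan-class-I ABC must be positive to form ratios", call. = FALSE)
  }
  tibble::tibble(
    donor = wide$donor,
    subset = wide$subset,
    epitope_abc = wide[[epitope_antibody]],
    pan_abc = pan,
    ratio = wide[[epitope_antibody]] / pan
  )
}

#' Normalize donor ABC values to a reference cell subset
#'
#' Divides each subset's per-donor ABC by the same donor's value in the
#' reference subset (monocytes in the cross-cell-type comparisons), so
#' the reference row equals 1. Donors lacking the reference subset are
#' kept with `NA` and flagged, not dropped silently.
#'
#' @param donor_abc Output of [aggregate_donor()].
#' @param reference_subset Subset label to normalize against.
#' @return `donor_abc` with added columns `rel_abc` and
#'   `missing_reference`.
#' @export
normalize_to_reference_subset <- function(donor_abc,
                                          reference_subset = "monocyte") {
  ref <- donor_abc |>
    dplyr::filter(.data$subset == reference_subset) |>
    dplyr::select("donor", "antibody", ref_abc = "mean_abc")
  out <- donor_abc |>
    dplyr::left_join(ref, by = c("donor", "antibody")) |>
    dplyr::mutate(
      missing_reference = is.na(.data$ref_abc),
      rel_abc = .data$mean_abc / .data$ref_abc
    ) |>
    dplyr::select(-"ref_abc")
  if (any(out$missing_reference)) {
    warning(sprintf("%d row(s) lack a %s reference value",
                    sum(out$missing_reference), reference_subset),
            call. = FALSE)
  }
  out
}
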