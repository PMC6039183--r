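# Ratio summaries (peptide receptivity, surface fraction, tapasin, 2^-dCt)
# and the group-comparison statistics used to rank allotypes: classical
# one-way ANOVA with a configurable pairwise follow-up, Welch's t-test and
# Pearson correlation/OLS. Tests operate on donor-level means (one point
# per donor).

#' Map a p value to a significance tier
#'
#' The conventional star annotation: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001, `"ns"` otherwise.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' Exogenous peptide receptivity ratio (HC10)
#'
#' HC10 stains open (peptide-receptive) class I heavy chains; the ratio
#' of the specific-peptide signal to the matched DMSO/control-peptide
#' signal per donor and subset reports receptivity (1 = no signal).
#'
#' @param specific_mfi,control_mfi MFI vectors; records with
#'   `control_mfi <= 0` are excluded with a warning.
#' @return Numeric ratio vector (NA where excluded).
#' @export
hc10_ratio <- function(specific_mfi, control_mfi) {
  bad <- control_mfi <= 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with non-positive control MFI excluded",
                    sum(bad)), call. = FALSE)
  }
  ifelse(bad, NA_real_, specific_mfi / control_mfi)
}

#' Surface fraction of total HLA class I
#'
#' Ratio of staining on fixed cells (surface only) to fixed and
#' permeabilized cells (surface + intracellular); values below 1
#' indicate an intracellular pool.
#'
#' @param fixed_mfi,fixed_perm_mfi MFI vectors; non-positive
#'   denominators excluded with a warning.
#' @return Numeric ratio vector.
#' @export
surface_fraction <- function(fixed_mfi, fixed_perm_mfi) {
  bad <- fixed_perm_mfi <= 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with non-positive denominator excluded",
                    sum(bad)), call. = FALSE)
  }
  ifelse(bad, NA_real_, fixed_mfi / fixed_perm_mfi)
}

#' Tapasin/pan-class-I staining ratio normalized to a reference subset
#'
#' Per subset, tapasin MFI over W6/32 MFI; each donor's subset values
#' are then divided by that donor's reference-subset (monocyte) ratio,
#' so the reference row equals 1.
#'
#' @param ratios Data frame with columns `donor`, `subset`,
#'   `tapasin_mfi`, `pan_mfi`.
#' @param reference_subset Reference label (default `"monocyte"`).
#' @return Tibble adding `ratio` (tapasin/pan) and `rel_ratio`
#'   (normalized; NA and flagged when the reference is missing).
#' @export
tapasin_ratio <- function(ratios, reference_subset = "monocyte") {
  stopifnot(all(c("donor", "subset", "tapasin_mfi", "pan_mfi")
                %in% names(ratios)))
  if (any(ratios$pan_mfi <= 0)) {
    stop("pan-class-I MFI must be positive", call. = FALSE)
  }
  out <- ratios |>
    tibble::as_tibble() |>
    dplyr::mutate(ratio = .data$tapasin_mfi / .data$pan_mfi)
  ref <- out |>
    dplyr::filter(.data$subset == reference_subset) |>
    dplyr::select("donor", ref_ratio = "ratio")
  out <- out |>
    dplyr::left_join(ref, by = "donor") |>
    dplyr::mutate(missing_reference = is.na(.data$ref_ratio),
                  rel_ratio = .data$ratio / .data$ref_ratio) |>
    dplyr::select(-"ref_ratio")
  if (any(out$missing_reference)) {
    warning("some donors lack the reference subset", call. = FALSE)
  }
  out
}

#' Relative transcript abundance from RT-PCR cycle thresholds
#'
#' `2^-(Ct_target - Ct_reference)`: relative expression of the target
#' versus an endogenous control.
#'
#' @param ct_target,ct_reference Finite cycle-threshold values.
#' @return Numeric vector of 2^-dCt values.
#' @export
expr_2dct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^(-(ct_target - ct_reference))
}

#' One-way ANOVA across groups with pairwise follow-up
#'
#' Classical one-way ANOVA of donor-level values grouped by allele (or
#' subset), with the overall F and p, a configurable pairwise follow-up
#' (Tukey HSD by default, Bonferroni-adjusted pairwise t-tests, or
#' none), and star significance tiers.
#'
#' @param values Numeric vector of donor-level observations.
#' @param group Grouping factor/character of the same length.
#' @param posthoc `"tukey"`, `"bonferroni"` or `"none"`.
#' @return A list with `group_means`, `f`, `p`, `tier`, `pairwise`
#'   (tibble of comparisons with adjusted p and tiers; NULL when
#'   `posthoc = "none"`).
#' @export
one_way_anova <- function(values, group,
                          posthoc = c("tukey", "bonferroni", "none")) {
  posthoc <- match.arg(posthoc)
  stopifnot(length(values) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least 2 groups required", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2)) {
    stop(sprintf("group(s) with fewer than 2 observations: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
         call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("degenerate input: all observations identical", call. = FALSE)
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  means <- tapply(values, group, mean)

  pairwise <- NULL
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    cmp <- rownames(tk)
    pairwise <- tibble::tibble(
      comparison = cmp,
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      method = "tukey",
      tier = significance_tier(tk[, "p adj"])
    )
  } else if (posthoc == "bonferroni") {
    pw <- stats::pairwise.t.test(values, group,
                                 p.adjust.method = "bonferroni",
                                 pool.sd = FALSE)
    long <- as.data.frame(as.table(pw$p.value))
    long <- long[!is.na(long$Freq), ]
    pairwise <- tibble::tibble(
      comparison = paste(long$Var1, long$Var2, sep = "-"),
      diff = NA_real_,
      p_adj = long$Freq,
      method = "bonferroni",
      tier = significance_tier(long$Freq)
    )
  }
  list(
    group_means = tibble::tibble(group = names(means),
                                 mean = as.numeric(means),
                                 n = as.integer(sizes[names(means)])),
    f = f, p = p, tier = significance_tier(p),
    pairwise = pairwise
  )
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p value.
#'
#' @param values_a,values_b Numeric vectors, each with >= 2 values.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`, `tier`.
#' @export
welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(values_a), mean_b = mean(values_b),
                  tier = "ns"))
    }
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b),
       tier = significance_tier(ht$p.value))
}

#' Pearson correlation and ordinary least-squares line
#'
#' @param x,y Paired numeric vectors, at least 3 points, `var(x) > 0`.
#' @return A list with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
pearson_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("at least 3 paired points required", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
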