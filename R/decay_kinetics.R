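# Surface half-life estimation from Brefeldin-A time courses.
# The model is one-phase exponential decay with the plateau constrained to
# zero: y(t) = y0 * exp(-k t), t_half = ln(2)/k. Fits are per series
# (per donor and day), then averaged across independent experiments.

#' Convert a first-order decay rate to a half-life
#'
#' @param k Decay rate per hour, > 0.
#' @return Half-life in hours, `log(2) / k`.
#' @export
halflife_from_rate <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("decay rate k must be finite and positive", call. = FALSE)
  }
  log(2) / k
}

#' Fit one-phase exponential decay with zero plateau
#'
#' Nonlinear least squares of `y = y0 * exp(-k * t)` with `y0, k > 0`
#' and the plateau fixed at exactly zero. Starting values come from the
#' log-linear regression of `log(y)` on `t` over the positive
#' observations; points with MFI <= 0 are retained in the least-squares
#' objective but excluded from the initializer. A series whose
#' initializing slope is non-negative is flagged non-decaying; a fit
#' that fails to converge is returned as a failure record rather than an
#' error, so batch processing continues.
#'
#' @param time_h Hours, >= 0, at least three points including 0.
#' @param mfi Isotype-subtracted geometric MFI at each time point.
#' @param loss `"linear"` (unweighted least squares on the MFI scale,
#'   the default) or `"log"` (least squares on `log(y)`, positive points
#'   only).
#' @return A one-row tibble: `y0`, `k`, `t_half`, `rss`, `fit_ok`,
#'   `non_decaying`.
#' @examples
#' t <- c(0, 2, 4, 8, 24)
#' fit_one_phase_decay(t, 100 * exp(-log(2) / 6 * t))
#' @export
fit_one_phase_decay <- function(time_h, mfi, loss = c("linear", "log")) {
  loss <- match.arg(loss)
  stopifnot(length(time_h) == length(mfi))
  if (length(time_h) < 3) {
    stop("at least 3 time points are required", call. = FALSE)
  }
  if (any(time_h < 0) || is.unsorted(time_h, strictly = TRUE)) {
    stop("time points must be non-negative and strictly increasing",
         call. = FALSE)
  }
  fail <- tibble::tibble(y0 = NA_real_, k = NA_real_, t_half = NA_real_,
                         rss = NA_real_, fit_ok = FALSE,
                         non_decaying = FALSE)

  pos <- mfi > 0
  if (sum(pos) < 2) return(fail)
  init <- stats::lm(log(mfi[pos]) ~ time_h[pos])
  slope0 <- unname(stats::coef(init)[2L])
  if (!is.finite(slope0) || slope0 >= 0) {
    fail$non_decaying <- TRUE
    return(fail)
  }
  start <- list(y0 = exp(unname(stats::coef(init)[1L])), k = -slope0)

  dat <- data.frame(t = time_h, y = mfi)
  fit <- tryCatch({
    if (loss == "linear") {
      minpack.lm::nlsLM(y ~ y0 * exp(-k * t), data = dat, start = start,
                        lower = c(y0 = .Machine$double.eps,
                                  k = .Machine$double.eps),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      dpos <- dat[dat$y > 0, ]
      minpack.lm::nlsLM(log(y) ~ log(y0) - k * t, data = dpos, start = start,
                        lower = c(y0 = .Machine$double.eps,
                                  k = .Machine$double.eps),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail)

  co <- stats::coef(fit)
  if (co[["k"]] <= .Machine$double.eps * 2) {
    fail$non_decaying <- TRUE
    return(fail)
  }
  pred <- co[["y0"]] * exp(-co[["k"]] * time_h)
  tibble::tibble(
    y0 = co[["y0"]], k = co[["k"]],
    t_half = halflife_from_rate(co[["k"]]),
    rss = sum((mfi - pred)^2),
    fit_ok = TRUE, non_decaying = FALSE
  )
}

#' Fit decay series from a long-format table
#'
#' Applies [fit_one_phase_decay()] per group (donor/draw/subset/antibody
#' by default, or `series` if present), returning one row per series.
#'
#' @param decay Data frame with `time_h`, `mfi` and grouping columns.
#' @param group_cols Columns identifying one series.
#' @param loss Passed to [fit_one_phase_decay()].
#' @return Tibble of per-series fit results.
#' @export
fit_decay_table <- function(decay,
                            group_cols = intersect(
                              c("series", "donor", "draw", "subset",
                                "antibody"), names(decay)),
                            loss = "linear") {
  stopifnot(all(c("time_h", "mfi") %in% names(decay)),
            length(group_cols) >= 1)
  decay |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(~ fit_one_phase_decay(.x$time_h, .x$mfi,
                                              loss = loss)) |>
    dplyr::ungroup()
}

#' Aggregate half-life fits per donor and apply the QC inclusion rule
#'
#' Half-lives from independent experiments are averaged per
#' donor/subset/antibody. A donor passes QC only with n >= 2 successful
#' fits and SEM/mean below 0.33; donors whose fits all failed are
#' excluded (reported in the `excluded` attribute).
#'
#' @param fits Output of [fit_decay_table()].
#' @param sem_fraction QC threshold on SEM/mean (default 0.33).
#' @return Tibble with `mean_t_half`, `sem`, `n`, `qc_pass` per
#'   donor/subset/antibody (or per remaining grouping columns).
#' @export
aggregate_halflives <- function(fits, sem_fraction = 0.33) {
  group_cols <- intersect(c("donor", "subset", "antibody"), names(fits))
  if (length(group_cols) == 0) {
    fits$donor <- "all"
    group_cols <- "donor"
  }
  ok <- fits |> dplyr::filter(.data$fit_ok)
  excluded <- fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(n_ok = sum(.data$fit_ok), .groups = "drop") |>
    dplyr::filter(.data$n_ok == 0)
  out <- ok |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      mean_t_half = mean(.data$t_half),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$t_half) / sqrt(dplyr::n()), 0),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      qc_pass = .data$n >= 2 & .data$sem / .data$mean_t_half < sem_fraction
    )
  attr(out, "excluded") <- excluded
  out
}
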