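#' Analysis configuration for period-over-period comparison
#'
#' Fixes the window geometry of the analysis: the focal window is the
#' `period_length_weeks` calendar weeks starting with the week containing
#' `focal_start_date`; the comparison window is either the same number of
#' weeks immediately preceding it (`"previous_period"`) or the same weeks
#' shifted back `year_length_weeks` weeks (`"same_period_previous_year"`).
#' The year shift is in whole weeks (default 52) rather than 365 days so both
#' windows stay aligned to calendar-week boundaries.
#'
#' @param period_length_weeks weeks per window; 29 is the span of the NC
#'   COVID-19 state-of-emergency period (2020-03-10 to 2020-09-30) that
#'   motivates the default.
#' @param focal_start_date first day of the focal period.
#' @param year_length_weeks whole-week year shift for the seasonal mode.
#' @param data_start,data_end bounds of the weekly series the windows must
#'   fit inside.
#' @param week_rule `"iso"` or `"mmwr"`.
#' @return validated `analysis_config` list. Its `focal_window` element is the
#'   `Date` vector of the focal window's week starts.
#' @export
analysis_config <- function(period_length_weeks = 29L,
                            focal_start_date = as.Date("2020-03-10"),
                            year_length_weeks = 52L,
                            data_start = as.Date("2014-01-01"),
                            data_end = as.Date("2020-09-30"),
                            week_rule = c("iso", "mmwr")) {
  week_rule <- match.arg(week_rule)
  period_length_weeks <- as.integer(period_length_weeks)
  year_length_weeks <- as.integer(year_length_weeks)
  focal_start_date <- as.Date(focal_start_date)
  data_start <- as.Date(data_start)
  data_end <- as.Date(data_end)
  if (period_length_weeks < 1L) {
    stop("`period_length_weeks` must be >= 1.", call. = FALSE)
  }
  focal_first <- week_start(focal_start_date, week_rule)
  focal <- seq(focal_first, by = 7L, length.out = period_length_weeks)
  if (focal_first < data_start || max(focal) + 6L > data_end) {
    stop("focal window does not fit inside [data_start, data_end].",
         call. = FALSE)
  }
  structure(
    list(
      period_length_weeks = period_length_weeks,
      focal_start_date = focal_start_date,
      year_length_weeks = year_length_weeks,
      data_start = data_start, data_end = data_end,
      week_rule = week_rule,
      focal_window = focal
    ),
    class = "analysis_config"
  )
}

# a window is the Date of its first week's start plus a length in weeks;
# helpers below keep that representation in one place
window_weeks <- function(start, n_weeks) {
  seq(start, by = 7L, length.out = n_weeks)
}

#' Mean weekly count over a window
#'
#' @param weekly a `weekly_counts` tibble (see [aggregate_weekly()]).
#' @param outcome one of `"runs"`, `"naloxone_administrations"`,
#'   `"multiple_naloxone_administrations"`.
#' @param window_start `Date`: week start of the window's first week.
#' @param n_weeks window length in whole weeks.
#' @return arithmetic mean of the window's weekly counts.
#' @export
period_mean <- function(weekly, outcome, window_start, n_weeks) {
  wks <- window_weeks(window_start, n_weeks)
  idx <- match(wks, weekly$week_start)
  if (anyNA(idx)) {
    stop("window weeks missing from series: ",
         paste(format(wks[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mean(weekly[[outcome]][idx])
}

#' Period-over-period percent change
#'
#' \eqn{\Delta_p = (p_t - p_{t-1}) / p_{t-1}}, returned as a percentage:
#' `100 * (p_t - p_t_minus_1) / p_t_minus_1`.
#'
#' @param p_t mean weekly count in the primary window.
#' @param p_t_minus_1 mean weekly count in the comparison window; must be
#'   positive for the change to be defined.
#' @return percent change (vectorized).
#' @examples
#' pop_change(25.6, 20.6)  # 24.3% at one decimal
#' @export
pop_change <- function(p_t, p_t_minus_1) {
  if (any(p_t_minus_1 <= 0)) {
    stop("period-over-period change undefined: comparison-period mean <= 0.",
         call. = FALSE)
  }
  100 * (p_t - p_t_minus_1) / p_t_minus_1
}

#' Comparison window for a primary window
#'
#' @param primary_start `Date`: week start of the primary window.
#' @param mode `"previous_period"` or `"same_period_previous_year"`.
#' @param config an [analysis_config()].
#' @return `Date`: week start of the comparison window (same length as the
#'   primary window).
#' @export
comparison_window_for <- function(primary_start,
                                  mode = c("previous_period",
                                           "same_period_previous_year"),
                                  config) {
  mode <- match.arg(mode)
  shift <- switch(mode,
    previous_period = config$period_length_weeks,
    same_period_previous_year = config$year_length_weeks
  )
  primary_start - 7L * shift
}

# week starts of all complete weeks in the series, with contiguity check
complete_weeks <- function(weekly) {
  ws <- weekly$week_start[weekly$complete]
  if (length(ws) > 1 && any(diff(as.numeric(ws)) != 7)) {
    stop("complete weeks of the series are not contiguous.", call. = FALSE)
  }
  ws
}

#' Enumerate the sliding-window quasi-control distribution
#'
#' Slides a primary window of `period_length_weeks` back one calendar week at
#' a time over the pre-focal history and records each window's
#' period-over-period change against its comparison window. A start week is
#' admissible when (i) both windows consist only of complete weeks inside the
#' data, and (ii) the primary window ends strictly before the start of the
#' focal week. The number of control observations therefore has the closed
#' form `W - span + 1`, with `W` the number of complete pre-focal weeks and
#' `span` equal to twice the period length (previous-period mode) or period
#' length + year length (year-over-year mode).
#'
#' Control observations whose comparison-window mean is zero have no defined
#' change and are dropped with a warning (possible for the rare
#' multiple-naloxone outcome in sparse data).
#'
#' @param weekly a `weekly_counts` tibble covering
#'   `[config$data_start, config$data_end]`.
#' @param outcome outcome column name.
#' @param mode comparison mode.
#' @param config an [analysis_config()].
#' @return tibble of class `pop_controls`, one row per control observation,
#'   ordered by primary window start: `primary_start`, `primary_end`,
#'   `comparison_start`, `comparison_end`, `p_t`, `p_t_minus_1`,
#'   `delta_pct`; attributes `outcome` and `mode`.
#' @export
enumerate_controls <- function(weekly, outcome,
                               mode = c("previous_period",
                                        "same_period_previous_year"),
                               config) {
  mode <- match.arg(mode)
  ws <- complete_weeks(weekly)
  n <- config$period_length_weeks
  shift <- if (mode == "previous_period") n else config$year_length_weeks
  focal_first <- config$focal_window[1]
  # admissible primary starts: comparison window inside complete weeks,
  # primary window ending strictly before the focal week start
  starts <- ws[ws - 7L * shift >= min(ws) &
                 ws + 7L * (n - 1L) + 6L < focal_first &
                 ws + 7L * (n - 1L) <= max(ws)]
  if (length(starts) < 1L) {
    stop("no admissible control window: the series is shorter than one ",
         "full primary + comparison span before the focal period.",
         call. = FALSE)
  }
  counts <- weekly[[outcome]][match(ws, weekly$week_start)]
  csum <- cumsum(c(0, counts))
  win_mean <- function(start) {
    i <- match(start, ws)
    (csum[i + n] - csum[i]) / n
  }
  p_t <- vapply(starts, win_mean, numeric(1))
  comp <- starts - 7L * shift
  p_t1 <- vapply(comp, win_mean, numeric(1))
  undefined <- p_t1 <= 0
  if (any(undefined)) {
    warning(sum(undefined), " control window(s) dropped: ",
            "comparison-period mean is zero.", call. = FALSE)
  }
  out <- tibble::tibble(
    primary_start = starts,
    primary_end = starts + 7L * (n - 1L) + 6L,
    comparison_start = comp,
    comparison_end = comp + 7L * (n - 1L) + 6L,
    p_t = p_t,
    p_t_minus_1 = p_t1,
    delta_pct = ifelse(undefined, NA_real_, 100 * (p_t - p_t1) / p_t1)
  )[!undefined, ]
  attr(out, "outcome") <- outcome
  attr(out, "mode") <- mode
  class(out) <- c("pop_controls", class(out))
  out
}

#' Focal-period comparison
#'
#' Computes the focal (e.g. COVID-19) window's mean, its comparison window's
#' mean, and the period-over-period percent change, under the given mode.
#'
#' @inheritParams enumerate_controls
#' @return one-row tibble with the same columns as [enumerate_controls()].
#' @export
focal_comparison <- function(weekly, outcome,
                             mode = c("previous_period",
                                      "same_period_previous_year"),
                             config) {
  mode <- match.arg(mode)
  n <- config$period_length_weeks
  fstart <- config$focal_window[1]
  cstart <- comparison_window_for(fstart, mode, config)
  p_t <- period_mean(weekly, outcome, fstart, n)
  p_t1 <- period_mean(weekly, outcome, cstart, n)
  tibble::tibble(
    primary_start = fstart,
    primary_end = fstart + 7L * (n - 1L) + 6L,
    comparison_start = cstart,
    comparison_end = cstart + 7L * (n - 1L) + 6L,
    p_t = p_t,
    p_t_minus_1 = p_t1,
    delta_pct = pop_change(p_t, p_t1)
  )
}

#' Percentile of a focal change within the quasi-control distribution
#'
#' Places the focal period-over-period change within the empirical
#' distribution of historical changes: `100 * #(controls < focal) / #controls`
#' under the default strict-less rule. `ties = "midrank"` gives ties half
#' weight instead.
#'
#' @param delta_focal focal change, in percent (same scale as `delta_pct`).
#' @param controls a `pop_controls` tibble (or numeric vector of control
#'   changes in percent).
#' @param ties `"strict"` (default) or `"midrank"`.
#' @return percentile in `[0, 100]`.
#' @export
percentile_of <- function(delta_focal, controls, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  d <- if (is.data.frame(controls)) controls$delta_pct else as.numeric(controls)
  if (length(d) == 0) {
    stop("empty control distribution.", call. = FALSE)
  }
  below <- sum(d < delta_focal)
  if (ties == "midrank") below <- below + sum(d == delta_focal) / 2
  100 * below / length(d)
}

#' Write the control-distribution CSV
#'
#' One row per control observation (window bounds, means, change in percent),
#' the canonical tabular output behind the figure-style bar series.
#'
#' @param controls a `pop_controls` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_controls <- function(controls, path) {
  out <- tibble::as_tibble(controls)
  out$outcome <- attr(controls, "outcome")
  out$comparison_mode <- attr(controls, "mode")
  readr::write_csv(out, path)
  invisible(path)
}
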