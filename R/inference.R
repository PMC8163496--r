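#' Welch unequal-variances t test from summary statistics
#'
#' Two-sample t test without the equal-variance assumption, computed directly
#' from group means, standard deviations, and sizes — the form needed when
#' only published summary statistics are available:
#' \deqn{t = \frac{m_1 - m_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with Welch–Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'   {\frac{(s_1^2/n_1)^2}{n_1-1} + \frac{(s_2^2/n_2)^2}{n_2-1}}}
#' and a two-tailed p-value from the Student-t distribution function.
#'
#' @param mean1,sd1,n1 first group's mean, SD, and size (`n1 >= 2`).
#' @param mean2,sd2,n2 second group's summaries.
#' @return object of class `welch_test` with elements `t_statistic`, `df`
#'   (non-integer in general), `p_value`, `p_rendered` (journal style:
#'   3 decimals, `"<.001"` below 0.0005), and `group_summaries`.
#' @examples
#' welch_test(25.6, 5.6, 29, 20.6, 6.5, 29)  # p renders as .003
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    stop("degenerate input: both group variances are zero.", call. = FALSE)
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(
      t_statistic = t_stat,
      df = df,
      p_value = p,
      p_rendered = render_p(p),
      group_summaries = list(
        group1 = c(mean = mean1, sd = sd1, n = n1),
        group2 = c(mean = mean2, sd = sd2, n = n2)
      )
    ),
    class = "welch_test"
  )
}

#' @rdname welch_test
#' @param x,y numeric vectors of weekly counts (e.g. the focal and comparison
#'   windows of a weekly series); summaries are computed and passed to
#'   [welch_test()].
#' @export
welch_test_counts <- function(x, y) {
  welch_test(mean(x), stats::sd(x), length(x),
             mean(y), stats::sd(y), length(y))
}

#' @export
print.welch_test <- function(x, ...) {
  g <- x$group_summaries
  cat(sprintf(
    "Welch two-sample t test\n  group 1: mean %.2f, SD %.2f, n %d\n  group 2: mean %.2f, SD %.2f, n %d\n  t = %.3f, df = %.1f, p = %s\n",
    g$group1["mean"], g$group1["sd"], g$group1["n"],
    g$group2["mean"], g$group2["sd"], g$group2["n"],
    x$t_statistic, x$df, x$p_rendered
  ))
  invisible(x)
}

#' Render a p-value in journal style
#'
#' Three decimals without a leading zero; values below 0.001 render as
#' `"<.001"`.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
render_p <- function(p) {
  ifelse(p < 1e-3, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' Classical additive seasonal decomposition of a weekly series
#'
#' Splits a weekly count series into trend (centered moving average over one
#' seasonal cycle), seasonal (per-week-of-cycle mean of the detrended series,
#' centered to sum to zero), and residual components — the classical additive
#' decomposition, delegated to [stats::decompose()]. Used as the diagnostic
#' that motivates the seasonality-adjusted (year-over-year) comparison mode.
#'
#' @param weekly a `weekly_counts` tibble, or a numeric vector of weekly
#'   counts.
#' @param outcome outcome column when `weekly` is a tibble.
#' @param period_weeks length of the seasonal cycle in weeks (default 52).
#' @return tibble with `week_start` (when available), `observed`, `trend`,
#'   `seasonal`, `residual`; `trend` and `residual` are `NA` in the half
#'   cycle at each end where the centered moving average is undefined, and
#'   `observed == trend + seasonal + residual` wherever `trend` is defined.
#' @export
seasonal_decompose <- function(weekly, outcome = "runs", period_weeks = 52L) {
  x <- if (is.data.frame(weekly)) weekly[[outcome]] else as.numeric(weekly)
  if (length(x) < 2L * period_weeks) {
    stop("series too short for decomposition: need at least ",
         2L * period_weeks, " weeks, got ", length(x), ".", call. = FALSE)
  }
  dec <- stats::decompose(stats::ts(x, frequency = period_weeks),
                          type = "additive")
  tibble::tibble(
    week_start = if (is.data.frame(weekly)) weekly$week_start else
      as.Date(NA) + seq_along(x) * 0,
    observed = x,
    trend = as.numeric(dec$trend),
    seasonal = as.numeric(dec$seasonal),
    residual = as.numeric(dec$random)
  )
}

#' Monte-Carlo type-I error of the Welch stage on Poisson weekly counts
#'
#' Draws pairs of independent Poisson weekly-count windows with a common
#' mean, applies [welch_test_counts()], and reports the rejection rate at
#' `alpha`. Weekly counts are not normal, so Welch inference is approximate;
#' this utility measures how close the realized size is to nominal.
#'
#' @param n_pairs number of simulated pairs.
#' @param n_weeks weeks per window (default 29).
#' @param lambda common Poisson mean.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rejection_rate`, `n_pairs`, `alpha`.
#' @export
welch_type1_rate <- function(n_pairs = 2000L, n_weeks = 29L, lambda = 20,
                             alpha = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(stats::rpois(n_pairs * n_weeks, lambda), nrow = n_weeks)
    y <- matrix(stats::rpois(n_pairs * n_weeks, lambda), nrow = n_weeks)
  })
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, stats::var) / n_weeks
  v2 <- apply(y, 2, stats::var) / n_weeks
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 + v2^2) * (n_weeks - 1)
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(rejection_rate = mean(p < alpha), n_pairs = n_pairs, alpha = alpha)
}
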