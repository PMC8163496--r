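# Fixture builders and independent oracles shared across test files.

# Weekly-counts tibble with constant or per-week counts for every calendar
# week intersecting [start_date, end_date]; nesting of the three outcomes is
# the caller's responsibility.
make_weekly <- function(runs, start_date, end_date,
                        naloxone = NULL, multiple = NULL) {
  ws <- week_seq(as.Date(start_date), as.Date(end_date))
  runs <- rep_len(runs, length(ws))
  naloxone <- if (is.null(naloxone)) runs else rep_len(naloxone, length(ws))
  multiple <- if (is.null(multiple)) naloxone else rep_len(multiple, length(ws))
  out <- tibble::tibble(
    iso_year = as.integer(format(ws + 3L, "%G")),
    iso_week = as.integer(format(ws + 3L, "%V")),
    week_start = ws,
    complete = ws >= as.Date(start_date) & (ws + 6L) <= as.Date(end_date),
    runs = as.integer(runs),
    naloxone_administrations = as.integer(naloxone),
    multiple_naloxone_administrations = as.integer(multiple)
  )
  class(out) <- c("weekly_counts", class(out))
  out
}

# Analysis config whose focal window is the LAST `period` complete weeks of a
# series starting at `start_date` with `n_weeks` complete weeks, so that the
# remaining history is exactly `n_weeks - period` weeks.
tail_focal_config <- function(start_date, n_weeks, period,
                              year_length_weeks = 52L) {
  s0 <- week_start(as.Date(start_date))
  analysis_config(
    period_length_weeks = period,
    focal_start_date = s0 + 7L * (n_weeks - period),
    year_length_weeks = year_length_weeks,
    data_start = s0,
    data_end = s0 + 7L * n_weeks - 1L
  )
}

# Brute-force control enumeration: naive scan over every week start,
# independent of the cumulative-sum implementation in enumerate_controls().
brute_force_controls <- function(weekly, outcome, mode, config) {
  ws <- weekly$week_start[weekly$complete]
  n <- config$period_length_weeks
  shift <- if (mode == "previous_period") n else config$year_length_weeks
  deltas <- c()
  starts <- as.Date(character())
  for (i in seq_along(ws)) {
    s <- ws[i]
    prim <- seq(s, by = 7L, length.out = n)
    comp <- prim - 7L * shift
    if (!all(prim %in% ws) || !all(comp %in% ws)) next
    if (max(prim) + 6L >= config$focal_window[1]) next
    p_t <- mean(weekly[[outcome]][match(prim, weekly$week_start)])
    p_t1 <- mean(weekly[[outcome]][match(comp, weekly$week_start)])
    if (p_t1 <= 0) next
    starts <- c(starts, s)
    deltas <- c(deltas, 100 * (p_t - p_t1) / p_t1)
  }
  tibble::tibble(primary_start = starts, delta_pct = deltas)
}

# Weekly series straight from simulated run tuples (no record explosion),
# for tests that only need the aggregate stage.
runs_to_weekly <- function(runs, cfg) {
  aggregate_weekly(
    tibble::tibble(incident_date = runs$incident_date,
                   naloxone_count = runs$n_naloxone_doses),
    cfg$start_date, cfg$end_date
  )
}

# Flat simulation config: no seasonality, no trend, optional step.
flat_config <- function(baseline = 20, start = "2019-08-19",
                        end = "2020-09-27", step_date = NULL,
                        step_multiplier = 1, seed = 1L, ...) {
  sim_config(
    start_date = as.Date(start), end_date = as.Date(end),
    baseline_weekly_mean = baseline,
    seasonal_amplitude = 0,
    trend_knots = data.frame(date = as.Date(start), multiplier = 1),
    step_date = if (is.null(step_date)) NULL else as.Date(step_date),
    step_multiplier = step_multiplier,
    seed = seed, ...
  )
}
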