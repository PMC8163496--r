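#' Simulation configuration for synthetic EMS overdose data
#'
#' Builds and validates the configuration driving the synthetic record
#' generator. The generator emulates a deidentified county EMS extract of
#' opioid overdose-related runs: weekly run counts follow a seasonal,
#' trending, optionally overdispersed counting process with an optional step
#' change at a "state of emergency" date, and each run carries the
#' demographic fields (incident date, birth date, gender) from which a
#' quasi-unique run identifier can be reconstructed downstream.
#'
#' The weekly intensity for the week with mid-date \eqn{d} is
#' \deqn{\lambda_w = \mu \cdot \mathrm{trend}(d) \cdot
#'   (1 + a \sin(2\pi(\mathrm{yearfrac}(d) + \phi))) \cdot
#'   m^{[d \ge d_{step}]}}
#' where \eqn{\mu} is `baseline_weekly_mean`, \eqn{a} the seasonal amplitude,
#' \eqn{\phi} the phase, and \eqn{m} the step multiplier. The seasonal cycle
#' has period 365.25 days; with `seasonal_phase = 0` it peaks around 1 April.
#'
#' @param start_date,end_date `Date` (or ISO-8601 string) bounds of the
#'   simulated extract, inclusive.
#' @param baseline_weekly_mean expected opioid-related runs per week before
#'   trend/season/step modulation. Default 20, the approximate weekly scale of
#'   a large metropolitan county EMS system.
#' @param seasonal_amplitude relative yearly sinusoidal modulation in `[0, 1)`.
#' @param seasonal_phase phase offset in fractions of a year.
#' @param trend_knots data frame with columns `date` and `multiplier`:
#'   piecewise-linear intensity multiplier interpolated between knots and held
#'   constant beyond the outer knots. Default rises to mid-2017 then declines
#'   through 2019 and flattens, the historical shape of county opioid
#'   overdose series over 2014-2020.
#' @param step_date `Date` at which a step change in intensity applies, or
#'   `NULL` for none.
#' @param step_multiplier positive multiplier applied on/after `step_date`.
#' @param dispersion negative-binomial size parameter (variance
#'   \eqn{\lambda + \lambda^2/\theta}); `NULL` for Poisson counts.
#' @param naloxone_dose_probs length-4 probability vector over per-run
#'   naloxone dose counts 0, 1, 2, 3. Default `c(.15, .60, .18, .07)`, an
#'   illustrative mixture in which roughly a quarter of dosed runs receive
#'   multiple doses; the real distribution is not published.
#' @param birth_date_pool_size number of distinct patient birth dates to draw
#'   from. The default (20000) makes (incident date, birth date, gender)
#'   collisions rare (well under 0.1% of runs); shrink it to stress-test run
#'   deduplication.
#' @param seed integer seed; every sampling function is run under this seed so
#'   identical configurations reproduce byte-identical output.
#' @return a validated `sim_config` list.
#' @seealso [simulate_runs()], [runs_to_records()]
#' @export
sim_config <- function(start_date = as.Date("2014-01-01"),
                       end_date = as.Date("2020-09-30"),
                       baseline_weekly_mean = 20,
                       seasonal_amplitude = 0.15,
                       seasonal_phase = 0,
                       trend_knots = default_trend_knots(),
                       step_date = as.Date("2020-03-10"),
                       step_multiplier = 1.5,
                       dispersion = NULL,
                       naloxone_dose_probs = c(0.15, 0.60, 0.18, 0.07),
                       birth_date_pool_size = 20000L,
                       seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (!is.null(step_date)) step_date <- as.Date(step_date)
  if (!(start_date < end_date)) {
    stop("`start_date` must precede `end_date`.", call. = FALSE)
  }
  if (!is.numeric(baseline_weekly_mean) || baseline_weekly_mean <= 0) {
    stop("`baseline_weekly_mean` must be a positive number.", call. = FALSE)
  }
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("`seasonal_amplitude` must lie in [0, 1).", call. = FALSE)
  }
  if (!is.null(step_date) && step_multiplier <= 0) {
    stop("`step_multiplier` must be positive.", call. = FALSE)
  }
  if (!is.null(dispersion) && dispersion <= 0) {
    stop("`dispersion` must be positive (or NULL for Poisson).", call. = FALSE)
  }
  if (length(naloxone_dose_probs) != 4 || any(naloxone_dose_probs < 0) ||
      abs(sum(naloxone_dose_probs) - 1) > 1e-9) {
    stop("`naloxone_dose_probs` must be 4 non-negative values summing to 1.",
         call. = FALSE)
  }
  trend_knots <- as.data.frame(trend_knots)
  stopifnot(all(c("date", "multiplier") %in% names(trend_knots)))
  trend_knots$date <- as.Date(trend_knots$date)
  trend_knots <- trend_knots[order(trend_knots$date), ]
  if (any(trend_knots$multiplier <= 0)) {
    stop("trend multipliers must be positive.", call. = FALSE)
  }
  structure(
    list(
      start_date = start_date, end_date = end_date,
      baseline_weekly_mean = baseline_weekly_mean,
      seasonal_amplitude = seasonal_amplitude,
      seasonal_phase = seasonal_phase,
      trend_knots = trend_knots,
      step_date = step_date, step_multiplier = step_multiplier,
      dispersion = dispersion,
      naloxone_dose_probs = naloxone_dose_probs,
      birth_date_pool_size = as.integer(birth_date_pool_size),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default piecewise-linear trend: rise to mid-2017, decline through 2019,
#' then flat.
#' @return data frame of `date`, `multiplier` knots.
#' @export
default_trend_knots <- function() {
  data.frame(
    date = as.Date(c("2014-01-01", "2017-07-01", "2019-12-31")),
    multiplier = c(0.75, 1.25, 0.90)
  )
}

# fraction of the 365.25-day seasonal cycle elapsed at `dates`,
# anchored at 2000-01-01 so the same calendar date always maps to
# (almost) the same phase regardless of the simulated range
year_fraction <- function(dates) {
  (as.numeric(dates - as.Date("2000-01-01")) %% 365.25) / 365.25
}

trend_multiplier <- function(dates, knots) {
  if (nrow(knots) == 1L) return(rep(knots$multiplier, length(dates)))
  stats::approx(
    x = as.numeric(knots$date), y = knots$multiplier,
    xout = as.numeric(dates), rule = 2
  )$y
}

#' Deterministic weekly intensity schedule
#'
#' Evaluates the expected weekly run count for every calendar week
#' intersecting the configured date range. No randomness is involved; this is
#' the mean structure the stochastic generator draws around. Boundary weeks
#' only partially inside the range have their intensity scaled by the covered
#' fraction of the week.
#'
#' @param config a [sim_config()].
#' @param week_rule week convention passed to [week_seq()].
#' @return tibble with `week_start`, `days_covered`, and `intensity` columns.
#' @examples
#' cfg <- sim_config(seasonal_amplitude = 0, step_date = NULL,
#'                   trend_knots = data.frame(date = as.Date("2014-01-01"),
#'                                            multiplier = 1))
#' simulate_weekly_intensity(cfg)  # constant baseline_weekly_mean
#' @export
simulate_weekly_intensity <- function(config, week_rule = c("iso", "mmwr")) {
  stopifnot(inherits(config, "sim_config"))
  week_rule <- match.arg(week_rule)
  ws <- week_seq(config$start_date, config$end_date, week_rule)
  mid <- ws + 3L
  lambda <- config$baseline_weekly_mean *
    trend_multiplier(mid, config$trend_knots) *
    (1 + config$seasonal_amplitude *
       sin(2 * pi * (year_fraction(mid) + config$seasonal_phase)))
  if (!is.null(config$step_date)) {
    lambda <- lambda * ifelse(mid >= config$step_date, config$step_multiplier, 1)
  }
  if (any(lambda <= 0)) {
    stop("configuration yields non-positive weekly intensity; ",
         "check amplitude and trend multipliers.", call. = FALSE)
  }
  cover_from <- pmax(ws, config$start_date)
  cover_to <- pmin(ws + 6L, config$end_date)
  days <- as.integer(cover_to - cover_from) + 1L
  tibble::tibble(
    week_start = ws,
    days_covered = days,
    intensity = lambda * days / 7
  )
}

#' Simulate run-level EMS overdose data
#'
#' Draws weekly run counts around the [simulate_weekly_intensity()] schedule
#' (Poisson, or negative binomial when `dispersion` is set), then assigns each
#' run an incident date uniform within its week, patient demographics, a
#' naloxone dose count from the configured mixture, and primary/secondary
#' clinical impression codes. All runs are opioid overdose-related, as in a
#' pre-filtered county extract; with probability 0.2 the opioid code appears
#' only in the secondary impression, exercising the classifier's OR rule.
#'
#' @param config a [sim_config()].
#' @param week_rule week convention.
#' @return tibble of runs: `incident_date`, `birth_date`, `gender`,
#'   `n_naloxone_doses`, `primary_impression`, `secondary_impression`, with the
#'   drawn weekly counts attached as attribute `"weekly_truth"` (tibble of
#'   `week_start`, `n_runs`) — the ground truth the ingest stage should
#'   recover.
#' @export
simulate_runs <- function(config, week_rule = c("iso", "mmwr")) {
  stopifnot(inherits(config, "sim_config"))
  week_rule <- match.arg(week_rule)
  sched <- simulate_weekly_intensity(config, week_rule)
  vocab <- default_impression_vocabulary()
  distractors <- c("Altered Mental Status", "Respiratory Distress",
                   "Unconscious / Unresponsive", "Cardiac Arrest")
  withr::with_seed(config$seed, {
    n_w <- if (is.null(config$dispersion)) {
      stats::rpois(nrow(sched), sched$intensity)
    } else {
      stats::rnbinom(nrow(sched), size = config$dispersion, mu = sched$intensity)
    }
    total <- sum(n_w)
    wk <- rep(seq_len(nrow(sched)), n_w)
    # incident dates uniform over each week's covered days
    lo <- pmax(sched$week_start, config$start_date)[wk]
    incident <- lo + floor(stats::runif(total) * sched$days_covered[wk])
    # birth-date pool bounded above at 1998 so patients are adults for any
    # incident date in range; pool size controls identifier-collision rate
    pool <- as.Date("1998-12-31") -
      sample.int(17500L, config$birth_date_pool_size, replace = TRUE)
    birth <- sample(pool, total, replace = TRUE)
    gender <- sample(c("M", "F", "U"), total, replace = TRUE,
                     prob = c(0.60, 0.38, 0.02))
    doses <- sample(0:3, total, replace = TRUE, prob = config$naloxone_dose_probs)
    opioid_primary <- stats::runif(total) < 0.8
    primary <- ifelse(opioid_primary,
                      sample(vocab, total, replace = TRUE),
                      sample(distractors, total, replace = TRUE))
    secondary <- ifelse(opioid_primary,
                        sample(c("", distractors), total, replace = TRUE),
                        sample(vocab, total, replace = TRUE))
    runs <- tibble::tibble(
      incident_date = incident,
      birth_date = birth,
      gender = gender,
      n_naloxone_doses = doses,
      primary_impression = primary,
      secondary_impression = secondary
    )
  })
  attr(runs, "weekly_truth") <- tibble::tibble(
    week_start = sched$week_start, n_runs = n_w
  )
  runs
}

#' Explode runs into treatment-level records
#'
#' Inverse of the ingest stage's grouping: a run with `k >= 1` naloxone doses
#' emits `k` naloxone rows; a run with no naloxone emits a single row for a
#' non-naloxone treatment. All rows of a run share its identifier fields.
#'
#' @param runs tibble from [simulate_runs()] (or any tibble with the same
#'   columns).
#' @return tibble of treatment records with columns `incident_date`,
#'   `patient_birth_date`, `patient_gender`, `primary_impression`,
#'   `secondary_impression`, `medication`.
#' @export
runs_to_records <- function(runs) {
  stopifnot(all(runs$n_naloxone_doses >= 0))
  n_rows <- pmax(runs$n_naloxone_doses, 1L)
  idx <- rep(seq_len(nrow(runs)), n_rows)
  naloxone_forms <- c("Naloxone", "NARCAN", "Naloxone HCl")
  med <- ifelse(
    rep(runs$n_naloxone_doses >= 1, n_rows),
    naloxone_forms[1L + idx %% length(naloxone_forms)],
    "Oxygen"
  )
  tibble::tibble(
    incident_date = runs$incident_date[idx],
    patient_birth_date = runs$birth_date[idx],
    patient_gender = runs$gender[idx],
    primary_impression = runs$primary_impression[idx],
    secondary_impression = runs$secondary_impression[idx],
    medication = med
  )
}

#' Write treatment records and a sidecar metadata file
#'
#' Writes the treatment-record CSV schema consumed by
#' [read_treatment_records()] (ISO-8601 dates, UTF-8, header row) plus a
#' `<path>.meta.json`-style sidecar echoing the generating configuration.
#'
#' @param records tibble from [runs_to_records()].
#' @param path output CSV path.
#' @param config the generating [sim_config()], echoed to the sidecar; `NULL`
#'   skips the sidecar.
#' @return `path`, invisibly.
#' @export
write_treatment_records <- function(records, path, config = NULL) {
  readr::write_csv(records, path)
  if (!is.null(config)) {
    meta <- unclass(config)
    meta$trend_knots <- data.frame(
      date = format(config$trend_knots$date),
      multiplier = config$trend_knots$multiplier
    )
    for (fld in c("start_date", "end_date", "step_date")) {
      if (!is.null(meta[[fld]])) meta[[fld]] <- format(meta[[fld]])
    }
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
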