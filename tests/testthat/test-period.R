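test_that("period_mean averages exactly the requested window", {
  wk <- make_weekly(10, "2019-01-07", "2019-12-29")
  expect_equal(period_mean(wk, "runs", as.Date("2019-01-07"), 29), 10)

  set.seed(1)
  counts <- rpois(40, 7)
  wk2 <- make_weekly(counts, "2019-01-07", as.character(as.Date("2019-01-07") + 40 * 7 - 1))
  s <- wk2$week_start[5]
  expect_equal(period_mean(wk2, "runs", s, 29), sum(counts[5:33]) / 29)
  expect_error(period_mean(wk2, "runs", as.Date("2019-01-06"), 29), "missing")
})

test_that("pop_change is the percent form of (p_t - p_t-1)/p_t-1", {
  expect_equal(round(pop_change(25.6, 20.6), 1), 24.3)
  expect_equal(round(pop_change(5.0, 3.3), 1), 51.5)
  expect_equal(pop_change(7, 7), 0)
  expect_equal(pop_change(3, 2), 50)
  expect_error(pop_change(5, 0), "undefined")
})

test_that("comparison windows abut (previous) or shift a year back (seasonal)", {
  cfg <- tail_focal_config("2019-01-07", 90, 29)
  s <- as.Date("2019-01-07") + 7 * 29
  expect_equal(comparison_window_for(s, "previous_period", cfg),
               as.Date("2019-01-07"))
  cfg2 <- tail_focal_config("2019-01-07", 90, 3, year_length_weeks = 52L)
  s2 <- as.Date("2019-01-07") + 7 * 52
  expect_equal(comparison_window_for(s2, "same_period_previous_year", cfg2),
               as.Date("2019-01-07"))
  # the study geometry: focal week 2020-03-09, previous-period comparison
  # covers late 2019-08 through early 2020-03
  cfg3 <- analysis_config()
  comp <- comparison_window_for(cfg3$focal_window[1], "previous_period", cfg3)
  expect_equal(comp, as.Date("2019-08-19"))
  expect_equal(comp + 7 * 29 - 1, as.Date("2020-03-08"))
})

test_that("control enumeration matches the closed form on toy series", {
  # 10 weeks of history, 3-week windows, previous-period mode -> 5 controls
  wk <- make_weekly(5, "2019-01-07",
                    as.character(as.Date("2019-01-07") + 13 * 7 - 1))
  cfg <- tail_focal_config("2019-01-07", 13, 3)
  ctrl <- enumerate_controls(wk, "runs", "previous_period", cfg)
  expect_equal(nrow(ctrl), 5)
  expect_true(all(ctrl$delta_pct == 0))

  # 60 weeks of history, 3-week windows, 52-week year shift -> 6 controls
  wk2 <- make_weekly(5, "2019-01-07",
                     as.character(as.Date("2019-01-07") + 63 * 7 - 1))
  cfg2 <- tail_focal_config("2019-01-07", 63, 3)
  ctrl2 <- enumerate_controls(wk2, "runs", "same_period_previous_year", cfg2)
  expect_equal(nrow(ctrl2), 6)

  # deltas ordered by primary start; metadata spans whole weeks
  expect_true(all(diff(ctrl$primary_start) == 7))
  expect_true(all(ctrl$primary_end - ctrl$primary_start == 3 * 7 - 1))
  expect_error(
    enumerate_controls(wk[1:4, ], "runs", "previous_period", cfg),
    "admissible|contiguous"
  )
})

test_that("enumeration equals the brute-force oracle on randomized series", {
  set.seed(20)
  for (rep in 1:50) {
    period <- sample(2:4, 1)
    year_len <- sample(5:8, 1)
    n_hist <- sample((2 * max(period, year_len) + 1):40, 1)
    n_weeks <- n_hist + period
    counts <- rpois(n_weeks + 2, 6) + 1
    wk <- make_weekly(counts, "2018-01-01",
                      as.character(as.Date("2018-01-01") + n_weeks * 7 + 5))
    cfg <- tail_focal_config("2018-01-01", n_weeks, period,
                             year_length_weeks = year_len)
    for (mode in c("previous_period", "same_period_previous_year")) {
      fast <- enumerate_controls(wk, "runs", mode, cfg)
      slow <- brute_force_controls(wk, "runs", mode, cfg)
      expect_equal(fast$primary_start, slow$primary_start)
      expect_equal(fast$delta_pct, slow$delta_pct)
    }
  }
})

test_that("percentile placement follows the strict-less rule with midrank option", {
  ctrl <- c(-10, 0, 20, 40)
  expect_equal(percentile_of(50, ctrl), 100)
  expect_equal(percentile_of(-20, ctrl), 0)
  expect_equal(percentile_of(20, ctrl), 50)              # tie excluded
  expect_equal(percentile_of(20, ctrl, ties = "midrank"), 62.5)
  expect_error(percentile_of(1, numeric(0)), "empty")
  # strictly increasing across gaps between control values
  expect_lt(percentile_of(10, ctrl), percentile_of(30, ctrl))
})

test_that("adding a constant shrinks deltas toward zero, windows unchanged", {
  set.seed(4)
  counts <- rpois(45, 8) + 1
  wk <- make_weekly(counts, "2018-01-01",
                    as.character(as.Date("2018-01-01") + 45 * 7 - 1))
  cfg <- tail_focal_config("2018-01-01", 45, 4)
  base <- enumerate_controls(wk, "runs", "previous_period", cfg)
  for (c_add in c(5, 50)) {
    shifted <- wk
    shifted$runs <- shifted$runs + c_add
    got <- enumerate_controls(shifted, "runs", "previous_period", cfg)
    expect_equal(got$primary_start, base$primary_start)
    expect_equal(nrow(got), nrow(base))
    expect_true(all(abs(got$delta_pct) <= abs(base$delta_pct) + 1e-12))
    expect_true(all(sign(got$delta_pct) == sign(base$delta_pct) |
                      base$delta_pct == 0))
  }
})

test_that("year-over-year mode cancels pure seasonality; previous-period does not", {
  cfg <- sim_config(
    start_date = as.Date("2014-01-06"), end_date = as.Date("2020-09-27"),
    baseline_weekly_mean = 40, seasonal_amplitude = 0.3,
    trend_knots = data.frame(date = as.Date("2014-01-06"), multiplier = 1),
    step_date = NULL
  )
  lam <- simulate_weekly_intensity(cfg)
  wk <- make_weekly(lam$intensity, "2014-01-06", "2020-09-27")
  wk$runs <- lam$intensity  # deterministic mean series, no noise
  ac <- analysis_config(data_start = as.Date("2014-01-06"),
                        data_end = as.Date("2020-09-27"))
  foc_yoy <- focal_comparison(wk, "runs", "same_period_previous_year", ac)
  foc_prev <- focal_comparison(wk, "runs", "previous_period", ac)
  ctrl_prev <- enumerate_controls(wk, "runs", "previous_period", ac)
  # the 52-week shift is 364 days vs the 365.25-day cycle, so yoy residual
  # seasonality is small but not exactly zero
  expect_lt(abs(foc_yoy$delta_pct), 2)
  expect_gt(max(abs(ctrl_prev$delta_pct)), 20)
  expect_gt(abs(foc_prev$delta_pct), 5)
})

test_that("focal delta recovers a pure step and saturates the percentile", {
  cfg <- flat_config(baseline = 100, start = "2014-01-06", end = "2020-09-27",
                     step_date = "2020-03-10", step_multiplier = 2)
  lam <- simulate_weekly_intensity(cfg)
  wk <- make_weekly(1, "2014-01-06", "2020-09-27")
  wk$runs <- lam$intensity
  ac <- analysis_config(data_start = as.Date("2014-01-06"),
                        data_end = as.Date("2020-09-27"))
  for (mode in c("previous_period", "same_period_previous_year")) {
    foc <- focal_comparison(wk, "runs", mode, ac)
    expect_equal(foc$delta_pct, 100, tolerance = 1e-9)
    ctrl <- enumerate_controls(wk, "runs", mode, ac)
    expect_equal(percentile_of(foc$delta_pct, ctrl), 100)
  }
})

test_that("zero-mean comparison windows are dropped with a warning", {
  counts <- c(rep(0, 6), rep(5, 14))
  wk <- make_weekly(counts, "2019-01-07",
                    as.character(as.Date("2019-01-07") + 20 * 7 - 1))
  cfg <- tail_focal_config("2019-01-07", 20, 3)
  expect_warning(
    ctrl <- enumerate_controls(wk, "runs", "previous_period", cfg),
    "zero"
  )
  expect_true(all(ctrl$p_t_minus_1 > 0))
  expect_true(all(is.finite(ctrl$delta_pct)))
})
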