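#' Assemble the full surveillance report
#'
#' Runs the complete period-over-period analysis for the three weekly
#' outcomes and both comparison modes, producing:
#'
#' * `table1` — per outcome: focal-period mean (SD); for each comparison
#'   mode the comparison mean (SD), percent change, and Welch test p-value.
#'   Means and SDs are rounded to one decimal and the percent-change column
#'   is recomputed from those rounded means, so the printed table is
#'   internally consistent (the change column can always be reproduced from
#'   the means shown).
#' * `table2` — per outcome and mode: the percentile of the focal change
#'   within the sliding-window quasi-control distribution, with the number of
#'   control observations (surfacing the enumeration convention).
#' * `figure_series` — per outcome and mode: the ordered bar series of
#'   historical changes ending with the flagged focal observation, as drawn
#'   in period-over-period figures.
#'
#' @param weekly a `weekly_counts` tibble covering the configured data range.
#' @param config an [analysis_config()].
#' @param ties tie rule for [percentile_of()].
#' @return object of class `ems_pop_report`: list of `table1`, `table2`,
#'   `figure_series` (named list of tibbles), and `config`.
#' @export
build_report <- function(weekly, config, ties = "strict") {
  outcomes <- c("runs", "naloxone_administrations",
                "multiple_naloxone_administrations")
  modes <- c("previous_period", "same_period_previous_year")
  n <- config$period_length_weeks

  window_counts <- function(outcome, start) {
    idx <- match(window_weeks(start, n), weekly$week_start)
    weekly[[outcome]][idx]
  }

  t1 <- list(); t2 <- list(); fig <- list()
  for (oc in outcomes) {
    foc_counts <- window_counts(oc, config$focal_window[1])
    row <- tibble::tibble(
      outcome = oc,
      focal_mean = round(mean(foc_counts), 1),
      focal_sd = round(stats::sd(foc_counts), 1)
    )
    for (md in modes) {
      foc <- focal_comparison(weekly, oc, md, config)
      comp_counts <- window_counts(oc, foc$comparison_start)
      wt <- welch_test_counts(foc_counts, comp_counts)
      ctrl <- enumerate_controls(weekly, oc, md, config)
      pctile <- percentile_of(foc$delta_pct, ctrl, ties = ties)
      cm <- round(mean(comp_counts), 1)
      csd <- round(stats::sd(comp_counts), 1)
      row[[paste0(md, "_mean")]] <- cm
      row[[paste0(md, "_sd")]] <- csd
      row[[paste0(md, "_pct_change")]] <- round(pop_change(round(mean(foc_counts), 1), cm), 1)
      row[[paste0(md, "_p")]] <- render_p(wt$p_value)
      t2[[paste(oc, md)]] <- tibble::tibble(
        outcome = oc, comparison_mode = md,
        percentile = round(pctile, 1),
        n_controls = nrow(ctrl)
      )
      series <- tibble::as_tibble(ctrl)
      series$focal <- FALSE
      foc$focal <- TRUE
      series <- dplyr::bind_rows(series, foc)
      series$outcome <- oc
      series$comparison_mode <- md
      fig[[paste(oc, md, sep = ".")]] <- series
    }
    t1[[oc]] <- row
  }
  structure(
    list(
      table1 = dplyr::bind_rows(t1),
      table2 = dplyr::bind_rows(t2),
      figure_series = fig,
      config = config
    ),
    class = "ems_pop_report"
  )
}

#' @export
print.ems_pop_report <- function(x, ...) {
  cat("Period-over-period surveillance report\n")
  cat(sprintf("  focal window: %s to %s (%d weeks)\n",
              format(x$config$focal_window[1]),
              format(max(x$config$focal_window) + 6L),
              x$config$period_length_weeks))
  cat("\nOutcome means and percent change (table1):\n")
  print(as.data.frame(x$table1), row.names = FALSE)
  cat("\nPercentile of focal change within quasi-control distribution (table2):\n")
  print(as.data.frame(x$table2), row.names = FALSE)
  invisible(x)
}

#' Bar-series table behind a period-over-period figure
#'
#' One row per control observation plus a flagged focal row; `x` is the
#' primary window's end date, `y` the percent change. The CSV written by
#' [write_report()] is the canonical output; plotting is a convenience.
#'
#' @param controls a `pop_controls` tibble.
#' @param focal one-row tibble from [focal_comparison()].
#' @return tibble with `primary_end`, `delta_pct`, `focal` columns.
#' @export
render_figure_series <- function(controls, focal) {
  stopifnot(nrow(focal) == 1)
  out <- tibble::tibble(
    primary_end = c(controls$primary_end, focal$primary_end),
    delta_pct = c(controls$delta_pct, focal$delta_pct),
    focal = c(rep(FALSE, nrow(controls)), TRUE)
  )
  out[order(out$primary_end), ]
}

#' Plot a period-over-period bar series
#'
#' Bar chart of historical changes with the focal period highlighted, in the
#' style of period-over-period surveillance figures. Requires ggplot2.
#'
#' @param series tibble from [render_figure_series()] (or one element of a
#'   report's `figure_series`).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_pop_series <- function(series, title = "Period-over-period change") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$primary_end, y = .data$delta_pct,
                               fill = .data$focal)) +
    ggplot2::geom_col(width = 6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "darkorange")) +
    ggplot2::labs(x = "Primary window end", y = "Change (%)", title = title) +
    ggplot2::theme_minimal()
}

#' Write report tables to a directory
#'
#' Writes `table1.csv`, `table2.csv`, and one `series_<outcome>_<mode>.csv`
#' per figure series. Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report an `ems_pop_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table1, file.path(dir, "table1.csv"))
  readr::write_csv(report$table2, file.path(dir, "table2.csv"))
  for (nm in names(report$figure_series)) {
    readr::write_csv(
      report$figure_series[[nm]],
      file.path(dir, paste0("series_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    )
  }
  invisible(dir)
}
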