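#' Calendar-week helpers
#'
#' Surveillance counts are indexed by calendar week. Two conventions are
#' supported: ISO-8601 weeks (Monday start; the package default) and MMWR
#' weeks (Sunday start), the convention used by US notifiable-disease
#' surveillance.
#'
#' @param dates a `Date` vector.
#' @param week_rule `"iso"` (Monday-start) or `"mmwr"` (Sunday-start).
#' @return `week_start()`: the `Date` of the first day of each date's week.
#' @examples
#' week_start(as.Date("2020-03-10"))            # Monday 2020-03-09
#' week_start(as.Date("2020-03-10"), "mmwr")    # Sunday 2020-03-08
#' @export
week_start <- function(dates, week_rule = c("iso", "mmwr")) {
  week_rule <- match.arg(week_rule)
  stopifnot(inherits(dates, "Date"))
  dow <- as.integer(format(dates, "%u")) # Monday = 1 ... Sunday = 7
  offset <- if (week_rule == "iso") dow - 1L else dow %% 7L
  dates - offset
}

#' @rdname week_start
#' @param from,to `Date` scalars bounding the sequence (inclusive).
#' @return `week_seq()`: `Date` vector of week starts for every week that
#'   intersects `[from, to]`.
#' @export
week_seq <- function(from, to, week_rule = c("iso", "mmwr")) {
  week_rule <- match.arg(week_rule)
  stopifnot(inherits(from, "Date"), inherits(to, "Date"), from <= to)
  seq(week_start(from, week_rule), week_start(to, week_rule), by = 7L)
}

# ISO year/week labels for a vector of week-start dates. For MMWR weeks the
# epidemiological year/week of the week's Thursday-equivalent (day 4) is used,
# which matches the CDC rule that a week belongs to the year holding most of
# its days.
week_labels <- function(week_starts) {
  mid <- week_starts + 3L
  list(
    year = as.integer(format(mid, "%G")),
    week = as.integer(format(mid, "%V"))
  )
}
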