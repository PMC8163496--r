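#' Illustrative opioid-overdose impression vocabulary
#'
#' EMS clinical impression codes treated as indicating an opioid
#' overdose-related run. Real agencies code impressions against local or
#' NEMSIS-derived value sets that are not published with county extracts, so
#' this default is illustrative; supply the agency's own code list in
#' production use.
#'
#' @return character vector of impression codes.
#' @export
default_impression_vocabulary <- function() {
  c(
    "Overdose/Poisoning - Opioid",
    "Opioid Overdose",
    "Drug Overdose - Heroin",
    "Poisoning/Drug Ingestion - Narcotic"
  )
}

#' Default naloxone medication synonyms
#'
#' Medication strings (case-insensitive, whitespace-trimmed) counted as a
#' naloxone administration; includes the Narcan trade name.
#' @return character vector of normalized synonyms.
#' @export
naloxone_synonyms <- function() {
  c("naloxone", "narcan", "naloxone hcl", "naloxone hydrochloride")
}

#' Read treatment-level EMS records
#'
#' Reads the treatment-record CSV schema (one row per medication
#' administration during an EMS run; ISO-8601 dates, UTF-8, header row).
#' Rows without a parseable incident date cannot be placed in time and are
#' rejected; they are returned in the `"quarantine"` attribute with a reason,
#' and optionally written to a quarantine CSV.
#'
#' @param path CSV path.
#' @param quarantine_path optional path for rejected rows.
#' @return tibble of valid records; attribute `"quarantine"` holds rejects.
#' @export
read_treatment_records <- function(path, quarantine_path = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      incident_date = readr::col_date(),
      patient_birth_date = readr::col_date(),
      patient_gender = readr::col_character(),
      primary_impression = readr::col_character(),
      secondary_impression = readr::col_character(),
      medication = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- is.na(raw$incident_date) | is.na(raw$medication) |
    !nzchar(trimws(ifelse(is.na(raw$medication), "", raw$medication)))
  quarantine <- raw[bad, , drop = FALSE]
  if (nrow(quarantine) > 0) {
    quarantine$reason <- ifelse(is.na(quarantine$incident_date),
                                "missing incident_date", "missing medication")
    message(nrow(quarantine), " record(s) rejected at ingest.")
    if (!is.null(quarantine_path)) readr::write_csv(quarantine, quarantine_path)
  }
  out <- raw[!bad, , drop = FALSE]
  attr(out, "quarantine") <- quarantine
  out
}

#' Quasi-unique run identifier
#'
#' The deidentified extract carries no run number, so runs are reconstructed
#' from the composite (incident date, patient birth date, patient gender).
#' Records missing either demographic component cannot be safely grouped and
#' receive a record-unique fallback key (each such record is treated as its
#' own run); the fallback is a deterministic function of the record's
#' position, so keys are stable across program runs on the same input.
#'
#' @param incident_date `Date` vector (must be non-missing).
#' @param birth_date `Date` vector, may contain `NA`.
#' @param gender character vector, may contain `NA`/empty.
#' @param record_index integer vector used to build fallback keys; defaults to
#'   the element positions.
#' @return character key vector, one per record.
#' @export
make_run_id <- function(incident_date, birth_date, gender,
                        record_index = seq_along(incident_date)) {
  if (any(is.na(incident_date))) {
    stop("records without an incident date must be rejected before keying.",
         call. = FALSE)
  }
  gender <- ifelse(is.na(gender) | !nzchar(trimws(gender)), NA_character_,
                   toupper(trimws(gender)))
  key <- paste(format(incident_date), format(birth_date), gender, sep = "|")
  orphan <- is.na(birth_date) | is.na(gender)
  key[orphan] <- paste0("orphan|", format(incident_date[orphan]), "|#",
                        record_index[orphan])
  key
}

#' Classify a record as opioid overdose-related
#'
#' A record is opioid-related when its primary OR secondary impression
#' matches the vocabulary (case-insensitive exact match after whitespace
#' trimming). Empty or missing impressions never match.
#'
#' @param primary_impression,secondary_impression character vectors.
#' @param vocabulary non-empty character vector of impression codes.
#' @return logical vector.
#' @export
classify_opioid_run <- function(primary_impression, secondary_impression,
                                vocabulary = default_impression_vocabulary()) {
  if (length(vocabulary) == 0) {
    stop("`vocabulary` must be a non-empty set of impression codes.",
         call. = FALSE)
  }
  voc <- tolower(trimws(vocabulary))
  norm <- function(x) {
    x <- ifelse(is.na(x), "", tolower(trimws(x)))
    nzchar(x) & x %in% voc
  }
  norm(primary_impression) | norm(secondary_impression)
}

#' Reconstruct EMS runs from treatment records
#'
#' Groups records by the quasi-unique run identifier and derives, per run:
#' the incident date, opioid-relatedness (any record's impressions match the
#' vocabulary), the naloxone administration count (records whose medication
#' normalizes to a naloxone synonym), and the multiple-naloxone flag
#' (count >= 2). Exact duplicate rows are kept by default — two identical
#' naloxone rows may be two genuine doses; set `dedupe = TRUE` for extracts
#' known to contain accidental duplication.
#'
#' @param records tibble from [read_treatment_records()].
#' @param vocabulary opioid impression vocabulary.
#' @param synonyms naloxone medication synonyms.
#' @param dedupe drop exact duplicate rows before grouping.
#' @return tibble of runs: `run_id`, `incident_date`, `is_opioid_related`,
#'   `naloxone_count`, `is_multiple_naloxone`.
#' @export
build_runs <- function(records,
                       vocabulary = default_impression_vocabulary(),
                       synonyms = naloxone_synonyms(),
                       dedupe = FALSE) {
  if (dedupe) records <- dplyr::distinct(records)
  med <- tolower(trimws(records$medication))
  records$.is_naloxone <- med %in% tolower(trimws(synonyms))
  records$.is_opioid <- classify_opioid_run(
    records$primary_impression, records$secondary_impression, vocabulary
  )
  records$run_id <- make_run_id(
    records$incident_date, records$patient_birth_date, records$patient_gender
  )
  runs <- records |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(
      incident_date = min(.data$incident_date),
      is_opioid_related = any(.data$.is_opioid),
      naloxone_count = sum(.data$.is_naloxone),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_multiple_naloxone = .data$naloxone_count >= 2L) |>
    dplyr::arrange(.data$incident_date, .data$run_id)
  runs
}

#' Aggregate runs to weekly outcome counts
#'
#' Counts, for every calendar week covering `[start_date, end_date]`, the
#' three surveillance outcomes among opioid-related runs:
#' `runs` (all opioid-related runs), `naloxone_administrations` (runs with at
#' least one naloxone administration), and `multiple_naloxone_administrations`
#' (runs with two or more). Counting runs rather than total doses keeps the
#' outcomes nested (multiple <= naloxone <= runs) week by week; set
#' `count_doses = TRUE` to count total doses for outcome 2 instead.
#'
#' Weeks with no events appear with count 0. Boundary weeks only partly inside
#' the date range are flagged `complete = FALSE`; they stay in the series but
#' are excluded from window enumeration downstream.
#'
#' @param runs tibble from [build_runs()] (non-opioid runs are dropped), or
#'   any tibble with `incident_date` and `naloxone_count` columns.
#' @param start_date,end_date `Date` bounds of the surveillance interval.
#' @param week_rule `"iso"` or `"mmwr"`.
#' @param count_doses count total naloxone doses instead of dosed runs for
#'   outcome 2.
#' @return tibble (`weekly_counts`): `iso_year`, `iso_week`, `week_start`,
#'   `complete`, `runs`, `naloxone_administrations`,
#'   `multiple_naloxone_administrations`.
#' @export
aggregate_weekly <- function(runs, start_date, end_date,
                             week_rule = c("iso", "mmwr"),
                             count_doses = FALSE) {
  week_rule <- match.arg(week_rule)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if ("is_opioid_related" %in% names(runs)) {
    runs <- runs[runs$is_opioid_related, , drop = FALSE]
  }
  if (nrow(runs) == 0) {
    warning("no opioid-related runs; returning an all-zero series.",
            call. = FALSE)
  }
  ws <- week_seq(start_date, end_date, week_rule)
  labs <- week_labels(ws)
  wk <- week_start(runs$incident_date, week_rule)
  idx <- match(wk, ws)
  if (anyNA(idx)) {
    stop("runs fall outside [start_date, end_date].", call. = FALSE)
  }
  tally <- function(keep) {
    tabulate(idx[keep], nbins = length(ws))
  }
  nal2 <- if (count_doses) {
    as.integer(unname(tapply(
      runs$naloxone_count, factor(idx, levels = seq_along(ws)),
      sum, default = 0
    )))
  } else {
    tally(runs$naloxone_count >= 1L)
  }
  n_runs <- tally(rep(TRUE, nrow(runs)))
  n_multi <- tally(runs$naloxone_count >= 2L)
  out <- tibble::tibble(
    iso_year = labs$year,
    iso_week = labs$week,
    week_start = ws,
    complete = ws >= start_date & (ws + 6L) <= end_date,
    runs = n_runs,
    naloxone_administrations = nal2,
    multiple_naloxone_administrations = n_multi
  )
  class(out) <- c("weekly_counts", class(out))
  out
}

#' Write / read the weekly-counts CSV
#'
#' @param weekly a `weekly_counts` tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_weekly_counts()` returns the tibble.
#' @export
write_weekly_counts <- function(weekly, path) {
  readr::write_csv(weekly, path)
  invisible(path)
}

#' @rdname write_weekly_counts
#' @export
read_weekly_counts <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      iso_year = readr::col_integer(),
      iso_week = readr::col_integer(),
      week_start = readr::col_date(),
      complete = readr::col_logical(),
      runs = readr::col_integer(),
      naloxone_administrations = readr::col_integer(),
      multiple_naloxone_administrations = readr::col_integer()
    ),
    progress = FALSE
  )
  class(out) <- c("weekly_counts", class(out))
  out
}
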