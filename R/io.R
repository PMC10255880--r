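# Canonical tabular schemas and readers/writers for stepping events, daily
# wear records, and longitudinal cohort data.
#
# Canonical formats are plain UTF-8 CSV with a header row. Timestamps are
# local ("wall clock") times written as ISO 8601 without a zone designator;
# internally they are stored as POSIXct in UTC so that day arithmetic is
# unaffected by daylight-saving transitions.

.cohort_levels <- list(
  sex         = c("male", "female"),
  education   = c("secondary", "some college", "college/degree"),
  comorbidity = c("none", "one or more"),
  sf36_class  = c("very good/excellent", "good", "fair/poor"),
  allocation  = c("control", "intervention"),
  site        = c("bristol/bath", "birmingham", "exeter")
)

.cohort_periods <- c(0L, 6L, 12L, 24L)

# Default vendor column maps. The vendor export layouts are configurable: pass
# `col_map` to override (canonical name -> exported column name).
.dialect_maps <- list(
  canonical    = c(participant_id = "participant_id", device = "device",
                   start = "start", duration_s = "duration_s", steps = "steps"),
  thigh_export = c(participant_id = "subject", start = "event_start",
                   duration_s = "duration (s)", steps = "step_count"),
  wrist_export = c(participant_id = "subject_code", start = "segment_start",
                   duration_s = "segment_duration", steps = "steps")
)

#' @noRd
parse_local_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' @noRd
format_local_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# Row-wise validation engine shared by the three readers. `checks` is a list
# of functions(data) -> logical vector (TRUE = bad) with a message attribute.
#' @noRd
collect_problems <- function(data, checks) {
  problems <- purrr::imap(checks, function(fun, msg) {
    bad <- fun(data)
    if (any(bad)) tibble(row = which(bad), problem = msg) else NULL
  })
  bind_rows(problems)
}

#' @noRd
apply_validation <- function(data, problems, mode, what) {
  mode <- rlang::arg_match(mode, c("strict", "permissive"))
  if (nrow(problems) == 0) {
    attr(data, "problems") <- problems
    return(data)
  }
  problems <- arrange(problems, .data$row)
  if (mode == "strict") {
    shown <- head(problems, 5)
    abort(c(sprintf("%d invalid %s row(s)", length(unique(problems$row)), what),
            sprintf("row %d: %s", shown$row, shown$problem)),
          class = "pfstep_validation_error")
  }
  keep <- setdiff(seq_len(nrow(data)), unique(problems$row))
  out <- data[keep, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Read stepping events from CSV
#'
#' Reads a table of variable-length stepping events (one row per contiguous
#' stepping bout) and returns validated events with the derived cadence
#' (steps per minute). Vendor-style exports are supported through column-map
#' dialects; the canonical layout has columns `participant_id`, `device`,
#' `start`, `duration_s`, `steps`.
#'
#' @param path Path to a CSV file.
#' @param dialect One of `"canonical"`, `"thigh_export"`, `"wrist_export"`.
#'   The vendor dialects rename exported columns onto the canonical schema;
#'   `thigh_export` assumes device `"thigh"` and `wrist_export` device
#'   `"wrist"` when the file carries no device column.
#' @param mode `"strict"` (default) aborts on any invalid row; `"permissive"`
#'   drops invalid rows and records row-numbered diagnostics in the
#'   `"problems"` attribute of the result.
#' @param col_map Optional named character vector overriding the dialect's
#'   column map (canonical name -> column name in the file).
#' @return A tibble of events with columns `participant_id`, `device`
#'   (factor thigh/wrist), `start` (POSIXct, clock time), `duration_s`,
#'   `steps`, `cadence`; invalid-row diagnostics in `attr(, "problems")`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(participant_id = "p1", device = "wrist",
#'                      start = "2024-05-01T10:00:00", duration_s = 60,
#'                      steps = 62), path, row.names = FALSE)
#' read_events(path)$cadence  # 62 steps/min
#' @export
read_events <- function(path, dialect = "canonical", mode = "strict", col_map = NULL) {
  dialect <- rlang::arg_match(dialect, names(.dialect_maps))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  map <- .dialect_maps[[dialect]]
  if (!is.null(col_map)) map[names(col_map)] <- col_map

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "pfstep_schema_error")
  }

  data <- tibble(
    participant_id = raw[[map[["participant_id"]]]],
    device = if ("device" %in% names(map) && map[["device"]] %in% names(raw)) {
      raw[[map[["device"]]]]
    } else if (dialect == "thigh_export") "thigh" else "wrist",
    start_raw = raw[[map[["start"]]]],
    duration_s = suppressWarnings(as.numeric(raw[[map[["duration_s"]]]])),
    steps = suppressWarnings(as.numeric(raw[[map[["steps"]]]]))
  )
  data$start <- suppressWarnings(parse_local_timestamp(data$start_raw))

  checks <- list(
    "missing participant_id" = function(d) is.na(d$participant_id) | d$participant_id == "",
    "unknown device (expected thigh/wrist)" = function(d) !d$device %in% .devices,
    "unparseable timestamp" = function(d) is.na(d$start),
    "duration must be a positive number of seconds" =
      function(d) is.na(d$duration_s) | d$duration_s <= 0,
    "steps must be a count >= 1" =
      function(d) is.na(d$steps) | d$steps < 1 | d$steps != floor(d$steps)
  )
  data <- apply_validation(data, collect_problems(data, checks), mode, "event")
  out <- tibble(
    participant_id = data$participant_id,
    device = as_device(data$device),
    start = data$start,
    duration_s = data$duration_s,
    steps = as.integer(data$steps),
    cadence = data$steps / (data$duration_s / 60)
  )
  attr(out, "problems") <- attr(data, "problems")
  out
}

#' Read daily wear records from CSV
#'
#' Canonical columns: `participant_id`, `device`, `date` (YYYY-MM-DD),
#' `wear_hours` in \[0, 24\]. For longitudinal cohort data an optional
#' `period` column (months 0/6/12/24) is carried through when present.
#'
#' @inheritParams read_events
#' @return A tibble of wear records; diagnostics in `attr(, "problems")`.
#' @export
read_wear <- function(path, mode = "strict") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("participant_id", "device", "date", "wear_hours")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "pfstep_schema_error")
  }
  data <- tibble(
    participant_id = raw$participant_id,
    device = raw$device,
    date = suppressWarnings(as.Date(raw$date)),
    wear_hours = suppressWarnings(as.numeric(raw$wear_hours))
  )
  if ("period" %in% names(raw)) {
    data$period <- suppressWarnings(as.integer(raw$period))
  }
  checks <- list(
    "missing participant_id" = function(d) is.na(d$participant_id) | d$participant_id == "",
    "unknown device (expected thigh/wrist)" = function(d) !d$device %in% .devices,
    "unparseable date" = function(d) is.na(d$date),
    "wear_hours must lie in [0, 24]" =
      function(d) is.na(d$wear_hours) | d$wear_hours < 0 | d$wear_hours > 24
  )
  if ("period" %in% names(data)) {
    checks[["period must be one of 0, 6, 12, 24 months"]] <-
      function(d) is.na(d$period) | !d$period %in% .cohort_periods
  }
  data <- apply_validation(data, collect_problems(data, checks), mode, "wear")
  dup <- duplicated(data[c("participant_id", "device", "date")])
  if (any(dup)) {
    abort(sprintf("duplicate wear record(s) for %d participant-device-date(s)", sum(dup)),
          class = "pfstep_validation_error")
  }
  data$device <- as_device(data$device)
  data
}

#' Read longitudinal cohort records from CSV
#'
#' One row per participant-period with the SPPB physical-function score
#' (integer 0-12) and the modelling covariates: age at recruitment, sex,
#' IMD quintile (1-5), highest education, comorbidity, SF-36 general-health
#' class, trial allocation, and study site.
#'
#' @inheritParams read_events
#' @return A tibble of cohort records with categorical covariates as factors;
#'   diagnostics in `attr(, "problems")`.
#' @export
read_cohort <- function(path, mode = "strict") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("participant_id", "period", "sppb", "age_at_recruitment", "sex",
                "imd_quintile", "education", "comorbidity", "sf36_class",
                "allocation", "site")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "pfstep_schema_error")
  }
  data <- tibble(
    participant_id = raw$participant_id,
    period = suppressWarnings(as.integer(raw$period)),
    sppb = suppressWarnings(as.numeric(raw$sppb)),
    age_at_recruitment = suppressWarnings(as.numeric(raw$age_at_recruitment)),
    sex = raw$sex, imd_quintile = suppressWarnings(as.integer(raw$imd_quintile)),
    education = raw$education, comorbidity = raw$comorbidity,
    sf36_class = raw$sf36_class, allocation = raw$allocation, site = raw$site
  )
  checks <- list(
    "missing participant_id" = function(d) is.na(d$participant_id) | d$participant_id == "",
    "period must be one of 0, 6, 12, 24 months" =
      function(d) is.na(d$period) | !d$period %in% .cohort_periods,
    "sppb must be an integer in [0, 12]" =
      function(d) is.na(d$sppb) | d$sppb < 0 | d$sppb > 12 | d$sppb != floor(d$sppb),
    "age_at_recruitment must be a positive number" =
      function(d) is.na(d$age_at_recruitment) | d$age_at_recruitment <= 0,
    "imd_quintile must be 1-5" =
      function(d) is.na(d$imd_quintile) | !d$imd_quintile %in% 1:5
  )
  for (fld in names(.cohort_levels)) {
    local({
      f <- fld
      checks[[sprintf("%s must be one of: %s", f,
                      paste(.cohort_levels[[f]], collapse = ", "))]] <<-
        function(d) !d[[f]] %in% .cohort_levels[[f]]
    })
  }
  data <- apply_validation(data, collect_problems(data, checks), mode, "cohort")
  for (fld in names(.cohort_levels)) {
    data[[fld]] <- factor(data[[fld]], levels = .cohort_levels[[fld]])
  }
  data$sppb <- as.integer(data$sppb)
  data
}

#' Write events, wear records, or cohort records to canonical CSV
#'
#' Counterparts of [read_events()], [read_wear()] and [read_cohort()];
#' writing then reading reproduces the collection exactly (the derived
#' `cadence` column is recomputed, not stored).
#'
#' @param events,wear,cohort Tibbles as returned by the corresponding reader
#'   (or built by the simulators).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble(
    participant_id = events$participant_id,
    device = as.character(events$device),
    start = format_local_timestamp(events$start),
    duration_s = events$duration_s,
    steps = events$steps
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_wear <- function(wear, path) {
  out <- wear
  out$device <- as.character(out$device)
  out$date <- format(out$date, "%Y-%m-%d")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (fld in names(.cohort_levels)) out[[fld]] <- as.character(out[[fld]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
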