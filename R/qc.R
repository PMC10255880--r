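# Event-level quality control, cadence banding, and aggregation into daily,
# period, and biomarker summaries.
#
# Band conventions: cadence is continuous. Non-walking covers [min, walking)
# = [20, 45) steps/min; walking covers [45, 175]; walking is split at the
# *unrounded* median walking cadence with slower-paced walking = [45, median]
# (steps at cadences "below and including" the median) and faster-paced
# walking = (median, 175]. Splitting on the exact median (while reporting a
# rounded value) avoids boundary events changing band when the median is
# rounded first. Slower-paced steps = non-walking + slower-paced walking.

#' Cadence band definition
#'
#' Defines the cadence intervals used to classify steps: the analysable
#' cadence range (default 20-175 steps/min), the walking threshold (45
#' steps/min; slower stepping is not considered walking), and the median
#' walking cadence at which walking is split into slower- and faster-paced
#' walking. The median is population- and device-specific (74 steps/min for
#' a thigh-worn system, 76 for a wrist-worn system in the paired validation
#' sample, 62 in the longitudinal cohort) and is normally estimated from the
#' filtered events with [median_walking_cadence()].
#'
#' @param median_walking_cadence Median cadence (steps/min) of walking events
#'   (cadence >= `walking_threshold`); the slower/faster split point.
#' @param min_cadence,walking_threshold,max_cadence Band limits in steps/min.
#' @return An object of class `cadence_bands`.
#' @examples
#' cadence_bands(76)
#' @export
cadence_bands <- function(median_walking_cadence,
                          min_cadence = 20, walking_threshold = 45,
                          max_cadence = 175) {
  check_scalar_number(min_cadence, "min_cadence", min = 0)
  check_scalar_number(walking_threshold, "walking_threshold")
  check_scalar_number(max_cadence, "max_cadence")
  check_scalar_number(median_walking_cadence, "median_walking_cadence")
  if (!(min_cadence < walking_threshold && walking_threshold <= median_walking_cadence &&
        median_walking_cadence < max_cadence)) {
    abort("cadence bands must satisfy min < walking_threshold <= median < max",
          class = "pfstep_config_error")
  }
  structure(list(min_cadence = min_cadence,
                 walking_threshold = walking_threshold,
                 median_walking_cadence = median_walking_cadence,
                 max_cadence = max_cadence),
            class = "cadence_bands")
}

#' @exportS3Method base::print
print.cadence_bands <- function(x, ...) {
  m <- x$median_walking_cadence
  cat("Cadence bands (steps/min)\n")
  cat(sprintf("  total steps:               %g-%g\n", x$min_cadence, x$max_cadence))
  cat(sprintf("  non-walking steps:         %g-<%g\n", x$min_cadence, x$walking_threshold))
  cat(sprintf("  walking steps:             %g-%g\n", x$walking_threshold, x$max_cadence))
  cat(sprintf("  slower-paced walking:      %g-%g\n", x$walking_threshold, m))
  cat(sprintf("  faster-paced walking:      >%g-%g\n", m, x$max_cadence))
  cat(sprintf("  (split at median walking cadence %g, reported as %d)\n", m, round(m)))
  invisible(x)
}

#' Filter stepping events by reliability rules
#'
#' Applies the event-level exclusions: events with fewer than `min_steps`
#' steps (short bursts give unreliable cadence estimates), events with
#' cadence strictly below `min_cadence` or strictly above `max_cadence`
#' steps/min (outside the range both measurement systems report), and events
#' starting after a participant's first `max_days` distinct calendar dates
#' (to avoid cyclical weekly behaviour distorting averages). Boundary
#' cadences of exactly 20 or 175 steps/min are kept.
#'
#' @param events Event tibble from [read_events()] or the simulator.
#' @param bands A [cadence_bands()] object (only the min/max limits are used;
#'   the default limits apply if `NULL`).
#' @param max_days Number of distinct calendar dates retained per participant
#'   (default 7); `Inf` disables truncation.
#' @param min_steps Minimum steps per event (default 10).
#' @return The kept events, with an exclusion report in
#'   `attr(, "exclusions")`: a tibble of rule / events_removed. An event
#'   failing several rules is counted under the first rule in the order
#'   min_steps, cadence_low, cadence_high, beyond_max_days.
#' @export
filter_events <- function(events, bands = NULL, max_days = 7, min_steps = 10) {
  min_c <- if (is.null(bands)) 20 else bands$min_cadence
  max_c <- if (is.null(bands)) 175 else bands$max_cadence
  if (nrow(events) == 0) {
    report <- tibble(rule = c("min_steps", "cadence_low", "cadence_high", "beyond_max_days"),
                     events_removed = 0L)
    attr(events, "exclusions") <- report
    return(events)
  }

  fail_steps <- events$steps < min_steps
  fail_low <- !fail_steps & events$cadence < min_c
  fail_high <- !fail_steps & !fail_low & events$cadence > max_c

  # First `max_days` distinct dates per participant, chronological, over all
  # of that participant's event records (both devices share the protocol).
  date <- as.Date(events$start, tz = "UTC")
  fail_late <- rep(FALSE, nrow(events))
  if (is.finite(max_days)) {
    day_rank <- tibble(participant_id = events$participant_id, date = date) %>%
      distinct() %>%
      arrange(.data$participant_id, .data$date) %>%
      group_by(.data$participant_id) %>%
      mutate(day_index = dplyr::row_number()) %>%
      ungroup()
    idx <- left_join(tibble(participant_id = events$participant_id, date = date),
                     day_rank, by = c("participant_id", "date"))
    fail_late <- !fail_steps & !fail_low & !fail_high & idx$day_index > max_days
  }

  report <- tibble(
    rule = c("min_steps", "cadence_low", "cadence_high", "beyond_max_days"),
    events_removed = c(sum(fail_steps), sum(fail_low), sum(fail_high), sum(fail_late))
  )
  kept <- events[!(fail_steps | fail_low | fail_high | fail_late), , drop = FALSE]
  attr(kept, "exclusions") <- report
  kept
}

#' Valid days for a paired-device protocol
#'
#' A participant-date is valid when *both* devices were worn for at least
#' `min_hours` hours that day (default 20 h, a stringent 24-h protocol).
#'
#' @param wear Wear tibble (`participant_id`, `device`, `date`, `wear_hours`).
#' @param min_hours Wear-hours threshold, inclusive.
#' @return Tibble of valid `participant_id` / `date` pairs.
#' @export
valid_days_paired <- function(wear, min_hours = 20) {
  devices_present <- unique(as.character(wear$device))
  wear %>%
    group_by(.data$participant_id, .data$date) %>%
    summarise(n_ok = sum(.data$wear_hours >= min_hours),
              n_dev = dplyr::n_distinct(.data$device), .groups = "drop") %>%
    filter(.data$n_dev == length(devices_present), .data$n_ok == .data$n_dev) %>%
    select("participant_id", "date")
}

#' Valid recording periods for a longitudinal cohort protocol
#'
#' A participant-period is valid when the device was worn at least
#' `min_hours` hours/day on at least `min_days` days in the period
#' (default 18 h on 6 days).
#'
#' @param wear Wear tibble with a `period` column (months).
#' @param min_hours Daily wear-hours threshold, inclusive.
#' @param min_days Minimum number of qualifying days, inclusive.
#' @return Tibble of valid `participant_id` / `period` pairs.
#' @export
valid_period_cohort <- function(wear, min_hours = 18, min_days = 6) {
  if (!"period" %in% names(wear)) {
    abort("cohort wear records need a 'period' column (months)")
  }
  wear %>%
    group_by(.data$participant_id, .data$period) %>%
    summarise(n_ok = sum(.data$wear_hours >= min_hours), .groups = "drop") %>%
    filter(.data$n_ok >= min_days) %>%
    select("participant_id", "period")
}

#' Median walking cadence
#'
#' The unweighted median cadence (each event one vote, regardless of its
#' step count) over all events at or above the walking threshold, pooled
#' across participants, days and periods. This is the population- and
#' system-specific split point between slower- and faster-paced walking.
#'
#' @param events Filtered event tibble.
#' @param walking_threshold Walking cadence threshold (steps/min), inclusive.
#' @return Median walking cadence in steps/min (a single number).
#' @export
median_walking_cadence <- function(events, walking_threshold = 45) {
  cad <- events$cadence[events$cadence >= walking_threshold]
  if (length(cad) == 0) {
    abort("no walking events (cadence >= walking threshold); cannot compute a median walking cadence")
  }
  median(cad)
}

#' @noRd
band_of <- function(cadence, bands) {
  dplyr::case_when(
    cadence < bands$walking_threshold ~ "non_walking",
    cadence <= bands$median_walking_cadence ~ "slower_walking",
    TRUE ~ "faster_walking"
  )
}

#' Aggregate events into daily cadence-band step counts
#'
#' Sums each participant-device-date's steps within the cadence bands:
#' non-walking, slower-paced walking, faster-paced walking, plus the derived
#' walking (slower + faster), slower-paced (non-walking + slower walking)
#' and total steps. Events are assigned to the calendar date of their start
#' time. If `valid_days` is supplied, only those participant-dates are kept.
#'
#' @param events Filtered event tibble (assumed within the band limits).
#' @param bands A [cadence_bands()] object with the median set.
#' @param valid_days Optional tibble of valid `participant_id` / `date` rows
#'   (from [valid_days_paired()]); `NULL` keeps all days.
#' @return Tibble with one row per participant-device-date and columns
#'   `non_walking`, `slower_walking`, `faster_walking`, `walking`,
#'   `slower_paced`, `total` (integer step counts). A `period` column on the
#'   events is carried through the grouping.
#' @export
aggregate_daily <- function(events, bands, valid_days = NULL) {
  if (nrow(events) == 0 ||
      (!is.null(valid_days) && nrow(valid_days) == 0)) {
    return(tibble(participant_id = character(), device = factor(character(), levels = .devices),
                  date = as.Date(character()), non_walking = integer(),
                  slower_walking = integer(), faster_walking = integer(),
                  walking = integer(), slower_paced = integer(), total = integer()))
  }
  ev <- events %>%
    mutate(date = as.Date(.data$start, tz = "UTC"),
           band = band_of(.data$cadence, bands))
  if (!is.null(valid_days)) {
    ev <- semi_join(ev, valid_days, by = c("participant_id", "date"))
  }
  keys <- intersect(c("participant_id", "device", "period", "date"), names(ev))
  daily <- ev %>%
    group_by(across(all_of(keys)), .data$band) %>%
    summarise(steps = sum(.data$steps), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "band", values_from = "steps", values_fill = 0L)
  for (b in c("non_walking", "slower_walking", "faster_walking")) {
    if (!b %in% names(daily)) daily[[b]] <- 0L
  }
  daily %>%
    mutate(walking = .data$slower_walking + .data$faster_walking,
           slower_paced = .data$non_walking + .data$slower_walking,
           total = .data$non_walking + .data$walking) %>%
    select(all_of(keys), "non_walking", "slower_walking", "faster_walking",
           "walking", "slower_paced", "total")
}

#' Average daily aggregates over recording periods
#'
#' Second aggregation stage for longitudinal data: the arithmetic mean of
#' the daily band step counts over each participant-period's valid days,
#' giving mean daily step counts per band.
#'
#' @param daily Daily aggregate tibble from [aggregate_daily()] carrying a
#'   `period` column.
#' @param valid_periods Optional tibble of valid `participant_id` / `period`
#'   rows (from [valid_period_cohort()]); `NULL` keeps all periods.
#' @return Tibble with one row per participant-period (and device, if
#'   present): per-band mean daily steps and `n_days`, the number of days
#'   averaged.
#' @export
aggregate_period <- function(daily, valid_periods = NULL) {
  if (!"period" %in% names(daily)) {
    abort("daily aggregates need a 'period' column to be averaged over periods")
  }
  if (!is.null(valid_periods)) {
    daily <- semi_join(daily, valid_periods, by = c("participant_id", "period"))
  }
  keys <- intersect(c("participant_id", "device", "period"), names(daily))
  bands <- c("non_walking", "slower_walking", "faster_walking", "walking",
             "slower_paced", "total")
  daily %>%
    group_by(across(all_of(keys))) %>%
    summarise(across(all_of(bands), mean), n_days = dplyr::n(), .groups = "drop")
}

#' The pfSTEP biomarker
#'
#' Condenses mean daily stepping into two integers: the average number of
#' slower-paced steps per day (non-walking plus slower-paced walking)
#' followed by the average number of faster-paced walking steps per day,
#' e.g. `(6931; 428)`. Their sum is the average total steps per day; when
#' rounding the two components independently would break that identity, the
#' larger component absorbs the one-step adjustment.
#'
#' @param period_aggregate A one-row (or per-group averaged) aggregate with
#'   `slower_paced`, `faster_walking` and `total` mean daily steps, e.g.
#'   from [aggregate_period()]; alternatively two bare numbers via
#'   `slower` / `faster`.
#' @param slower,faster Mean slower-paced and faster-paced walking steps/day
#'   (used when `period_aggregate` is missing).
#' @param split_cadence The median walking cadence the split was made at
#'   (carried for reporting).
#' @return An object of class `pfstep`, a list with integer components
#'   `slower_paced_steps` and `faster_paced_steps` plus `split_cadence`;
#'   printed as `(S; F)`.
#' @examples
#' pfstep(slower = 6931, faster = 428, split_cadence = 62)
#' @export
pfstep <- function(period_aggregate = NULL, slower = NULL, faster = NULL,
                   split_cadence = NA_real_) {
  if (!is.null(period_aggregate)) {
    slower <- mean(period_aggregate$slower_paced)
    faster <- mean(period_aggregate$faster_walking)
  }
  if (is.null(slower) || is.null(faster)) {
    abort("supply either a period aggregate or both 'slower' and 'faster'")
  }
  comps <- round_preserving_sum(c(slower, faster))
  structure(list(slower_paced_steps = comps[1], faster_paced_steps = comps[2],
                 split_cadence = split_cadence),
            class = "pfstep")
}

#' @exportS3Method base::print
print.pfstep <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.pfstep <- function(x, ...) {
  sprintf("(%d; %d)", x$slower_paced_steps, x$faster_paced_steps)
}

#' Change in mean daily steps between two periods
#'
#' Computes the decline (baseline minus follow-up) in mean daily steps per
#' band between two recording periods, together with the percent change
#' relative to baseline (rounded to the nearest integer percent).
#'
#' @param period_means Tibble with a `period` column and per-band mean daily
#'   step columns (e.g. from [aggregate_period()] averaged over participants,
#'   or published period means such as [react_stepping_means()]).
#' @param from,to The baseline and comparison period values.
#' @return Tibble with one row per band: `mean_from`, `mean_to`, `change`
#'   (positive = decline), `percent` (integer; `NA` with a flag when the
#'   baseline mean is zero).
#' @export
period_change <- function(period_means, from, to) {
  bands <- intersect(c("non_walking", "slower_walking", "faster_walking",
                       "walking", "slower_paced", "total"), names(period_means))
  if (length(bands) == 0) abort("no band columns found in 'period_means'")
  row_from <- period_means[period_means$period == from, , drop = FALSE]
  row_to <- period_means[period_means$period == to, , drop = FALSE]
  if (nrow(row_from) != 1 || nrow(row_to) != 1) {
    abort(sprintf("periods %s and %s must each match exactly one row", from, to))
  }
  m0 <- unlist(row_from[bands])
  m1 <- unlist(row_to[bands])
  zero_base <- m0 == 0
  tibble(
    band = bands,
    mean_from = unname(m0),
    mean_to = unname(m1),
    change = unname(m0 - m1),
    percent = unname(ifelse(zero_base, NA_integer_,
                            as.integer(round((m0 - m1) / m0 * 100)))),
    zero_baseline = unname(zero_base)
  )
}
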