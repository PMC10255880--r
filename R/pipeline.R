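# Orchestration: reproducible end-to-end profiles tying QC, banding,
# agreement and association stages together, with a declarative config and
# a manifest sufficient to reproduce every output.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_paired()] and
#' [run_cohort()]. All randomness (bootstrap resampling) flows from the
#' single `seed`. Configurations can also be read from a YAML file with
#' [read_pipeline_config()]; explicit arguments override file values.
#'
#' @param profile `"paired"` (two-device agreement study) or `"cohort"`
#'   (longitudinal cohort study).
#' @param events,wear,cohort,daily Input CSV paths: canonical events + wear
#'   for the paired profile; cohort records + per-day band steps (with
#'   `period` and `wear_hours` columns, as written by [run_simulated_inputs()])
#'   for the cohort profile.
#' @param output_dir Directory for the report bundle (created if needed).
#' @param min_steps,min_cadence,max_cadence,walking_threshold Event filter
#'   and band parameters (steps; steps/min).
#' @param max_days Recording truncation (distinct calendar days kept).
#' @param min_hours_paired Paired-profile valid-day wear threshold (h).
#' @param min_hours_cohort,min_days_cohort Cohort-profile validity rule.
#' @param responses Bands to run agreement models for.
#' @param n_boot Bootstrap replicates for CCC intervals (0 skips intervals).
#' @param models Association models to fit (subset of 1:3).
#' @param scenario_thetas Named vector `c(slower, faster)`: SPPB points per
#'   1000 steps used for scenario projections.
#' @param scenarios List of `c(delta_slower, delta_faster)` changes in
#'   thousands of steps/day; defaults to the three worked examples
#'   (maintained decline, +500/+500, substitution).
#' @param pooled_median Cohort profile: compute the median walking cadence
#'   pooled over all periods (default) or from baseline only.
#' @param seed Integer master seed.
#' @return A `pfstep_config` list.
#' @export
pfstep_config <- function(profile = c("paired", "cohort"),
                          events = NULL, wear = NULL, cohort = NULL, daily = NULL,
                          output_dir = "pfstep_out",
                          min_steps = 10, min_cadence = 20, max_cadence = 175,
                          walking_threshold = 45, max_days = 7,
                          min_hours_paired = 20,
                          min_hours_cohort = 18, min_days_cohort = 6,
                          responses = c("total", "walking", "slower_walking", "faster_walking"),
                          n_boot = 500,
                          models = 1:3,
                          scenario_thetas = c(slower = 0.13, faster = 0.53),
                          scenarios = list(c(-0.708, -0.236), c(0.5, 0.5), c(-0.5, 1.0)),
                          pooled_median = TRUE,
                          seed = 1L) {
  profile <- rlang::arg_match(profile)
  for (f in c("min_steps", "min_cadence", "max_cadence", "walking_threshold",
              "max_days", "min_hours_paired", "min_hours_cohort", "min_days_cohort")) {
    check_scalar_number(get(f), f, min = 1e-9)
  }
  check_count(n_boot, "n_boot", min = 0)
  check_count(seed, "seed")
  structure(list(profile = profile, events = events, wear = wear,
                 cohort = cohort, daily = daily, output_dir = output_dir,
                 min_steps = min_steps, min_cadence = min_cadence,
                 max_cadence = max_cadence, walking_threshold = walking_threshold,
                 max_days = max_days, min_hours_paired = min_hours_paired,
                 min_hours_cohort = min_hours_cohort, min_days_cohort = min_days_cohort,
                 responses = responses, n_boot = n_boot, models = models,
                 scenario_thetas = scenario_thetas, scenarios = scenarios,
                 pooled_median = pooled_median, seed = seed),
            class = "pfstep_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of `key: value` pairs matching the arguments of
#'   [pfstep_config()].
#' @param overrides Named list of values overriding the file.
#' @return A `pfstep_config` list.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  if (!is.null(vals$scenarios)) vals$scenarios <- lapply(vals$scenarios, unlist)
  if (!is.null(vals$scenario_thetas)) vals$scenario_thetas <- unlist(vals$scenario_thetas)
  do.call(pfstep_config, vals)
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(c(sprintf("pipeline stage '%s' failed", name), conditionMessage(e)),
          class = "pfstep_stage_error")
  })
}

#' @noRd
require_path <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("missing %s file: %s", what, path %||% "<not set>"))
  }
  path
}

#' @noRd
write_manifest <- function(config, out_dir, extra = list()) {
  cfg <- unclass(config)
  manifest <- c(list(profile = config$profile,
                     config_hash = rlang::hash(cfg),
                     seed = config$seed,
                     package = "pfstep",
                     package_version = as.character(utils::packageVersion("pfstep")),
                     r_version = paste(R.version$major, R.version$minor, sep = ".")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the paired-device agreement profile
#'
#' End-to-end: read events and wear, apply the event filters, determine
#' valid days (both devices worn >= the threshold), estimate each system's
#' median walking cadence and band thresholds, aggregate to daily band step
#' counts, and fit the variance-components agreement model (with bootstrap
#' CCC intervals) for each requested band. Writes the report bundle
#' (exclusion report, band thresholds, per-band agreement results, variance
#' shares, scatter statistics, manifest) to `config$output_dir`.
#' Deterministic for a fixed config and seed.
#'
#' @param config A `pfstep_config` with `profile = "paired"`.
#' @return Invisibly, a list with the report components (`exclusions`,
#'   `bands`, `daily`, `agreement` fits, `scatter`, `manifest`).
#' @export
run_paired <- function(config) {
  stopifnot(inherits(config, "pfstep_config"))
  if (config$profile != "paired") abort("config profile must be 'paired'")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  events <- stage("read_events", read_events(require_path(config$events, "events")))
  wear <- stage("read_wear", read_wear(require_path(config$wear, "wear")))

  n_in <- nrow(events)
  limits <- cadence_bands(config$walking_threshold + 1,  # placeholder median; limits only
                          config$min_cadence, config$walking_threshold, config$max_cadence)
  kept <- stage("filter_events",
                filter_events(events, limits, max_days = config$max_days,
                              min_steps = config$min_steps))
  exclusions <- attr(kept, "exclusions")
  accounting <- list(events_in = n_in, events_kept = nrow(kept),
                     events_removed = as.list(setNames(exclusions$events_removed,
                                                       exclusions$rule)))
  stopifnot(n_in == nrow(kept) + sum(exclusions$events_removed))

  valid <- stage("valid_days", valid_days_paired(wear, min_hours = config$min_hours_paired))

  daily <- stage("banding_aggregation", {
    purrr::map_dfr(.devices, function(dev) {
      ev <- filter(kept, .data$device == dev)
      med <- median_walking_cadence(ev, config$walking_threshold)
      bands <- cadence_bands(med, config$min_cadence, config$walking_threshold,
                             config$max_cadence)
      mutate(aggregate_daily(ev, bands, valid), median_walking_cadence = med)
    })
  })
  band_table <- daily %>%
    distinct(.data$device, .data$median_walking_cadence) %>%
    mutate(min_cadence = config$min_cadence,
           walking_threshold = config$walking_threshold,
           max_cadence = config$max_cadence,
           slower_walking_upper = round(.data$median_walking_cadence),
           faster_walking_lower = round(.data$median_walking_cadence) + 1)

  fits <- stage("agreement", {
    fits <- purrr::map(config$responses, function(resp) {
      f <- fit_agreement(daily, response = resp)
      if (config$n_boot > 0) {
        f <- ccc_ci(f, n_boot = config$n_boot,
                    seed = derive_seed(config$seed, match(resp, config$responses)))
      }
      f
    })
    setNames(fits, config$responses)
  })
  scatter <- stage("scatter_stats", daily_scatter_stats(daily, config$responses))

  agreement_tbl <- purrr::map_dfr(fits, glance)
  shares_tbl <- purrr::map_dfr(fits, function(f) {
    mutate(variance_share_report(f), response = f$response)
  })

  readr::write_csv(exclusions, file.path(out_dir, "exclusion_report.csv"), progress = FALSE)
  jsonlite::write_json(accounting, file.path(out_dir, "exclusion_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(band_table, file.path(out_dir, "band_thresholds.csv"), progress = FALSE)
  readr::write_csv(daily, file.path(out_dir, "daily_aggregates.csv"), progress = FALSE)
  readr::write_csv(agreement_tbl, file.path(out_dir, "agreement_results.csv"), progress = FALSE)
  readr::write_csv(shares_tbl, file.path(out_dir, "variance_shares.csv"), progress = FALSE)
  readr::write_csv(scatter, file.path(out_dir, "scatter_stats.csv"), progress = FALSE)
  jsonlite::write_json(
    purrr::map(fits, function(f) {
      list(response = f$response, ccc = f$ccc,
           ccc_ci = if (is.null(f$ccc_ci)) NULL else as.numeric(f$ccc_ci),
           pearson_daily = f$pearson_daily, device_bias = f$device_bias,
           variance_components = as.list(c(
             var_subject = f$var_subject, var_subject_day = f$var_subject_day,
             var_subject_device = f$var_subject_device, s2_device = f$s2_device,
             var_error = f$var_error)))
    }),
    file.path(out_dir, "agreement_results.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  manifest <- write_manifest(config, out_dir, extra = list(accounting = accounting))

  invisible(list(exclusions = exclusions, bands = band_table, daily = daily,
                 agreement = fits, scatter = scatter, manifest = manifest))
}

#' Run the longitudinal cohort profile
#'
#' End-to-end: read cohort records and per-day band step counts, apply the
#' cohort validity rule (>= 18 h wear on >= 6 days per period by default),
#' average daily aggregates into period-level mean daily steps, summarise
#' stepping by period, compute the pfSTEP biomarker, fit the requested
#' association models with stepping x time interactions, and project the
#' configured stepping-change scenarios. Writes the report bundle to
#' `config$output_dir`.
#'
#' @param config A `pfstep_config` with `profile = "cohort"`.
#' @return Invisibly, a list with `period_summary`, `pfstep`, `fits`,
#'   `coefficients`, `model_fit`, `scenarios`, `period_change`, `manifest`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "pfstep_config"))
  if (config$profile != "cohort") abort("config profile must be 'cohort'")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("read_cohort", read_cohort(require_path(config$cohort, "cohort")))
  daily <- stage("read_daily", {
    readr::read_csv(require_path(config$daily, "daily stepping"),
                    show_col_types = FALSE, progress = FALSE)
  })
  need <- c("participant_id", "period", "non_walking", "slower_walking",
            "faster_walking", "wear_hours")
  if (!all(need %in% names(daily))) {
    abort(sprintf("daily stepping table needs columns: %s", paste(need, collapse = ", ")))
  }
  daily <- mutate(daily,
                  walking = .data$slower_walking + .data$faster_walking,
                  slower_paced = .data$non_walking + .data$slower_walking,
                  total = .data$non_walking + .data$walking)

  valid_periods <- stage("valid_periods",
                         valid_period_cohort(daily, min_hours = config$min_hours_cohort,
                                             min_days = config$min_days_cohort))
  if (nrow(valid_periods) == 0) {
    abort("no valid participant-periods under the wear criteria (empty report)",
          class = "pfstep_stage_error")
  }
  qualifying <- filter(daily, .data$wear_hours >= config$min_hours_cohort)
  period_agg <- stage("period_aggregation", aggregate_period(qualifying, valid_periods))

  period_summary <- period_agg %>%
    group_by(.data$period) %>%
    summarise(n = dplyr::n(),
              across(c("total", "non_walking", "slower_paced", "slower_walking",
                       "faster_walking"),
                     list(mean = mean, sd = sd)), .groups = "drop")

  baseline <- filter(period_agg, .data$period == min(.data$period))
  biomarker <- stage("pfstep", pfstep(slower = mean(baseline$slower_paced),
                                      faster = mean(baseline$faster_walking)))

  means_wide <- period_agg %>%
    group_by(.data$period) %>%
    summarise(across(c("total", "slower_paced", "faster_walking"), mean), .groups = "drop")
  change <- if (nrow(means_wide) >= 2) {
    period_change(means_wide, from = min(means_wide$period), to = max(means_wide$period))
  } else NULL

  model_data <- stage("prepare_association", prepare_association_data(cohort, period_agg))
  if (nrow(model_data) == 0) {
    abort("no valid participant-periods after applying the inclusion rules (empty report)",
          class = "pfstep_stage_error")
  }
  fits <- stage("association", {
    setNames(purrr::map(config$models, function(m) fit_association(model_data, model = m)),
             paste0("model", config$models))
  })
  coef_tbl <- purrr::map_dfr(fits, function(f) mutate(f$stepping, model = f$model_id))
  fit_tbl <- purrr::map_dfr(fits, glance)

  th <- config$scenario_thetas
  scenario_tbl <- purrr::map_dfr(config$scenarios, function(d) {
    scn <- scenario(d[1], d[2], theta_slower = th[["slower"]], theta_faster = th[["faster"]])
    tibble(delta_slower = d[1], delta_faster = d[2],
           theta_slower = th[["slower"]], theta_faster = th[["faster"]],
           sppb_change = project_scenario(scn))
  })

  readr::write_csv(period_summary, file.path(out_dir, "period_summary.csv"), progress = FALSE)
  readr::write_csv(coef_tbl, file.path(out_dir, "association_coefficients.csv"), progress = FALSE)
  readr::write_csv(fit_tbl, file.path(out_dir, "model_fit.csv"), progress = FALSE)
  readr::write_csv(scenario_tbl, file.path(out_dir, "scenarios.csv"), progress = FALSE)
  if (!is.null(change)) {
    readr::write_csv(change, file.path(out_dir, "period_change.csv"), progress = FALSE)
  }
  jsonlite::write_json(list(slower_paced_steps = biomarker$slower_paced_steps,
                            faster_paced_steps = biomarker$faster_paced_steps,
                            rendered = format(biomarker)),
                       file.path(out_dir, "pfstep.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  jsonlite::write_json(scenario_tbl, file.path(out_dir, "scenarios.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- write_manifest(config, out_dir,
                             extra = list(n_participants = dplyr::n_distinct(model_data$participant_id),
                                          n_participant_periods = nrow(model_data)))

  invisible(list(period_summary = period_summary, pfstep = biomarker, fits = fits,
                 coefficients = coef_tbl, model_fit = fit_tbl,
                 scenarios = scenario_tbl, period_change = change,
                 manifest = manifest))
}

#' Write simulated inputs for a pipeline profile
#'
#' Convenience wrapper that runs the requested simulator and writes its
#' outputs as the canonical CSV inputs of [run_paired()] / [run_cohort()],
#' with the ground truth beside them as JSON.
#'
#' @param profile `"paired"` or `"cohort"`.
#' @param dir Output directory (created if needed).
#' @param config A [paired_sim_config()] or [cohort_sim_config()]; defaults
#'   are used when `NULL`.
#' @return Named list of the file paths written.
#' @export
run_simulated_inputs <- function(profile = c("paired", "cohort"), dir,
                                 config = NULL) {
  profile <- rlang::arg_match(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (profile == "paired") {
    config <- config %||% paired_sim_config()
    sim <- simulate_paired_events(config)
    paths <- list(events = file.path(dir, "events.csv"),
                  wear = file.path(dir, "wear.csv"),
                  truth = file.path(dir, "truth.json"))
    write_events(sim$events, paths$events)
    write_wear(sim$wear, paths$wear)
    jsonlite::write_json(list(components = as.list(sim$truth$components),
                              device_bias = sim$truth$device_bias,
                              mu_total_steps = sim$truth$mu_total_steps),
                         paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    config <- config %||% cohort_sim_config()
    sim <- simulate_cohort(config, detail = "daily")
    paths <- list(cohort = file.path(dir, "cohort.csv"),
                  daily = file.path(dir, "daily_stepping.csv"),
                  truth = file.path(dir, "truth.json"))
    write_cohort(sim$cohort, paths$cohort)
    readr::write_csv(sim$daily, paths$daily, progress = FALSE)
    jsonlite::write_json(list(theta_slow_by_period = sim$truth$theta_slow_by_period,
                              theta_fast_by_period = sim$truth$theta_fast_by_period,
                              periods = sim$truth$periods,
                              intercept = sim$truth$intercept),
                         paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  paths
}
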