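# Synthetic longitudinal cohort with known ground truth: declining stepping
# over four recording periods and an SPPB outcome generated from a
# random-intercepts linear model with stepping x time effects.

#' Configuration for the longitudinal cohort simulator
#'
#' Defaults emulate a 651-participant older-adult cohort followed over four
#' recording periods (0, 6, 12, 24 months). Per-period band means and SDs
#' default to the published cohort summary ([react_stepping_means()]);
#' covariate prevalences default to the published population structure; and
#' SPPB is generated from a linear predictor with per-period stepping
#' effects (SPPB points per 1000 steps), covariate effects, a participant
#' random intercept, and residual noise, then rounded and clipped to the
#' 0-12 SPPB scale.
#'
#' Stepping is drawn per band on the log scale: a shared participant
#' activity factor (correlated across bands) plus period-level noise,
#' calibrated so each band's per-period mean and SD match the configured
#' targets. The per-period stepping effects `theta_*_by_period` are
#' *effective* slopes at each period; a downstream stepping x time model
#' recovers `theta(t) - theta(0)` as the interaction coefficient at t.
#'
#' @param n_participants Number of participants (>= 10).
#' @param periods Recording periods in months.
#' @param stepping_means_by_period,stepping_sds_by_period Data frames (or
#'   tibbles) with columns `non_walking`, `slower_walking`, `faster_walking`
#'   and one row per period: target mean and SD daily steps per band.
#' @param theta_slow_by_period,theta_fast_by_period Effective SPPB points
#'   per 1000 slower-paced (non-walking + slower walking) and faster-paced
#'   walking steps at each period. Defaults are the published fully adjusted
#'   two-band model: baseline effects 0.03 / 0.05 plus interaction gains of
#'   (0.04, 0.06, 0.13) / (0.22, 0.35, 0.53) at 6, 12, 24 months.
#' @param covariate_prevalences Named list of category probabilities for
#'   `sex`, `imd_quintile`, `education`, `comorbidity`, `sf36_class`,
#'   `allocation`, `site`; each must sum to 1.
#' @param covariate_effects Named list of additive SPPB effects per category
#'   (first level = reference = 0), plus `age` (per year, age centred at 77)
#'   and `allocation_by_period` (intervention effect at each period).
#' @param intercept Baseline SPPB linear-predictor intercept.
#' @param period_effects SPPB change at each period relative to baseline
#'   (time main effects); the default is a gradual age-related decline in
#'   physical function over follow-up.
#' @param var_random_intercept,var_residual Participant random-intercept and
#'   residual variances (SPPB^2).
#' @param missingness Per-period probability that a participant's recording
#'   period is invalid (insufficient wear); recycled to `length(periods)`.
#' @param activity_correlation Share of each band's log-scale variance
#'   attributable to the participant (persistent activity level).
#' @param n_days Days of accelerometer recording per period (daily detail).
#' @param seed Integer master seed.
#' @return A validated `cohort_sim_config` object (a list).
#' @export
cohort_sim_config <- function(n_participants = 651,
                              periods = c(0L, 6L, 12L, 24L),
                              stepping_means_by_period = NULL,
                              stepping_sds_by_period = NULL,
                              theta_slow_by_period = c(0.03, 0.07, 0.09, 0.16),
                              theta_fast_by_period = c(0.05, 0.27, 0.40, 0.58),
                              covariate_prevalences = NULL,
                              covariate_effects = NULL,
                              intercept = 8.7,
                              period_effects = c(0, -0.2, -0.4, -0.8),
                              var_random_intercept = 1.4,
                              var_residual = 0.5,
                              missingness = c(0.066, 0.132, 0.164, 0.226),
                              activity_correlation = 0.6,
                              n_days = 7, seed = 1L) {
  published <- react_stepping_means()
  stepping_means_by_period <- stepping_means_by_period %||%
    published[c("non_walking", "slower_walking", "faster_walking")]
  stepping_sds_by_period <- stepping_sds_by_period %||%
    setNames(published[c("non_walking_sd", "slower_walking_sd", "faster_walking_sd")],
             c("non_walking", "slower_walking", "faster_walking"))
  covariate_prevalences <- covariate_prevalences %||% list(
    sex = c(male = 217, female = 434) / 651,
    imd_quintile = c(69, 130, 130, 136, 186) / 651,
    education = setNames(c(291, 171, 189) / 651, .cohort_levels$education),
    comorbidity = setNames(c(549, 102) / 651, .cohort_levels$comorbidity),
    sf36_class = setNames(c(99, 310, 242) / 651, .cohort_levels$sf36_class),
    allocation = setNames(c(300, 351) / 651, .cohort_levels$allocation),
    site = setNames(c(278, 152, 221) / 651, .cohort_levels$site)
  )
  covariate_effects <- covariate_effects %||% list(
    age = -0.03,
    sex = c(0, -0.15),
    imd_quintile = c(0, 0.10, 0.15, 0.20, 0.25),
    education = c(0, 0.10, 0.20),
    comorbidity = c(0, -0.30),
    sf36_class = c(0, -0.40, -0.90),
    site = c(0, 0.05, -0.05),
    allocation_by_period = c(0, 0.20, 0.15, 0.10)
  )
  cfg <- list(n_participants = n_participants, periods = as.integer(periods),
              stepping_means_by_period = as_tibble(stepping_means_by_period),
              stepping_sds_by_period = as_tibble(stepping_sds_by_period),
              theta_slow_by_period = theta_slow_by_period,
              theta_fast_by_period = theta_fast_by_period,
              covariate_prevalences = covariate_prevalences,
              covariate_effects = covariate_effects,
              intercept = intercept, period_effects = period_effects,
              var_random_intercept = var_random_intercept,
              var_residual = var_residual,
              missingness = rep_len(missingness, length(periods)),
              activity_correlation = activity_correlation,
              n_days = n_days, seed = seed)
  validate_cohort_sim_config(cfg)
  structure(cfg, class = "cohort_sim_config")
}

#' @noRd
validate_cohort_sim_config <- function(cfg) {
  check_count(cfg$n_participants, "n_participants", min = 10)
  np <- length(cfg$periods)
  if (np < 2 || !all(cfg$periods %in% .cohort_periods)) {
    abort("invalid configuration: 'periods' must be at least two of 0, 6, 12, 24",
          class = "pfstep_config_error")
  }
  for (f in c("stepping_means_by_period", "stepping_sds_by_period")) {
    tab <- cfg[[f]]
    if (nrow(tab) != np ||
        !all(c("non_walking", "slower_walking", "faster_walking") %in% names(tab))) {
      abort(sprintf("invalid configuration: '%s' needs one row per period and the three band columns", f),
            class = "pfstep_config_error")
    }
    if (any(unlist(tab[c("non_walking", "slower_walking", "faster_walking")]) <= 0)) {
      abort(sprintf("invalid configuration: '%s' must be positive", f),
            class = "pfstep_config_error")
    }
  }
  for (f in c("theta_slow_by_period", "theta_fast_by_period")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != np || any(!is.finite(cfg[[f]]))) {
      abort(sprintf("invalid configuration: '%s' must be %d finite numbers", f, np),
            class = "pfstep_config_error")
    }
  }
  for (f in names(cfg$covariate_prevalences)) {
    p <- cfg$covariate_prevalences[[f]]
    check_prob(p, sprintf("covariate_prevalences$%s", f))
    if (abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("invalid configuration: 'covariate_prevalences$%s' must sum to 1", f),
            class = "pfstep_config_error")
    }
  }
  if (!is.numeric(cfg$period_effects) || length(cfg$period_effects) != np ||
      any(!is.finite(cfg$period_effects))) {
    abort(sprintf("invalid configuration: 'period_effects' must be %d finite numbers", np),
          class = "pfstep_config_error")
  }
  check_scalar_number(cfg$var_random_intercept, "var_random_intercept", min = 0)
  check_scalar_number(cfg$var_residual, "var_residual", min = 0)
  check_prob(cfg$missingness, "missingness")
  check_prob(cfg$activity_correlation, "activity_correlation")
  check_count(cfg$n_days, "n_days", min = 1)
  check_count(cfg$seed, "seed")
  invisible(cfg)
}

#' @noRd
draw_categorical <- function(n, probs) {
  lv <- names(probs) %||% as.character(seq_along(probs))
  factor(sample(lv, n, replace = TRUE, prob = probs), levels = lv)
}

#' Simulate a longitudinal stepping / physical-function cohort
#'
#' Generates (a) per-participant covariates, (b) stepping per participant-
#' period (as per-band mean daily steps, optionally expanded to daily values
#' with wear hours), and (c) the SPPB outcome from the configured
#' random-intercepts linear model, rounded and clipped to 0-12.
#' Period validity (wear-based missingness) is drawn per participant-period;
#' in `detail = "daily"` invalid periods receive fewer than six 18-hour wear
#' days so the cohort validity rule reproduces the configured missingness.
#' Deterministic for a fixed config and seed.
#'
#' @param config A [cohort_sim_config()].
#' @param detail `"period"` (default) returns stepping already aggregated to
#'   per-period mean daily steps for valid periods; `"daily"` additionally
#'   generates per-day band steps and wear hours for every period so the
#'   full two-stage aggregation and validity pipeline can run on the output.
#' @return A list with `cohort` (one row per participant-period: covariates
#'   + sppb), `stepping` (valid participant-periods with per-band mean daily
#'   steps; for `detail = "daily"` also `daily`, per-day band steps with
#'   `wear_hours`), and `truth` (thetas, covariate effects, random
#'   intercepts, validity flags, and the realised linear predictor).
#' @export
simulate_cohort <- function(config, detail = c("period", "daily")) {
  validate_cohort_sim_config(config)
  detail <- rlang::arg_match(detail)
  set.seed(config$seed)
  n <- config$n_participants
  periods <- config$periods
  np <- length(periods)
  ids <- sprintf("c%04d", seq_len(n))
  bands <- c("non_walking", "slower_walking", "faster_walking")

  prev <- config$covariate_prevalences
  covars <- tibble(
    participant_id = ids,
    age_at_recruitment = pmin(98, pmax(65, round(rnorm(n, 77, 7)))),
    sex = draw_categorical(n, prev$sex),
    imd_quintile = as.integer(as.character(draw_categorical(n, setNames(prev$imd_quintile, 1:5)))),
    education = draw_categorical(n, prev$education),
    comorbidity = draw_categorical(n, prev$comorbidity),
    sf36_class = draw_categorical(n, prev$sf36_class),
    allocation = draw_categorical(n, prev$allocation),
    site = draw_categorical(n, prev$site)
  )

  # stepping: per band, log-normal with a persistent participant activity
  # factor (shared standard-normal z_i) and period-level noise
  rho <- config$activity_correlation
  z <- rnorm(n)
  grid <- tidyr::expand_grid(i = seq_len(n), t = seq_len(np))
  step_mat <- matrix(0, nrow(grid), 3, dimnames = list(NULL, bands))
  for (b in seq_along(bands)) {
    mu_t <- config$stepping_means_by_period[[bands[b]]]
    sd_t <- config$stepping_sds_by_period[[bands[b]]]
    cv_t <- sd_t / mu_t
    sdlog_t <- sqrt(log(1 + cv_t^2))
    meanlog_t <- log(mu_t) - sdlog_t^2 / 2
    s_subj <- sqrt(rho) * sdlog_t[1]
    s_per <- sqrt(pmax(0, sdlog_t^2 - s_subj^2))
    draw <- exp(meanlog_t[grid$t] + s_subj * z[grid$i] +
                  rnorm(nrow(grid), 0, s_per[grid$t]))
    # winsorise at the 99.5th percentile: free-living stepping has
    # physiological maxima and the extreme log-normal tail is unrealistic
    # for this population
    cap <- stats::qlnorm(0.995, meanlog_t[grid$t], sdlog_t[grid$t])
    step_mat[, b] <- pmin(draw, cap)
  }

  valid <- matrix(runif(n * np) > rep(config$missingness, each = n), n, np)

  stepping <- tibble(
    participant_id = ids[grid$i],
    period = periods[grid$t],
    non_walking = step_mat[, 1],
    slower_walking = step_mat[, 2],
    faster_walking = step_mat[, 3]
  )

  daily <- NULL
  if (detail == "daily") {
    nd <- config$n_days
    # day-level multiplicative noise with mean 1; period exposure is the
    # realised mean of the daily values
    s_day <- 0.35
    drows <- tidyr::expand_grid(r = seq_len(nrow(grid)), day = seq_len(nd))
    mult <- matrix(exp(rnorm(nrow(drows) * 3, -s_day^2 / 2, s_day)), ncol = 3)
    daily_mat <- round(step_mat[drows$r, ] * mult)
    n_good <- ifelse(valid[cbind(grid$i, grid$t)], nd, sample(3:5, nrow(grid), TRUE))
    # sub-threshold wear on the trailing days of invalid periods; qualifying
    # wear (>= 18 h) on days meant to count
    wear_vec <- round(pmin(24, pmax(0, rnorm(nrow(drows), 22.5, 1))), 2)
    bad_day <- drows$day > n_good[drows$r]
    wear_vec[bad_day] <- round(runif(sum(bad_day), 8, 17.9), 2)
    wear_vec[!bad_day] <- pmax(wear_vec[!bad_day], 18.1)
    daily <- tibble(
      participant_id = stepping$participant_id[drows$r],
      period = stepping$period[drows$r],
      device = factor("wrist", levels = .devices),
      date = as.Date("2024-01-08") + (match(stepping$period[drows$r], periods) - 1L) * 183L +
        drows$day - 1L,
      day = drows$day,
      non_walking = as.integer(daily_mat[, 1]),
      slower_walking = as.integer(daily_mat[, 2]),
      faster_walking = as.integer(daily_mat[, 3]),
      wear_hours = wear_vec
    ) %>%
      mutate(total = .data$non_walking + .data$slower_walking + .data$faster_walking)
    # exposure actually seen downstream: mean over qualifying days
    qual <- !bad_day
    exp_means <- tibble(r = drows$r[qual],
                        nw = daily_mat[qual, 1], sw = daily_mat[qual, 2],
                        fw = daily_mat[qual, 3]) %>%
      group_by(.data$r) %>%
      summarise(non_walking = mean(.data$nw), slower_walking = mean(.data$sw),
                faster_walking = mean(.data$fw), .groups = "drop")
    step_used <- step_mat
    step_used[exp_means$r, ] <- as.matrix(exp_means[bands])
  } else {
    step_used <- step_mat
  }

  # SPPB linear predictor from the exposure the analysis will see
  eff <- config$covariate_effects
  covar_lp <- eff$age * (covars$age_at_recruitment - 77) +
    eff$sex[as.integer(covars$sex)] +
    eff$imd_quintile[covars$imd_quintile] +
    eff$education[as.integer(covars$education)] +
    eff$comorbidity[as.integer(covars$comorbidity)] +
    eff$sf36_class[as.integer(covars$sf36_class)] +
    eff$site[as.integer(covars$site)]
  alloc_lp <- ifelse(covars$allocation[grid$i] == "intervention",
                     eff$allocation_by_period[grid$t], 0)
  b_i <- rnorm(n, 0, sqrt(config$var_random_intercept))
  slower_paced_k <- (step_used[, 1] + step_used[, 2]) / 1000
  faster_k <- step_used[, 3] / 1000
  # stepping effects act on deviations from the configured period means, so
  # the thetas tilt the outcome without shifting its location over follow-up
  # (keeps the 0-12 clip a rarely-binding range invariant, not a censoring
  # mechanism; slopes are unaffected by centring)
  mt <- config$stepping_means_by_period
  slow_ctr <- (mt$non_walking + mt$slower_walking)[grid$t] / 1000
  fast_ctr <- mt$faster_walking[grid$t] / 1000
  lp <- config$intercept + config$period_effects[grid$t] + covar_lp[grid$i] + alloc_lp +
    config$theta_slow_by_period[grid$t] * (slower_paced_k - slow_ctr) +
    config$theta_fast_by_period[grid$t] * (faster_k - fast_ctr) +
    b_i[grid$i]
  sppb_raw <- lp + rnorm(nrow(grid), 0, sqrt(config$var_residual))
  sppb <- as.integer(pmin(12, pmax(0, round(sppb_raw))))

  cohort <- tibble(participant_id = ids[grid$i], period = periods[grid$t],
                   sppb = sppb) %>%
    left_join(covars, by = "participant_id")

  valid_vec <- valid[cbind(grid$i, grid$t)]
  stepping_out <- stepping %>%
    mutate(non_walking = step_used[, 1], slower_walking = step_used[, 2],
           faster_walking = step_used[, 3],
           walking = .data$slower_walking + .data$faster_walking,
           slower_paced = .data$non_walking + .data$slower_walking,
           total = .data$non_walking + .data$walking)
  stepping_valid <- stepping_out[valid_vec, , drop = FALSE]

  truth <- list(
    period_effects = config$period_effects,
    theta_slow_by_period = config$theta_slow_by_period,
    theta_fast_by_period = config$theta_fast_by_period,
    periods = periods,
    covariate_effects = eff,
    intercept = config$intercept,
    random_intercepts = tibble(participant_id = ids, b = b_i),
    valid = tibble(participant_id = ids[grid$i], period = periods[grid$t],
                   valid = valid_vec),
    linear_predictor = lp
  )
  out <- list(cohort = cohort, stepping = stepping_valid, truth = truth)
  if (!is.null(daily)) out$daily <- daily
  out
}
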