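# Synthetic paired-device stepping data with known ground truth.
#
# The generator works top-down: latent daily step totals follow a crossed
# variance-components model (subject, subject x day shared across devices,
# subject x device, residual, plus a fixed wrist-thigh offset), daily totals
# are split into cadence bands, and band totals are partitioned into
# variable-length stepping events whose cadences are drawn from truncated
# log-normal distributions. Summing the (valid) events of a day therefore
# reproduces the latent daily total exactly, so every downstream filter and
# aggregation step can be checked against known truth.

#' Configuration for the paired-device simulator
#'
#' Defaults emulate a 7-day paired wear protocol in active older adults:
#' mean daily total steps 9065 on the thigh-worn reference system with a
#' +656 steps/day wrist offset, an overall daily-total SD near 5100, and
#' variance shares of roughly 51% between participants, 37% between days,
#' 1% between device-participant pairings, with the remainder residual.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_days Days of recording per participant (>= 1).
#' @param mu_total_steps Mean daily total steps on the thigh system.
#' @param var_subject,var_day,var_subject_device,var_error Variance
#'   components of the latent daily totals (steps^2): between-subject,
#'   subject x day (shared by both devices), subject x device, residual.
#' @param device_bias Fixed wrist minus thigh offset in daily total steps.
#' @param device_cadence_shift Added to wrist event cadences (steps/min) so
#'   the two systems' median walking cadences can differ (e.g. 76 vs 74).
#' @param cadence_mixture Per-band event mixture: a list with elements
#'   `non_walking`, `slower_walking`, `faster_walking`, each a list of
#'   `share` (expected share of daily steps), `steps_per_event` (mean event
#'   step count), `cadence_meanlog`, `cadence_sdlog` (log-normal cadence
#'   parameters, truncated to the band's cadence range). Band ranges are
#'   \[20, 45), \[45, `band_split`\] and (`band_split`, 175\].
#' @param band_split Cadence (steps/min) separating the generator's slower
#'   and faster walking mixtures; the analysis pipeline re-estimates its own
#'   split from the data.
#' @param share_concentration Concentration of the day-to-day Dirichlet
#'   noise on band shares (larger = steadier composition).
#' @param wear_mean,wear_sd Mean and SD of daily wear hours (truncated to
#'   \[0, 24\]).
#' @param p_low_wear Probability a participant-day-device has sub-threshold
#'   wear (drawn uniformly on \[12, 19.9\] h) to exercise valid-day logic.
#' @param invalid_event_rate Expected number of deliberately invalid events
#'   (fewer than 10 steps, or cadence outside \[20, 175\]) injected per
#'   participant-day-device, to exercise the event filters.
#' @param seed Integer master seed.
#' @return A validated `paired_sim_config` object (a list).
#' @export
paired_sim_config <- function(n_participants = 56, n_days = 7,
                              mu_total_steps = 9065,
                              var_subject = 1.33e7, var_day = 9.6e6,
                              var_subject_device = 2.6e5, var_error = 2.8e6,
                              device_bias = 656, device_cadence_shift = 2,
                              cadence_mixture = NULL, band_split = 75,
                              share_concentration = 60,
                              wear_mean = 22.8, wear_sd = 0.6,
                              p_low_wear = 0.04, invalid_event_rate = 0.5,
                              seed = 1L) {
  cadence_mixture <- cadence_mixture %||% list(
    non_walking = list(share = 0.35, steps_per_event = 16,
                       cadence_meanlog = log(33), cadence_sdlog = 0.18),
    slower_walking = list(share = 0.33, steps_per_event = 40,
                          cadence_meanlog = log(62), cadence_sdlog = 0.16),
    faster_walking = list(share = 0.32, steps_per_event = 120,
                          cadence_meanlog = log(95), cadence_sdlog = 0.18)
  )
  cfg <- list(n_participants = n_participants, n_days = n_days,
              mu_total_steps = mu_total_steps, var_subject = var_subject,
              var_day = var_day, var_subject_device = var_subject_device,
              var_error = var_error, device_bias = device_bias,
              device_cadence_shift = device_cadence_shift,
              cadence_mixture = cadence_mixture, band_split = band_split,
              share_concentration = share_concentration,
              wear_mean = wear_mean, wear_sd = wear_sd,
              p_low_wear = p_low_wear, invalid_event_rate = invalid_event_rate,
              seed = seed)
  validate_paired_sim_config(cfg)
  structure(cfg, class = "paired_sim_config")
}

#' @noRd
validate_paired_sim_config <- function(cfg) {
  check_count(cfg$n_participants, "n_participants", min = 2)
  check_count(cfg$n_days, "n_days", min = 1)
  check_scalar_number(cfg$mu_total_steps, "mu_total_steps", min = 0)
  for (f in c("var_subject", "var_day", "var_subject_device", "var_error")) {
    check_scalar_number(cfg[[f]], f, min = 0)
  }
  check_scalar_number(cfg$device_bias, "device_bias")
  check_prob(cfg$p_low_wear, "p_low_wear")
  check_scalar_number(cfg$invalid_event_rate, "invalid_event_rate", min = 0)
  check_scalar_number(cfg$band_split, "band_split", min = 45, max = 175)
  bands <- c("non_walking", "slower_walking", "faster_walking")
  if (!is.list(cfg$cadence_mixture) || !all(bands %in% names(cfg$cadence_mixture))) {
    abort("invalid configuration: 'cadence_mixture' must define non_walking, slower_walking and faster_walking",
          class = "pfstep_config_error")
  }
  for (b in bands) {
    mx <- cfg$cadence_mixture[[b]]
    loc <- exp(mx$cadence_meanlog)
    if (!is.finite(loc) || loc < 20 || loc > 175) {
      abort(sprintf("invalid configuration: 'cadence_mixture$%s$cadence_meanlog' implies a location outside [20, 175]", b),
            class = "pfstep_config_error")
    }
    check_scalar_number(mx$share, sprintf("cadence_mixture$%s$share", b), min = 0, max = 1)
    check_scalar_number(mx$steps_per_event, sprintf("cadence_mixture$%s$steps_per_event", b), min = 10)
  }
  check_count(cfg$seed, "seed")
  invisible(cfg)
}

#' @noRd
band_ranges <- function(cfg) {
  list(non_walking = c(20, 45 - 1e-9),
       slower_walking = c(45, cfg$band_split),
       faster_walking = c(cfg$band_split + 1e-9, 175))
}

#' Simulate latent paired daily step totals
#'
#' First stage of [simulate_paired_events()]: draws the latent daily band
#' step counts for both devices from the variance-components model, without
#' constructing event streams. Useful when only daily aggregates are needed
#' (e.g. agreement simulations).
#'
#' @param config A [paired_sim_config()].
#' @return A list with `daily` (tibble: participant_id, device, day, date,
#'   band step counts and total) and `truth` (the variance components,
#'   device bias, and latent random effects actually drawn).
#' @export
simulate_paired_daily <- function(config) {
  validate_paired_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  d <- config$n_days
  ids <- sprintf("p%03d", seq_len(n))

  alpha <- rnorm(n, 0, sqrt(config$var_subject))
  gamma <- matrix(rnorm(n * d, 0, sqrt(config$var_day)), n, d)
  ab <- matrix(rnorm(n * 2, 0, sqrt(config$var_subject_device)), n, 2)

  grid <- tidyr::expand_grid(i = seq_len(n), day = seq_len(d), j = 1:2)
  eps <- rnorm(nrow(grid), 0, sqrt(config$var_error))
  latent <- config$mu_total_steps + config$device_bias * (grid$j == 2) +
    alpha[grid$i] + gamma[cbind(grid$i, grid$day)] + ab[cbind(grid$i, grid$j)] + eps
  total <- pmax(0L, as.integer(round(latent)))

  shares <- vapply(config$cadence_mixture, function(m) m$share, numeric(1))
  shares <- shares / sum(shares)
  conc <- config$share_concentration
  g <- matrix(stats::rgamma(nrow(grid) * 3, shape = rep(shares * conc, each = nrow(grid))),
              nrow(grid), 3)
  g <- g / rowSums(g)
  band_steps <- t(vapply(seq_len(nrow(grid)),
                         function(r) round_preserving_sum(total[r] * g[r, ]),
                         integer(3)))

  daily <- tibble(
    participant_id = ids[grid$i],
    device = factor(.devices[grid$j], levels = .devices),
    day = grid$day,
    date = as.Date("2024-05-06") + grid$day - 1L,
    non_walking = band_steps[, 1],
    slower_walking = band_steps[, 2],
    faster_walking = band_steps[, 3],
    walking = band_steps[, 2] + band_steps[, 3],
    slower_paced = band_steps[, 1] + band_steps[, 2],
    total = total
  )
  truth <- list(
    components = c(var_subject = config$var_subject, var_day = config$var_day,
                   var_subject_device = config$var_subject_device,
                   var_error = config$var_error),
    device_bias = config$device_bias,
    mu_total_steps = config$mu_total_steps,
    subject_effects = tibble(participant_id = ids, alpha = alpha),
    latent_total = latent
  )
  list(daily = daily, truth = truth)
}

# Partition `steps` into n events of >= 10 steps each; returns integer vector.
#' @noRd
partition_steps <- function(steps, steps_per_event) {
  n_ev <- max(1L, min(steps %/% 10L, as.integer(round(steps / steps_per_event))))
  if (n_ev == 1L) return(steps)
  extra <- stats::rmultinom(1, steps - 10L * n_ev, rep(1, n_ev))[, 1]
  as.integer(10L + extra)
}

#' @noRd
rcadence_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qlnorm(u, meanlog, sdlog)))
}

#' Simulate paired-device stepping event streams
#'
#' Generates event tables for a thigh-worn reference system and a wrist-worn
#' system worn simultaneously, a daily wear-hours table, and the ground
#' truth used. Each participant-device-day's valid events sum exactly to the
#' latent daily total; a configurable number of deliberately invalid events
#' (fewer than 10 steps, or cadence outside the 20-175 steps/min range) is
#' injected on top so that the event filters have something to remove.
#' Deterministic for a fixed config and seed.
#'
#' @param config A [paired_sim_config()].
#' @return A list with `events` (canonical event tibble incl. cadence),
#'   `wear` (participant_id, device, date, wear_hours), and `truth` (as in
#'   [simulate_paired_daily()], plus the injected-invalid-event count).
#' @export
simulate_paired_events <- function(config) {
  sim <- simulate_paired_daily(config)
  daily <- sim$daily
  ranges <- band_ranges(config)
  bands <- names(ranges)

  rows <- vector("list", nrow(daily) * 3L)
  k <- 0L
  for (r in seq_len(nrow(daily))) {
    # roll bands that cannot host a valid (>= 10 step) event into the
    # largest band of the day, preserving the daily total
    bs <- c(daily$non_walking[r], daily$slower_walking[r], daily$faster_walking[r])
    small <- bs > 0 & bs < 10
    if (any(small)) {
      bs[which.max(bs)] <- bs[which.max(bs)] + sum(bs[small])
      bs[small] <- 0L
    }
    for (b in seq_along(bands)) {
      if (bs[b] <= 0) next
      mx <- config$cadence_mixture[[bands[b]]]
      steps <- partition_steps(bs[b], mx$steps_per_event)
      shift <- if (daily$device[r] == "wrist") config$device_cadence_shift else 0
      cad <- rcadence_trunc(length(steps), mx$cadence_meanlog, mx$cadence_sdlog,
                            ranges[[b]][1], ranges[[b]][2])
      cad <- pmin(ranges[[b]][2], pmax(ranges[[b]][1], cad + shift))
      k <- k + 1L
      rows[[k]] <- tibble(
        participant_id = daily$participant_id[r],
        device = daily$device[r],
        date = daily$date[r],
        tod = sort(round(runif(length(steps), 7 * 3600, 21 * 3600))),
        duration_s = steps / cad * 60,
        steps = steps,
        cadence = cad
      )
    }
  }
  events <- bind_rows(rows[seq_len(k)])

  # injected invalid events: half too few steps, a quarter below 20 steps/min,
  # a quarter above 175 steps/min
  n_cells <- nrow(daily)
  n_bad <- rpois(1, config$invalid_event_rate * n_cells)
  if (n_bad > 0) {
    cell <- sample.int(n_cells, n_bad, replace = TRUE)
    kind <- sample.int(4, n_bad, replace = TRUE)
    bad_steps <- ifelse(kind <= 2, sample(1:9, n_bad, replace = TRUE),
                        sample(10:60, n_bad, replace = TRUE))
    bad_cad <- ifelse(kind <= 2, runif(n_bad, 20, 100),
                      ifelse(kind == 3, runif(n_bad, 5, 19.5), runif(n_bad, 175.5, 200)))
    bad <- tibble(
      participant_id = daily$participant_id[cell],
      device = daily$device[cell],
      date = daily$date[cell],
      tod = round(runif(n_bad, 7 * 3600, 21 * 3600)),
      duration_s = bad_steps / bad_cad * 60,
      steps = as.integer(bad_steps),
      cadence = bad_cad
    )
    events <- bind_rows(events, bad)
  }

  events <- events %>%
    mutate(start = as.POSIXct(.data$date, tz = "UTC") + .data$tod) %>%
    arrange(.data$participant_id, .data$device, .data$start) %>%
    select("participant_id", "device", "start", "duration_s", "steps", "cadence")

  wear_grid <- distinct(daily, .data$participant_id, .data$device, .data$date)
  low <- runif(nrow(wear_grid)) < config$p_low_wear
  hours <- pmin(24, pmax(0, rnorm(nrow(wear_grid), config$wear_mean, config$wear_sd)))
  hours[low] <- runif(sum(low), 12, 19.9)
  wear <- mutate(wear_grid, wear_hours = round(hours, 2))

  truth <- sim$truth
  truth$daily <- daily
  truth$n_invalid_events <- if (exists("n_bad")) n_bad else 0L
  list(events = events, wear = wear, truth = truth)
}
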