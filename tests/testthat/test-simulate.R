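test_that("paired simulator is deterministic for a fixed config and seed", {
  cfg <- paired_sim_config(n_participants = 4, n_days = 3, seed = 77)
  a <- simulate_paired_events(cfg)
  b <- simulate_paired_events(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$wear, b$wear)
  expect_identical(a$truth$daily, b$truth$daily)
  c <- simulate_paired_events(paired_sim_config(n_participants = 4, n_days = 3, seed = 78))
  expect_false(identical(a$events$steps, c$events$steps))
})

test_that("degenerate variances give identical thigh and wrist daily totals", {
  cfg <- paired_sim_config(n_participants = 5, n_days = 4,
                           var_day = 0, var_subject_device = 0, var_error = 0,
                           device_bias = 0, seed = 9)
  sim <- simulate_paired_daily(cfg)
  wide <- tidyr::pivot_wider(sim$daily[c("participant_id", "day", "device", "total")],
                             names_from = "device", values_from = "total")
  expect_equal(wide$thigh, wide$wrist)
})

test_that("valid events conserve the latent daily totals exactly", {
  cfg <- paired_sim_config(n_participants = 6, n_days = 4, seed = 31,
                           invalid_event_rate = 1)
  sim <- simulate_paired_events(cfg)
  valid <- sim$events[sim$events$steps >= 10 &
                        sim$events$cadence >= 20 & sim$events$cadence <= 175, ]
  sums <- valid %>%
    dplyr::mutate(date = as.Date(start, tz = "UTC")) %>%
    dplyr::group_by(participant_id, device, date) %>%
    dplyr::summarise(total = sum(steps), .groups = "drop")
  chk <- dplyr::inner_join(sums, sim$truth$daily,
                           by = c("participant_id", "device", "date"),
                           suffix = c("", ".latent"))
  expect_equal(nrow(chk), nrow(sim$truth$daily))
  expect_equal(chk$total, chk$total.latent)
  # invalid events were actually injected (filters have work to do)
  expect_gt(nrow(sim$events), nrow(valid))
})

test_that("method-of-moments on latent daily totals recovers the components", {
  cfg <- paired_sim_config(n_participants = 500, n_days = 7,
                           var_subject = 9e5, var_day = 6e5,
                           var_subject_device = 5e4, var_error = 5e4,
                           device_bias = 0, seed = 202)
  sim <- simulate_paired_daily(cfg)
  d <- sim$daily
  wide <- tidyr::pivot_wider(d[c("participant_id", "day", "device", "total")],
                             names_from = "device", values_from = "total")
  # covariance structure of y_ijk:
  #   same day, different device     -> var_subject + var_day
  #   same device, different days    -> var_subject + var_subject_device
  #   different device and days      -> var_subject
  c_same_day <- cov(wide$thigh, wide$wrist)
  by_id <- split(wide, wide$participant_id)
  lag_pairs <- function(x, y) {
    n <- length(x)
    i <- rep(seq_len(n), each = n); j <- rep(seq_len(n), times = n)
    keep <- i != j
    cbind(x[i[keep]], y[j[keep]])
  }
  same_dev <- do.call(rbind, lapply(by_id, function(g) rbind(
    lag_pairs(g$thigh, g$thigh), lag_pairs(g$wrist, g$wrist))))
  diff_dev <- do.call(rbind, lapply(by_id, function(g) lag_pairs(g$thigh, g$wrist)))
  c_same_dev <- cov(same_dev[, 1], same_dev[, 2])
  c_diff <- cov(diff_dev[, 1], diff_dev[, 2])
  v_tot <- var(c(wide$thigh, wide$wrist))

  est <- c(subject = c_diff, day = c_same_day - c_diff,
           subject_device = c_same_dev - c_diff,
           error = v_tot - c_same_day - (c_same_dev - c_diff))
  truth <- c(9e5, 6e5, 5e4, 5e4)
  expect_true(all(abs(est - truth) / truth < 0.10))
})

test_that("paired defaults emulate the reference daily total level", {
  sim <- simulate_paired_daily(paired_sim_config(seed = 606))
  thigh <- sim$daily$total[sim$daily$device == "thigh"]
  se <- sd(thigh) / sqrt(length(unique(sim$daily$participant_id)))
  expect_lt(abs(mean(thigh) - 9065), 2 * se)
})

test_that("invalid simulator configurations name the offending field", {
  expect_error(paired_sim_config(n_participants = 1), "n_participants",
               class = "pfstep_config_error")
  expect_error(paired_sim_config(var_subject = -1), "var_subject",
               class = "pfstep_config_error")
  expect_error(
    paired_sim_config(cadence_mixture = list(
      non_walking = list(share = 0.4, steps_per_event = 16,
                         cadence_meanlog = log(10), cadence_sdlog = 0.2),
      slower_walking = list(share = 0.3, steps_per_event = 40,
                            cadence_meanlog = log(62), cadence_sdlog = 0.2),
      faster_walking = list(share = 0.3, steps_per_event = 120,
                            cadence_meanlog = log(95), cadence_sdlog = 0.2))),
    "cadence_meanlog", class = "pfstep_config_error")
  expect_error(cohort_sim_config(missingness = 1.5), "missingness",
               class = "pfstep_config_error")
  expect_error(cohort_sim_config(theta_fast_by_period = c(1, 2)),
               "theta_fast_by_period", class = "pfstep_config_error")
})

test_that("cohort simulator is deterministic and respects the SPPB range", {
  cfg <- cohort_sim_config(n_participants = 40, seed = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$stepping, b$stepping)
  expect_true(all(a$cohort$sppb >= 0 & a$cohort$sppb <= 12))
  expect_true(all(a$cohort$sppb == floor(a$cohort$sppb)))
  expect_true(all(levels(a$cohort$sf36_class) ==
                    c("very good/excellent", "good", "fair/poor")))
})

test_that("null stepping effects leave SPPB uncorrelated with stepping", {
  cfg <- cohort_sim_config(n_participants = 400,
                           theta_slow_by_period = rep(0, 4),
                           theta_fast_by_period = rep(0, 4),
                           var_random_intercept = 0, seed = 55)
  sim <- simulate_cohort(cfg)
  dat <- dplyr::inner_join(sim$cohort, sim$stepping,
                           by = c("participant_id", "period"))
  r <- cor(dat$sppb, dat$total)
  expect_lt(abs(r), 3 / sqrt(nrow(dat)))
})

test_that("cohort defaults reproduce the baseline stepping level", {
  sim <- simulate_cohort(cohort_sim_config(seed = 77))
  base <- sim$stepping[sim$stepping$period == 0, ]
  se <- sd(base$total) / sqrt(nrow(base))
  expect_lt(abs(mean(base$total) - 5815), 2 * se)
})

test_that("daily detail feeds the two-stage aggregation with matching exposure", {
  sim <- simulate_cohort(cohort_sim_config(n_participants = 30, seed = 41),
                         detail = "daily")
  expect_true(all(c("wear_hours", "period", "non_walking") %in% names(sim$daily)))
  vp <- valid_period_cohort(sim$daily)
  # validity derived from wear matches the generator's missingness draws
  truth_valid <- sim$truth$valid[sim$truth$valid$valid, c("participant_id", "period")]
  expect_equal(dplyr::arrange(vp, participant_id, period),
               dplyr::arrange(truth_valid, participant_id, period))
  # period aggregation over qualifying days reproduces the stepping table
  qual <- sim$daily[sim$daily$wear_hours >= 18, ]
  qual$total <- qual$non_walking + qual$slower_walking + qual$faster_walking
  qual$walking <- qual$slower_walking + qual$faster_walking
  qual$slower_paced <- qual$non_walking + qual$slower_walking
  agg <- aggregate_period(qual[setdiff(names(qual), c("device", "wear_hours"))], vp)
  chk <- dplyr::inner_join(agg, sim$stepping, by = c("participant_id", "period"),
                           suffix = c(".agg", ".sim"))
  expect_equal(nrow(chk), nrow(sim$stepping))
  expect_equal(chk$total.agg, chk$total.sim, tolerance = 1e-12)
})
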