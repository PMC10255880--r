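test_that("event filters remove short, out-of-range, and late events", {
  # fixture of 10 events: 2 below the step minimum, 1 slow, 1 fast, 1 on day 8
  ev <- dplyr::bind_rows(
    event_at(60, steps = 9, start = "2024-05-06 10:00:00"),    # too few steps
    event_at(60, steps = 5, start = "2024-05-07 10:00:00"),    # too few steps
    event_at(19.9, start = "2024-05-08 10:00:00"),             # below 20 steps/min
    event_at(176, start = "2024-05-09 10:00:00"),              # above 175 steps/min
    event_at(60, start = "2024-05-13 10:00:00"),               # day 8
    event_at(20, start = "2024-05-06 12:00:00"),               # inclusive boundary
    event_at(175, start = "2024-05-10 10:00:00"),              # inclusive boundary
    event_at(45, start = "2024-05-11 10:00:00"),
    event_at(90, start = "2024-05-12 10:00:00"),
    event_at(120, start = "2024-05-12 11:00:00")
  )
  kept <- filter_events(ev)
  expect_equal(nrow(kept), 5)
  rep <- attr(kept, "exclusions")
  expect_equal(rep$events_removed[rep$rule == "min_steps"], 2L)
  expect_equal(rep$events_removed[rep$rule == "cadence_low"], 1L)
  expect_equal(rep$events_removed[rep$rule == "cadence_high"], 1L)
  expect_equal(rep$events_removed[rep$rule == "beyond_max_days"], 1L)
  # counts add up
  expect_equal(nrow(ev), nrow(kept) + sum(rep$events_removed))
  # brute-force oracle over the same fixture
  dates <- as.Date(ev$start, tz = "UTC")
  first7 <- head(sort(unique(dates)), 7)
  brute <- ev[ev$steps >= 10 & ev$cadence >= 20 & ev$cadence <= 175 &
                dates %in% first7, ]
  expect_equal(kept$cadence, brute$cadence)
})

test_that("boundary cadences 20 and 175 are kept, 9 steps removed", {
  expect_equal(nrow(filter_events(event_at(20))), 1)
  expect_equal(nrow(filter_events(event_at(175))), 1)
  expect_equal(nrow(filter_events(event_at(60, steps = 9))), 0)
})

test_that("filtering is idempotent and ignores empty input", {
  sim <- simulate_paired_events(paired_sim_config(n_participants = 4, n_days = 3, seed = 21))
  once <- filter_events(sim$events)
  twice <- filter_events(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$steps, twice$steps)
  expect_equal(sum(attr(twice, "exclusions")$events_removed), 0)
  empty <- filter_events(once[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("paired valid days require both devices at the threshold", {
  # one below threshold
  w1 <- make_wear(c("p1", "p1"), c("thigh", "wrist"), "2024-05-06", c(21, 19.5))
  expect_equal(nrow(valid_days_paired(w1)), 0)
  # both exactly at 20 h: inclusive
  w2 <- make_wear(c("p1", "p1"), c("thigh", "wrist"), "2024-05-06", c(20, 20))
  expect_equal(nrow(valid_days_paired(w2)), 1)

  # 6 participant-dates vs brute-force intersection
  w <- make_wear(
    rep(c("p1", "p2", "p3"), each = 4),
    rep(c("thigh", "wrist"), 6),
    rep(rep(c("2024-05-06", "2024-05-07"), each = 2), 3),
    c(23, 22, 19, 21, 20, 20, 24, 24, 21, 12, 18, 23)
  )
  got <- valid_days_paired(w)
  wide <- tidyr::pivot_wider(w, names_from = device, values_from = wear_hours)
  want <- wide[wide$thigh >= 20 & wide$wrist >= 20, c("participant_id", "date")]
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("cohort period validity counts qualifying days", {
  w6 <- make_wear("p1", rep("wrist", 6), as.Date("2024-05-06") + 0:5,
                  rep(18, 6), period = 0)
  expect_equal(nrow(valid_period_cohort(w6)), 1)
  w7 <- make_wear("p1", rep("wrist", 7), as.Date("2024-05-06") + 0:6,
                  rep(17.9, 7), period = 0)
  expect_equal(nrow(valid_period_cohort(w7)), 0)
  # counting oracle on a mixed fixture
  w <- dplyr::bind_rows(
    make_wear("p1", rep("wrist", 7), as.Date("2024-05-06") + 0:6,
              c(20, 20, 20, 20, 20, 17, 18), period = 0),
    make_wear("p2", rep("wrist", 7), as.Date("2024-05-06") + 0:6,
              c(20, 20, 20, 20, 20, 17, 16), period = 0)
  )
  got <- valid_period_cohort(w)
  counts <- tapply(w$wear_hours >= 18, w$participant_id, sum)
  expect_equal(got$participant_id, names(counts)[counts >= 6])
  expect_error(valid_period_cohort(make_wear("p1", "wrist", "2024-05-06", 20)),
               "period")
})

test_that("median walking cadence is the unweighted event median above 45", {
  ev <- dplyr::bind_rows(lapply(c(50, 60, 70, 80), event_at))
  expect_equal(median_walking_cadence(ev), 65)
  # constant cadence
  evc <- dplyr::bind_rows(lapply(rep(72, 5), event_at))
  expect_equal(median_walking_cadence(evc), 72)
  # step counts do not weight the median
  ev_w <- dplyr::bind_rows(event_at(50, steps = 10000), event_at(60, steps = 10),
                           event_at(70, steps = 10))
  expect_equal(median_walking_cadence(ev_w), 60)
  # sub-threshold events are excluded; none left -> error
  expect_equal(median_walking_cadence(dplyr::bind_rows(ev, event_at(30))), 65)
  expect_error(median_walking_cadence(event_at(30)), "walking")
  # invariant to order and duplication
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(median_walking_cadence(shuf), 65)
  expect_equal(median_walking_cadence(dplyr::bind_rows(ev, ev)), 65)
})

test_that("daily aggregation assigns bands around the median split", {
  bands <- cadence_bands(76)
  # wrist event at cadence 80 with 100 steps: above the split -> faster-paced
  ev <- event_at(80, steps = 100)
  daily <- aggregate_daily(ev, bands)
  expect_equal(daily$faster_walking, 100L)
  expect_equal(daily$slower_walking, 0L)
  expect_equal(daily$total, 100L)
  # an event exactly at the median is slower-paced ("below and including")
  exact <- make_events("p1", "wrist", "2024-05-06 10:00:00", 60, 76)  # cadence 76
  at_median <- aggregate_daily(exact, bands)
  expect_equal(at_median$slower_walking, 76L)
  # no valid days -> empty
  none <- aggregate_daily(ev, bands,
                          valid_days = tibble::tibble(participant_id = character(),
                                                      date = as.Date(character())))
  expect_equal(nrow(none), 0)
})

test_that("daily band sums match a brute-force per-event assignment", {
  set.seed(91)
  cad <- runif(12, 20, 175)
  steps <- sample(10:300, 12, replace = TRUE)
  ev <- dplyr::bind_rows(purrr::map2(cad, steps, function(c, s) {
    event_at(c, steps = s,
             start = sample(c("2024-05-06 09:00:00", "2024-05-07 09:00:00"), 1))
  }))
  bands <- cadence_bands(70)
  daily <- aggregate_daily(ev, bands)
  date <- as.Date(ev$start, tz = "UTC")
  for (d in unique(date)) {
    sel <- date == d
    row <- daily[daily$date == d, ]
    expect_equal(row$non_walking, sum(ev$steps[sel & ev$cadence < 45]))
    expect_equal(row$slower_walking, sum(ev$steps[sel & ev$cadence >= 45 & ev$cadence <= 70]))
    expect_equal(row$faster_walking, sum(ev$steps[sel & ev$cadence > 70]))
  }
  # partition identities
  expect_true(all(daily$total == daily$non_walking + daily$walking))
  expect_true(all(daily$walking == daily$slower_walking + daily$faster_walking))
  expect_true(all(daily$slower_paced + daily$faster_walking == daily$total))
})

test_that("adding an event that violates any filter leaves aggregates unchanged", {
  sim <- simulate_paired_events(paired_sim_config(n_participants = 3, n_days = 3,
                                                  seed = 5, invalid_event_rate = 0))
  bands <- cadence_bands(70)
  base <- aggregate_daily(filter_events(sim$events), bands)
  polluted <- dplyr::bind_rows(
    sim$events,
    event_at(60, steps = 9, participant_id = "p001", start = "2024-05-06 09:00:00"),
    event_at(15, steps = 50, participant_id = "p002", start = "2024-05-06 09:00:00"),
    event_at(190, steps = 50, participant_id = "p003", start = "2024-05-06 09:00:00")
  )
  again <- aggregate_daily(filter_events(polluted), bands)
  expect_equal(as.data.frame(again), as.data.frame(base))
})

test_that("period aggregation averages valid days", {
  daily <- tibble::tibble(
    participant_id = "c1", period = 0L,
    date = as.Date("2024-05-06") + 0:1,
    non_walking = c(3000L, 4000L), slower_walking = c(500L, 1000L),
    faster_walking = c(500L, 1000L), walking = c(1000L, 2000L),
    slower_paced = c(3500L, 5000L), total = c(4000L, 6000L)
  )
  agg <- aggregate_period(daily)
  expect_equal(agg$total, 5000)
  expect_equal(agg$n_days, 2L)
  single <- aggregate_period(daily[1, ])
  expect_equal(single$total, 4000)
  # valid-period restriction drops excluded periods
  agg2 <- aggregate_period(daily, valid_periods = tibble::tibble(
    participant_id = "c9", period = 0L))
  expect_equal(nrow(agg2), 0)
})

test_that("pfSTEP components are integers that sum to the rounded total", {
  b <- pfstep(slower = 6931.0, faster = 428.0, split_cadence = 62)
  expect_identical(b$slower_paced_steps, 6931L)
  expect_identical(b$faster_paced_steps, 428L)
  expect_equal(format(b), "(6931; 428)")
  expect_equal(format(pfstep(slower = 0, faster = 0)), "(0; 0)")
  # rounding ties: components must sum to the rounded mean total
  tie <- pfstep(slower = 100.5, faster = 100.5)
  expect_equal(tie$slower_paced_steps + tie$faster_paced_steps, 201L)
  # property: sum identity over random values
  set.seed(14)
  for (i in 1:50) {
    s <- runif(1, 0, 10000); f <- runif(1, 0, 5000)
    p <- pfstep(slower = s, faster = f)
    expect_identical(p$slower_paced_steps + p$faster_paced_steps,
                     as.integer(round(s + f)))
  }
})

test_that("period change reproduces declines and percent reductions", {
  means <- react_stepping_means()
  ch <- period_change(means, from = 0, to = 24)
  expect_equal(ch$change[ch$band == "total"], 944)
  expect_equal(ch$change[ch$band == "slower_paced"], 708)
  expect_equal(ch$change[ch$band == "faster_walking"], 236)
  expect_equal(ch$percent[ch$band == "total"], 16L)
  expect_equal(ch$percent[ch$band == "faster_walking"], 26L)
  # identical summaries -> zero change
  same <- period_change(means[c(1, 1), ] %>% dplyr::mutate(period = c(0, 24)),
                        from = 0, to = 24)
  expect_true(all(same$change == 0))
  # zero baseline flagged, percent undefined
  z <- period_change(tibble::tibble(period = c(0, 24), total = c(0, 10)),
                     from = 0, to = 24)
  expect_true(z$zero_baseline)
  expect_true(is.na(z$percent))
})

test_that("cadence band construction enforces the ordering invariant", {
  expect_error(cadence_bands(40), class = "pfstep_config_error")
  expect_error(cadence_bands(180), class = "pfstep_config_error")
  b <- cadence_bands(62)
  expect_output(print(b), "62")
})
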