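test_that("total effect adds the interaction contrast to the baseline", {
  # printed-coefficient layout: baseline 0.04, 24-month interaction 0.21
  st <- tibble::tibble(
    band = "total", time = c(0L, 6L, 12L, 24L),
    role = c("baseline", "interaction", "interaction", "interaction"),
    estimate = c(0.04, 0.07, 0.12, 0.21)
  )
  expect_equal(total_effect(st, "total", 24), 0.25)
  expect_equal(total_effect(st, "total", 0), 0.04)
  expect_equal(total_effect(st, "total", 6), 0.11)
  expect_error(total_effect(st, "faster_walking", 24), "no stepping term")
  expect_error(total_effect(st, "total", 18), "no interaction coefficient")
})

test_that("scenario projections reproduce the worked SPPB examples", {
  expect_equal(project_scenario(scenario(-0.708, -0.236)), -0.22)
  expect_equal(project_scenario(scenario(0.5, 0.5)), 0.33)
  expect_equal(project_scenario(scenario(-0.5, 1.0)), 0.47)
  # arbitrary thetas: plain bilinear arithmetic to 2 decimals
  expect_equal(project_scenario(scenario(1, 1, theta_slower = 0.2, theta_faster = 0.3)),
               0.5)
  expect_error(scenario("a", 1))
})

test_that("relative increases match the printed baseline percentages", {
  means <- react_stepping_means()
  base <- means[means$period == 0, ]
  expect_equal(relative_increase(1000, base$total), 17L)
  expect_equal(relative_increase(1000, base$slower_paced), 20L)
  expect_equal(relative_increase(1000, base$slower_walking), 172L)
  expect_equal(relative_increase(1000, base$faster_walking), 112L)
  expect_equal(relative_increase(0, 500), 0L)
  expect_error(relative_increase(1000, 0), "positive")
})

test_that("stepping coefficients rescale exactly with the step unit", {
  sim <- small_cohort_sim(n = 120, seed = 6)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  f_k <- fit_association(dat, model = 1)
  dat_steps <- dat
  dat_steps$total_k <- dat_steps$total_k * 1000  # raw steps instead of thousands
  f_raw <- fit_association(dat_steps, model = 1)
  st_k <- f_k$stepping$estimate
  st_raw <- f_raw$stepping$estimate
  expect_equal(st_k, st_raw * 1000, tolerance = 1e-4)
})

test_that("estimates are invariant to row and covariate-column order", {
  sim <- small_cohort_sim(n = 100, seed = 16)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  f1 <- fit_association(dat, model = 3)
  set.seed(1)
  shuffled <- dat[sample(nrow(dat)), rev(names(dat))]
  f2 <- fit_association(shuffled, model = 3)
  expect_equal(f1$stepping$estimate, f2$stepping$estimate, tolerance = 1e-8)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("a single fit recovers the generating effects within sampling error", {
  sim <- small_cohort_sim(n = 500, seed = 26)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  f <- fit_association(dat, model = 3)
  st <- f$stepping
  fast24 <- st[st$band == "faster_walking" & st$time == 24, ]
  true_gain <- sim$truth$theta_fast_by_period[4] - sim$truth$theta_fast_by_period[1]
  expect_lt(abs(fast24$estimate - true_gain), 4 * fast24$se)
  expect_true(all(c("var_random_intercept", "var_residual") %in% names(unclass(f))))
  expect_gt(f$var_random_intercept, 0)
})

test_that("model comparison favours the generating two-band structure", {
  wins <- vapply(1:5, function(s) {
    sim <- small_cohort_sim(n = 400, seed = 36 + s)
    dat <- prepare_association_data(sim$cohort, sim$stepping)
    aics <- vapply(1:3, function(m) fit_association(dat, model = m)$aic, numeric(1))
    which.min(aics) == 3L
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("tidy, glance, and autoplot expose the model surfaces", {
  sim <- small_cohort_sim(n = 80, seed = 46)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  f <- fit_association(dat, model = 2)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "ci_lo", "ci_hi", "p") %in% names(td)))
  expect_true("faster_k" %in% td$term)
  gl <- glance(f)
  expect_equal(gl$model_id, 2L)
  expect_true(is.finite(gl$aic) && is.finite(gl$loglik))
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("the inclusion rule drops participants with fewer than two periods", {
  sim <- small_cohort_sim(n = 60, seed = 56)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  counts <- table(dat$participant_id)
  expect_true(all(counts >= 2))
  expect_error(fit_association(dat[dat$participant_id == dat$participant_id[1], ],
                               model = 1), "too few participants")
})

test_that("sensitivity refits agree when covariates carry no effect", {
  eff0 <- list(age = 0, sex = c(0, 0), imd_quintile = rep(0, 5),
               education = rep(0, 3), comorbidity = c(0, 0),
               sf36_class = rep(0, 3), site = rep(0, 3),
               allocation_by_period = rep(0, 4))
  sim <- small_cohort_sim(n = 300, seed = 66, covariate_effects = eff0)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  suite <- sensitivity_suite(dat, model = 3)
  expect_true(all(c("primary", "no_health_ses_covariates",
                    "stratum_control", "stratum_intervention") %in% suite$analysis))
  prim <- suite[suite$analysis == "primary" & suite$band == "faster_walking" &
                  suite$time == 24, ]
  red <- suite[suite$analysis == "no_health_ses_covariates" &
                 suite$band == "faster_walking" & suite$time == 24, ]
  expect_lt(abs(prim$estimate - red$estimate), 2 * prim$se)
  # strata generated with identical effects agree within simulation error
  ctl <- suite[suite$analysis == "stratum_control" & suite$band == "faster_walking" &
                 suite$time == 24, ]
  int <- suite[suite$analysis == "stratum_intervention" &
                 suite$band == "faster_walking" & suite$time == 24, ]
  expect_lt(abs(ctl$estimate - int$estimate), 3 * sqrt(ctl$se^2 + int$se^2))
})

test_that("a stratum too small to fit is skipped with a reason", {
  sim <- small_cohort_sim(n = 110, seed = 76)
  dat <- prepare_association_data(sim$cohort, sim$stepping)
  # shrink the intervention stratum to a single participant who contributes
  # every period (so the pooled allocation x time cells stay populated)
  int_counts <- table(dat$participant_id[dat$allocation == "intervention"])
  keep_int <- names(int_counts)[int_counts == 4][1]
  dat_small <- dat[dat$allocation == "control" |
                     dat$participant_id == keep_int, ]
  suite <- sensitivity_suite(dat_small, model = 1)
  skipped <- suite[suite$analysis == "stratum_intervention", ]
  expect_true(all(skipped$skipped))
  expect_match(skipped$reason[1], "stratum too small")
})
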