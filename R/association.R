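# Longitudinal association between stepping volume/rate and physical
# function (SPPB), via linear mixed models with participant random
# intercepts, categorical time, covariates, and stepping x time
# interactions.
#
# Three model choices mirror the candidate stepping representations:
#   model 1: total steps only
#   model 2: faster-paced walking steps only
#   model 3: faster-paced walking steps + slower-paced steps
#     (two non-overlapping cadence bands; avoids the collinearity of
#     entering total steps together with one of its subsets)
# Stepping enters per 1000 steps. Follow-up coefficients are interaction
# contrasts relative to baseline: the total effect at time t is the
# baseline coefficient plus the interaction coefficient at t.

.stepping_terms <- list(
  `1` = c(total = "total_k"),
  `2` = c(faster_walking = "faster_k"),
  `3` = c(faster_walking = "faster_k", slower_paced = "slower_paced_k")
)

.full_covariates <- c("age_at_recruitment", "sex", "site", "sf36_class",
                      "comorbidity", "imd_quintile_f", "education")
.core_covariates <- c("age_at_recruitment", "sex", "site")

#' Join cohort and stepping tables for association modelling
#'
#' Inner-joins participant-period SPPB/covariate records to period-level
#' mean daily stepping, rescales stepping to thousands of steps, restricts
#' to complete cases, and keeps participants contributing at least
#' `min_periods` valid periods (the longitudinal inclusion rule).
#'
#' @param cohort Cohort tibble (see [read_cohort()] / [simulate_cohort()]).
#' @param stepping Per participant-period mean daily steps with columns
#'   `total`, `faster_walking`, `slower_paced` (e.g. from
#'   [aggregate_period()] or the simulator).
#' @param min_periods Minimum valid periods per participant (default 2).
#' @return Analysis tibble with `time` (factor months, baseline reference),
#'   `total_k`, `faster_k`, `slower_paced_k` (thousands of steps/day) and
#'   `imd_quintile_f` (factor).
#' @export
prepare_association_data <- function(cohort, stepping, min_periods = 2) {
  need <- c("total", "faster_walking", "slower_paced")
  missing_cols <- setdiff(need, names(stepping))
  if (length(missing_cols) > 0) {
    abort(sprintf("stepping table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  data <- inner_join(cohort, stepping[c("participant_id", "period", need)],
                     by = c("participant_id", "period")) %>%
    mutate(time = factor(.data$period, levels = sort(unique(.data$period))),
           total_k = .data$total / 1000,
           faster_k = .data$faster_walking / 1000,
           slower_paced_k = .data$slower_paced / 1000,
           imd_quintile_f = factor(.data$imd_quintile, levels = 1:5))
  model_cols <- c("sppb", "time", "allocation", .full_covariates,
                  "total_k", "faster_k", "slower_paced_k")
  data <- data[stats::complete.cases(data[intersect(model_cols, names(data))]), , drop = FALSE]
  data %>%
    group_by(.data$participant_id) %>%
    filter(dplyr::n() >= min_periods) %>%
    ungroup() %>%
    droplevels()
}

#' @noRd
association_formula <- function(model, covariates, with_allocation = TRUE) {
  stepping <- .stepping_terms[[as.character(model)]]
  rhs <- c(paste(stepping, "* time"),
           if (with_allocation) "allocation * time" else "time",
           covariates, "(1 | participant_id)")
  as.formula(paste("sppb ~", paste(rhs, collapse = " + ")))
}

#' @noRd
fit_lmm_checked <- function(form, data, reml) {
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = data, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")),
      error = function(e) {
        abort(c("association model failed to fit", conditionMessage(e)),
              class = "pfstep_convergence_error")
      }),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  dropped <- attr(lme4::getME(fit, "X"), "col.dropped")
  if (!is.null(dropped) && length(dropped) > 0) {
    abort(sprintf("rank-deficient fixed effects; empty cells for term(s): %s",
                  paste(names(dropped), collapse = ", ")),
          class = "pfstep_rank_error")
  }
  fit
}

#' Fit a longitudinal stepping / physical-function model
#'
#' Fits SPPB on stepping (per 1000 steps), categorical time with baseline
#' reference, stepping x time and allocation x time interactions, the
#' configured covariates, and a participant random intercept. Coefficients
#' and confidence intervals come from the restricted-likelihood fit with
#' large-sample normal inference; AIC and log-likelihood come from a
#' full-likelihood refit so that models differing in fixed effects are
#' comparable.
#'
#' @param data Analysis tibble from [prepare_association_data()].
#' @param model 1 (total steps), 2 (faster-paced walking steps) or 3
#'   (faster-paced walking + slower-paced steps).
#' @param covariates Character vector of covariate terms; default the full
#'   adjustment set (age, sex, site, SF-36 class, comorbidity, IMD quintile,
#'   education). Allocation x time is always included unless
#'   `with_allocation = FALSE` (used for stratified fits).
#' @param with_allocation Include allocation and its time interaction.
#' @param level Confidence level (default 0.95).
#' @return An object of class `pfstep_association` with elements
#'   `coefficients` (tibble: term, estimate, se, ci_lo, ci_hi, p),
#'   `stepping` (the stepping baseline/interaction coefficients laid out by
#'   band and time), `var_random_intercept`, `var_residual`, `aic`,
#'   `loglik`, sample sizes. Methods: `tidy()`, `glance()`, `autoplot()`,
#'   [total_effect()].
#' @export
fit_association <- function(data, model = 3, covariates = .full_covariates,
                            with_allocation = TRUE, level = 0.95) {
  model <- as.integer(model)
  if (!model %in% 1:3) abort("'model' must be 1, 2 or 3")
  if (dplyr::n_distinct(data$participant_id) < 3) {
    abort("too few participants to fit a mixed model (need >= 3)")
  }
  data <- droplevels(data)
  covariates <- intersect(covariates, names(data))
  form <- association_formula(model, covariates, with_allocation)
  fit <- fit_lmm_checked(form, data, reml = TRUE)
  fit_ml <- fit_lmm_checked(form, data, reml = FALSE)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- tibble(term = names(est), estimate = unname(est), se = unname(se),
                  ci_lo = unname(est - z * se), ci_hi = unname(est + z * se),
                  p = 2 * stats::pnorm(-abs(unname(est) / unname(se))))

  stepping_vars <- .stepping_terms[[as.character(model)]]
  times <- levels(data$time)
  stepping <- purrr::map_dfr(names(stepping_vars), function(band) {
    v <- stepping_vars[[band]]
    purrr::map_dfr(times, function(tt) {
      nm <- if (tt == times[1]) v else
        c(paste0(v, ":time", tt), paste0("time", tt, ":", v))
      row <- coefs[coefs$term %in% nm, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      tibble(band = band, time = as.integer(tt),
             role = if (tt == times[1]) "baseline" else "interaction",
             estimate = row$estimate, se = row$se,
             ci_lo = row$ci_lo, ci_hi = row$ci_hi, p = row$p)
    })
  })

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    model_id = model,
    formula = form,
    coefficients = coefs,
    stepping = stepping,
    var_random_intercept = vc$vcov[vc$grp == "participant_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    aic = AIC(fit_ml),
    loglik = as.numeric(logLik(fit_ml)),
    level = level,
    n_participants = dplyr::n_distinct(data$participant_id),
    n_participant_periods = nrow(data),
    times = as.integer(times)
  ), class = "pfstep_association")
}

#' @exportS3Method base::print
print.pfstep_association <- function(x, ...) {
  cat(sprintf("Longitudinal SPPB model %d (%s)\n", x$model_id,
              paste(names(.stepping_terms[[as.character(x$model_id)]]), collapse = " + ")))
  cat(sprintf("  %d participants, %d participant-periods\n",
              x$n_participants, x$n_participant_periods))
  cat(sprintf("  AIC %.0f, log-likelihood %.0f (full likelihood)\n", x$aic, x$loglik))
  cat("  stepping coefficients (SPPB points per 1000 steps):\n")
  st <- x$stepping
  for (i in seq_len(nrow(st))) {
    cat(sprintf("    %-15s %2d months (%s): %6.2f (%.2f-%.2f)\n",
                st$band[i], st$time[i], st$role[i], st$estimate[i],
                st$ci_lo[i], st$ci_hi[i]))
  }
  invisible(x)
}

#' Total strength of a stepping association at a follow-up
#'
#' Follow-up stepping coefficients are interaction contrasts relative to
#' baseline; the total effect at time t is the baseline coefficient plus
#' the interaction coefficient at t (e.g. 0.04 + 0.21 = 0.25 SPPB points
#' per 1000 total steps at 24 months in a total-steps-only model).
#'
#' @param result A `pfstep_association` fit, or a tibble shaped like its
#'   `stepping` element (columns `band`, `time`, `role`, `estimate`).
#' @param band Stepping band: `"total"`, `"faster_walking"` or
#'   `"slower_paced"`.
#' @param time Follow-up time in months; at baseline the baseline
#'   coefficient is returned unchanged.
#' @return Total association strength in SPPB points per 1000 steps.
#' @export
total_effect <- function(result, band, time) {
  st <- if (inherits(result, "pfstep_association")) result$stepping else as_tibble(result)
  st <- st[st$band == band, , drop = FALSE]
  if (nrow(st) == 0) abort(sprintf("no stepping term for band '%s'", band))
  base <- st$estimate[st$role == "baseline"]
  if (length(base) != 1) abort("no baseline coefficient found")
  t0 <- min(st$time)
  if (time == t0) return(base)
  inter <- st$estimate[st$role == "interaction" & st$time == time]
  if (length(inter) != 1) abort(sprintf("no interaction coefficient at %s months for band '%s'", time, band))
  base + inter
}

#' @rdname fit_association
#' @param x,object A `pfstep_association` object.
#' @param ... Unused.
#' @export
tidy.pfstep_association <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_association
#' @export
glance.pfstep_association <- function(x, ...) {
  tibble(model_id = x$model_id, aic = x$aic, loglik = x$loglik,
         var_random_intercept = x$var_random_intercept,
         var_residual = x$var_residual,
         n_participants = x$n_participants,
         n_participant_periods = x$n_participant_periods)
}

#' @rdname fit_association
#' @export
autoplot.pfstep_association <- function(object, ...) {
  st <- object$stepping
  st$time_f <- factor(st$time)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$time_f, y = .data$estimate,
                                   colour = .data$band, group = .data$band)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "months (interactions relative to baseline)",
                  y = "SPPB points per 1000 steps",
                  title = sprintf("Model %d stepping coefficients", object$model_id),
                  colour = "band") +
    ggplot2::theme_minimal()
}

#' Sensitivity analyses around a primary association fit
#'
#' Refits the requested model (i) without the health and socio-economic
#' covariates (SF-36 class, comorbidity, IMD quintile, education), keeping
#' age, sex, site and allocation x time, and (ii) separately within each
#' allocation stratum (allocation terms dropped). Strata too small to
#' support a mixed model are recorded as skipped with the reason.
#'
#' @param data Analysis tibble from [prepare_association_data()].
#' @param model Model id (1, 2 or 3), as in [fit_association()].
#' @return A tibble of stepping coefficients with an `analysis` label
#'   (`primary`, `no_health_ses_covariates`, `stratum_control`,
#'   `stratum_intervention`); skipped strata appear with `skipped = TRUE`
#'   and a `reason`.
#' @export
sensitivity_suite <- function(data, model = 3) {
  out <- list()
  primary <- fit_association(data, model = model)
  out$primary <- mutate(primary$stepping, analysis = "primary",
                        skipped = FALSE, reason = NA_character_)
  reduced <- fit_association(data, model = model, covariates = .core_covariates)
  out$reduced <- mutate(reduced$stepping, analysis = "no_health_ses_covariates",
                        skipped = FALSE, reason = NA_character_)
  for (arm in levels(droplevels(data$allocation))) {
    stratum <- filter(data, .data$allocation == arm)
    label <- paste0("stratum_", arm)
    if (dplyr::n_distinct(stratum$participant_id) < 3) {
      out[[label]] <- tibble(band = NA_character_, time = NA_integer_,
                             role = NA_character_, estimate = NA_real_,
                             se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                             p = NA_real_, analysis = label, skipped = TRUE,
                             reason = "stratum too small to fit (fewer than 3 participants)")
      next
    }
    sfit <- tryCatch(
      fit_association(stratum, model = model, with_allocation = FALSE),
      error = function(e) e)
    if (inherits(sfit, "error")) {
      out[[label]] <- tibble(band = NA_character_, time = NA_integer_,
                             role = NA_character_, estimate = NA_real_,
                             se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                             p = NA_real_, analysis = label, skipped = TRUE,
                             reason = conditionMessage(sfit))
      next
    }
    out[[label]] <- mutate(sfit$stepping, analysis = label,
                           skipped = FALSE, reason = NA_character_)
  }
  bind_rows(out)
}
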