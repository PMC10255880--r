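# Method agreement between two wearable systems via the variance-components
# concordance correlation coefficient (CCC) for repeated daily measurements.
#
# Model: y_ijk = mu + beta_j + alpha_i + (alpha gamma)_ik + (alpha beta)_ij
#        + eps_ijk   (i participant, j device, k day)
# with random participant, participant x day (shared across devices) and
# participant x device effects and a fixed device contrast. The CCC is
#   (s2_subject + s2_subject_day) /
#   (s2_subject + s2_subject_day + s2_subject_device + s2_device + s2_error)
# where, for two devices, s2_device = (beta_wrist - beta_thigh)^2 / 2
# captures the systematic bias. With no bias and no device interaction this
# reduces to the intraclass correlation; with one day per participant and
# only the subject random effect it is the variance-components analogue of
# the classical moment-based CCC.

.agreement_terms <- c("subject", "subject_day", "subject_device")

#' @noRd
prepare_paired <- function(paired_daily, response) {
  if (!response %in% names(paired_daily)) {
    abort(sprintf("response band '%s' not found in the daily aggregates", response))
  }
  devices <- unique(as.character(paired_daily$device))
  if (length(devices) > 2) abort("more than two devices present; agreement is defined for device pairs")
  if (length(devices) < 2) abort("fewer than two devices present; agreement needs paired measurements")
  day_col <- intersect(c("date", "day"), names(paired_daily))[1]
  if (is.na(day_col)) abort("daily aggregates need a 'date' or 'day' column")
  long <- tibble(
    participant_id = as.character(paired_daily$participant_id),
    device = as_device(paired_daily$device),
    day_key = as.character(paired_daily[[day_col]]),
    y = as.numeric(paired_daily[[response]])
  )
  # keep only participant-days measured by both devices
  complete <- long %>%
    count(.data$participant_id, .data$day_key) %>%
    filter(.data$n == 2) %>%
    select(-"n")
  long <- semi_join(long, complete, by = c("participant_id", "day_key"))
  if (nrow(long) == 0) abort("no participant-days with both device values")
  long
}

#' @noRd
fit_agreement_lmm <- function(long, random_terms, reml = TRUE, start = NULL) {
  rt <- c(subject = "(1 | participant_id)",
          subject_day = "(1 | participant_id:day_key)",
          subject_device = "(1 | participant_id:device)")[random_terms]
  form <- as.formula(paste("y ~ device +", paste(rt, collapse = " + ")))
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = long, REML = reml, start = start,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")),
      error = function(e) {
        abort(c("agreement model failed to converge", conditionMessage(e)),
              class = "pfstep_convergence_error")
      }),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  fit
}

# Lean REML refit for bootstrap replicates: identical estimator to
# fit_agreement_lmm (lme4 deviance function + same optimizer) but skips the
# merMod packaging; returns the CCC directly.
#' @noRd
refit_ccc <- function(long, random_terms, reml = TRUE, start = NULL) {
  rt <- c(subject = "(1 | participant_id)",
          subject_day = "(1 | participant_id:day_key)",
          subject_device = "(1 | participant_id:device)")[random_terms]
  form <- as.formula(paste("y ~ device +", paste(rt, collapse = " + ")))
  ctl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore",
                           check.conv.grad = "ignore", check.conv.hess = "ignore")
  lf <- suppressWarnings(suppressMessages(
    lme4::lFormula(form, data = long, REML = reml, control = ctl)))
  dv <- do.call(lme4::mkLmerDevfun, lf)
  if (!is.null(start) && length(start) != length(lf$reTrms$theta)) start <- NULL
  opt <- suppressWarnings(suppressMessages(
    lme4::optimizeLmer(dv, start = start, control = ctl$optCtrl)))
  rho <- environment(dv)
  p <- ncol(lf$X)
  nobs <- nrow(lf$X)
  denom_df <- if (reml) nobs - p else nobs
  sigma2 <- (rho$resp$wrss() + rho$pp$sqrL(1)) / denom_df
  theta <- opt$par
  grp_names <- names(lf$reTrms$cnms)
  vcomp <- setNames(pmax(0, sigma2 * theta^2), grp_names)
  get_var <- function(grp) if (grp %in% grp_names) vcomp[[grp]] else 0
  comp <- c(
    var_subject = get_var("participant_id"),
    var_subject_day = get_var("participant_id:day_key"),
    var_subject_device = get_var("participant_id:device"),
    var_error = sigma2
  )
  beta <- rho$pp$beta(1)
  bias <- beta[match("devicewrist", colnames(lf$X))]
  if (is.na(bias)) bias <- 0
  s2_device <- bias^2 / 2
  denom <- sum(comp) + s2_device
  if (denom <= 0) 1 else (comp[["var_subject"]] + comp[["var_subject_day"]]) / denom
}

#' @noRd
extract_agreement <- function(fit, random_terms) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_var <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else max(0, v)
  }
  comp <- c(
    var_subject = if ("subject" %in% random_terms) get_var("participant_id") else 0,
    var_subject_day = if ("subject_day" %in% random_terms) get_var("participant_id:day_key") else 0,
    var_subject_device = if ("subject_device" %in% random_terms) get_var("participant_id:device") else 0,
    var_error = get_var("Residual")
  )
  bias <- unname(lme4::fixef(fit)["devicewrist"])
  if (is.na(bias)) bias <- 0
  s2_device <- bias^2 / 2
  denom <- sum(comp) + s2_device
  ccc <- if (denom <= 0) 1 else (comp[["var_subject"]] + comp[["var_subject_day"]]) / denom
  list(components = comp, device_bias = bias, s2_device = s2_device, ccc = unname(ccc))
}

#' Fit the variance-components agreement model
#'
#' Estimates the concordance correlation coefficient (CCC) between two
#' wearable systems from paired daily aggregates, using the variance
#' components of a linear mixed model with random participant,
#' participant x day and participant x device effects and a fixed device
#' contrast. Variance components are estimated by restricted likelihood by
#' default and negative estimates are truncated at zero; components
#' estimated at the zero boundary are retained (reported as 0), not dropped.
#'
#' @param paired_daily Daily aggregates for both devices, e.g. from
#'   [aggregate_daily()] or [simulate_paired_daily()]; must contain
#'   `participant_id`, `device`, a `date` (or `day`) column and the response
#'   band column. Only participant-days with both device values are used.
#' @param response Band to analyse: `"total"`, `"walking"`,
#'   `"slower_walking"` or `"faster_walking"` (any numeric column works).
#' @param random_terms Random effects to include; default all three. Drop
#'   `"subject_day"` for single-replicate designs where it is confounded
#'   with the residual.
#' @param reml Use restricted likelihood (default) or full likelihood.
#' @return An object of class `pfstep_agreement`: variance components,
#'   fixed device bias (wrist - thigh, steps/day), `s2_device` = bias^2/2,
#'   `ccc`, daily Pearson correlation, variance shares, sample sizes, and
#'   the analysed data (for bootstrapping and plotting). Methods: `tidy()`,
#'   `glance()`, `autoplot()`, [ccc_ci()], [variance_share_report()].
#' @examples
#' sim <- simulate_paired_daily(paired_sim_config(n_participants = 12, seed = 7))
#' fit <- fit_agreement(sim$daily, response = "total")
#' glance(fit)
#' @export
fit_agreement <- function(paired_daily, response = "total",
                          random_terms = .agreement_terms, reml = TRUE) {
  random_terms <- match.arg(random_terms, .agreement_terms, several.ok = TRUE)
  if (!"subject" %in% random_terms) abort("'random_terms' must include \"subject\"")
  long <- prepare_paired(paired_daily, response)
  if (dplyr::n_distinct(long$participant_id) < 2) {
    abort("agreement needs at least 2 participants with paired days")
  }
  fit <- fit_agreement_lmm(long, random_terms, reml = reml)
  est <- extract_agreement(fit, random_terms)
  theta <- unname(lme4::getME(fit, "theta"))

  wide <- tidyr::pivot_wider(long, names_from = "device", values_from = "y")
  pearson <- suppressWarnings(cor(wide$thigh, wide$wrist))

  # fixed order: subject, subject x day, subject x device, device bias, error
  shares_all <- c(subject = est$components[["var_subject"]],
                  subject_day = est$components[["var_subject_day"]],
                  subject_device = est$components[["var_subject_device"]],
                  device_bias = est$s2_device,
                  error = est$components[["var_error"]])
  shares <- if (sum(shares_all) > 0) shares_all / sum(shares_all) else
    setNames(c(1, 0, 0, 0, 0), names(shares_all))

  structure(list(
    response = response,
    random_terms = random_terms,
    var_subject = est$components[["var_subject"]],
    var_subject_day = est$components[["var_subject_day"]],
    var_subject_device = est$components[["var_subject_device"]],
    var_error = est$components[["var_error"]],
    device_bias = est$device_bias,
    s2_device = est$s2_device,
    ccc = est$ccc,
    ccc_ci = NULL,
    pearson_daily = pearson,
    variance_shares = shares,
    n_participants = dplyr::n_distinct(long$participant_id),
    n_paired_days = nrow(wide),
    reml = reml,
    theta = theta,
    data = long
  ), class = "pfstep_agreement")
}

#' @exportS3Method base::print
print.pfstep_agreement <- function(x, ...) {
  cat(sprintf("Variance-components agreement: %s steps/day\n", x$response))
  cat(sprintf("  %d participants, %d paired days\n", x$n_participants, x$n_paired_days))
  cat(sprintf("  CCC = %.3f", x$ccc))
  if (!is.null(x$ccc_ci)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$ccc_ci[1], x$ccc_ci[2]))
  cat(sprintf("; Pearson (daily) = %.3f\n", x$pearson_daily))
  cat(sprintf("  device bias (wrist - thigh) = %.1f steps/day\n", x$device_bias))
  sh <- round(100 * x$variance_shares)
  cat(sprintf("  variance shares: subject %d%%, subject x day %d%%, subject x device %d%%, device bias %d%%, error %d%%\n",
              sh[1], sh[2], sh[3], sh[4], sh[5]))
  invisible(x)
}

#' Cluster-bootstrap confidence interval for the CCC
#'
#' Percentile interval from resampling participants (clusters) with
#' replacement and refitting the agreement model on each replicate.
#' Deterministic for a fixed seed. If more than 20% of replicates fail to
#' converge a warning is recorded on the result.
#'
#' @param fit A [fit_agreement()] result.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return The `pfstep_agreement` object with `ccc_ci` set to `c(lo, hi)`
#'   (attributes: `replicates`, the replicate CCCs; `n_fail`, failed
#'   replicate count).
#' @export
ccc_ci <- function(fit, n_boot = 500, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "pfstep_agreement"))
  set.seed(seed)
  long <- fit$data
  split_by_id <- split(seq_len(nrow(long)), long$participant_id)
  ids <- names(split_by_id)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(split_by_id[take], use.names = FALSE)
    boot <- long[idx, , drop = FALSE]
    # duplicated participants must act as distinct clusters
    boot$participant_id <- rep(seq_along(take), lengths(split_by_id[take]))
    reps[b] <- tryCatch(
      refit_ccc(boot, fit$random_terms, reml = fit$reml, start = fit$theta),
      error = function(e) tryCatch({
        # fall back to the full fitting path (more robust near boundaries)
        bfit <- fit_agreement_lmm(boot, fit$random_terms, reml = fit$reml)
        extract_agreement(bfit, fit$random_terms)$ccc
      }, error = function(e2) NA_real_))
  }
  n_fail <- sum(is.na(reps))
  if (n_fail > 0.2 * n_boot) {
    warn(sprintf("%d of %d bootstrap replicates failed to converge; interval may be unreliable",
                 n_fail, n_boot))
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, type = 6))
  attr(ci, "replicates") <- reps
  attr(ci, "n_fail") <- n_fail
  fit$ccc_ci <- ci
  fit
}

#' Paired daily scatter statistics
#'
#' Per-band Pearson correlation of the paired daily values together with a
#' summary of deviation from the identity line (mean and SD of the
#' wrist - thigh daily differences and the root-mean-square deviation from
#' identity), as displayed in paired-device scatter plots where each point
#' is one day.
#'
#' @param paired_daily Daily aggregates for both devices.
#' @param responses Band columns to summarise.
#' @return A tibble with one row per band: `pearson`, `mean_diff`,
#'   `sd_diff`, `rmsd_identity`, `n_days`.
#' @export
daily_scatter_stats <- function(paired_daily,
                                responses = c("total", "walking",
                                              "slower_walking", "faster_walking")) {
  responses <- intersect(responses, names(paired_daily))
  if (length(responses) == 0) abort("none of the requested band columns are present")
  purrr::map_dfr(responses, function(resp) {
    long <- prepare_paired(paired_daily, resp)
    wide <- tidyr::pivot_wider(long, names_from = "device", values_from = "y")
    if (nrow(wide) < 3) abort(sprintf("fewer than 3 paired days for band '%s'", resp))
    d <- wide$wrist - wide$thigh
    tibble(band = resp,
           pearson = cor(wide$thigh, wide$wrist),
           mean_diff = mean(d), sd_diff = sd(d),
           rmsd_identity = sqrt(mean(d^2)),
           n_days = nrow(wide))
  })
}

#' Variance-share decomposition of an agreement fit
#'
#' Expresses each source of disagreement (participants, day-to-day
#' behaviour, participant x device interaction, systematic device bias,
#' residual error) as its share of the summed variance components, ordered
#' by share.
#'
#' @param fit A [fit_agreement()] result.
#' @return A tibble: `component`, `variance`, `share` (sums to 1).
#' @export
variance_share_report <- function(fit) {
  stopifnot(inherits(fit, "pfstep_agreement"))
  tibble(
    component = c("subject", "subject_day", "subject_device", "device_bias", "error"),
    variance = c(fit$var_subject, fit$var_subject_day, fit$var_subject_device,
                 fit$s2_device, fit$var_error),
    share = unname(fit$variance_shares)
  ) %>%
    arrange(dplyr::desc(.data$share))
}

#' @rdname fit_agreement
#' @param x A `pfstep_agreement` object.
#' @param ... Unused.
#' @export
tidy.pfstep_agreement <- function(x, ...) {
  tibble(
    term = c("var_subject", "var_subject_day", "var_subject_device",
             "s2_device", "var_error", "device_bias", "ccc", "pearson_daily"),
    estimate = c(x$var_subject, x$var_subject_day, x$var_subject_device,
                 x$s2_device, x$var_error, x$device_bias, x$ccc, x$pearson_daily)
  )
}

#' @rdname fit_agreement
#' @export
glance.pfstep_agreement <- function(x, ...) {
  tibble(response = x$response, ccc = x$ccc,
         ccc_lo = if (is.null(x$ccc_ci)) NA_real_ else x$ccc_ci[1],
         ccc_hi = if (is.null(x$ccc_ci)) NA_real_ else x$ccc_ci[2],
         pearson_daily = x$pearson_daily, device_bias = x$device_bias,
         n_participants = x$n_participants, n_paired_days = x$n_paired_days)
}

#' @rdname fit_agreement
#' @param object A `pfstep_agreement` object.
#' @export
autoplot.pfstep_agreement <- function(object, ...) {
  wide <- tidyr::pivot_wider(object$data, names_from = "device", values_from = "y")
  lab <- sprintf("CCC = %.2f, PCC = %.2f", object$ccc, object$pearson_daily)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$thigh, y = .data$wrist)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey55") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "thigh-worn system (steps/day)", y = "wrist-worn system (steps/day)",
                  title = sprintf("%s steps: paired daily estimates", object$response),
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Variance-share bar chart
#'
#' @param fit A [fit_agreement()] result.
#' @return A ggplot object.
#' @export
plot_variance_shares <- function(fit) {
  rep <- variance_share_report(fit)
  rep$component <- factor(rep$component, levels = rev(rep$component))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$share, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(round(100 * v), "%")) +
    ggplot2::labs(x = "share of total variance", y = NULL,
                  title = sprintf("Sources of disagreement: %s steps", fit$response)) +
    ggplot2::theme_minimal()
}
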