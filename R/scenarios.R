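# Scenario projections and descriptive arithmetic on period-level stepping
# summaries.

#' Published mean daily step counts of the longitudinal cohort
#'
#' The published period-level means (and SDs) of wrist-derived daily step
#' counts by cadence band in the longitudinal older-adult cohort (combined
#' control and intervention groups), used as the default targets of the
#' cohort simulator and as inputs to descriptive change computations.
#' Bands: total (20-175 steps/min), non-walking (20-44), slower-paced
#' (20-62), slower-paced walking (45-62), faster-paced walking (63-175).
#'
#' @return Tibble with one row per recording period (months 0, 6, 12, 24):
#'   `n` participants, per-band means, and matching `*_sd` columns.
#' @export
react_stepping_means <- function() {
  tibble(
    period = c(0L, 6L, 12L, 24L),
    n = c(608L, 565L, 544L, 504L),
    total = c(5815, 5569, 5250, 4871),
    non_walking = c(4342, 4147, 3965, 3776),
    slower_paced = c(4923, 4702, 4470, 4215),
    slower_walking = c(581, 555, 505, 439),
    faster_walking = c(892, 867, 780, 656),
    total_sd = c(3186, 3256, 3017, 3039),
    non_walking_sd = c(2371, 2386, 2259, 2353),
    slower_paced_sd = c(2640, 2676, 2490, 2570),
    slower_walking_sd = c(530, 544, 484, 459),
    faster_walking_sd = c(938, 996, 915, 857)
  )
}

#' Stepping-change scenario
#'
#' Bundles a hypothetical change in daily stepping (in thousands of steps,
#' negative for declines) with the model coefficients translating stepping
#' into SPPB points per 1000 steps.
#'
#' @param delta_slower,delta_faster Change in slower-paced and faster-paced
#'   walking steps, in thousands of steps/day.
#' @param theta_slower,theta_faster SPPB points per 1000 steps for the two
#'   bands (defaults are the fully adjusted two-band model's 24-month total
#'   effects, 0.13 and 0.53).
#' @return An object of class `pfstep_scenario`.
#' @export
scenario <- function(delta_slower, delta_faster,
                     theta_slower = 0.13, theta_faster = 0.53) {
  for (f in c("delta_slower", "delta_faster", "theta_slower", "theta_faster")) {
    check_scalar_number(get(f), f)
  }
  structure(list(delta_slower = delta_slower, delta_faster = delta_faster,
                 theta_slower = theta_slower, theta_faster = theta_faster),
            class = "pfstep_scenario")
}

#' Project the expected SPPB change of a stepping scenario
#'
#' The expected change in SPPB score implied by a change in daily stepping:
#' `delta_slower * theta_slower + delta_faster * theta_faster`, with deltas
#' in thousands of steps/day and thetas in SPPB points per 1000 steps.
#' Reported to 2 decimal places.
#'
#' @param scn A [scenario()] object.
#' @return Expected SPPB change (positive = improvement), rounded to 2
#'   decimals.
#' @examples
#' # maintaining baseline stepping instead of declining by 708 slower-paced
#' # and 236 faster-paced walking steps/day avoids a 0.22 SPPB decrease:
#' project_scenario(scenario(-0.708, -0.236))
#' @export
project_scenario <- function(scn) {
  stopifnot(inherits(scn, "pfstep_scenario"))
  round(scn$delta_slower * scn$theta_slower + scn$delta_faster * scn$theta_faster, 2)
}

#' Relative size of a step increase against a baseline mean
#'
#' Expresses an absolute increase in daily steps as a percent of a baseline
#' mean (rounded to the nearest integer percent), e.g. to judge how large
#' "1000 extra steps/day" is relative to a band's habitual level.
#'
#' @param increase Step increase (steps/day).
#' @param baseline_mean Baseline mean steps/day; must be positive.
#' @return Integer percent.
#' @examples
#' relative_increase(1000, 892)  # 112% of baseline faster-paced walking
#' @export
relative_increase <- function(increase, baseline_mean) {
  check_scalar_number(increase, "increase")
  if (!is.numeric(baseline_mean) || length(baseline_mean) != 1 ||
      !is.finite(baseline_mean) || baseline_mean <= 0) {
    abort("'baseline_mean' must be a positive number")
  }
  as.integer(round(increase / baseline_mean * 100))
}
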