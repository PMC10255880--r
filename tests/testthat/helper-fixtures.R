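# Small in-code fixture builders shared across test files.

make_events <- function(participant_id, device, start, duration_s, steps) {
  tibble::tibble(
    participant_id = participant_id,
    device = factor(device, levels = c("thigh", "wrist")),
    start = as.POSIXct(start, tz = "UTC"),
    duration_s = duration_s,
    steps = as.integer(steps),
    cadence = steps / (duration_s / 60)
  )
}

# event with a target cadence (steps/min): duration derived
event_at <- function(cadence, steps = 100, participant_id = "p1",
                     device = "wrist", start = "2024-05-06 10:00:00") {
  make_events(participant_id, device, start, steps / cadence * 60, steps)
}

make_wear <- function(participant_id, device, date, wear_hours, period = NULL) {
  out <- tibble::tibble(
    participant_id = participant_id,
    device = factor(device, levels = c("thigh", "wrist")),
    date = as.Date(date),
    wear_hours = wear_hours
  )
  if (!is.null(period)) out$period <- as.integer(period)
  out
}

make_cohort_row <- function(participant_id = "c1", period = 0L, sppb = 8L,
                            age = 77, sex = "female", imd = 3L,
                            education = "secondary", comorbidity = "none",
                            sf36 = "good", allocation = "control",
                            site = "exeter") {
  tibble::tibble(
    participant_id = participant_id, period = as.integer(period),
    sppb = as.integer(sppb), age_at_recruitment = age,
    sex = factor(sex, c("male", "female")),
    imd_quintile = as.integer(imd),
    education = factor(education, c("secondary", "some college", "college/degree")),
    comorbidity = factor(comorbidity, c("none", "one or more")),
    sf36_class = factor(sf36, c("very good/excellent", "good", "fair/poor")),
    allocation = factor(allocation, c("control", "intervention")),
    site = factor(site, c("bristol/bath", "birmingham", "exeter"))
  )
}

# fast small cohort simulation for association tests
small_cohort_sim <- function(n = 200, seed = 1, ...) {
  simulate_cohort(cohort_sim_config(n_participants = n, seed = seed, ...))
}
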