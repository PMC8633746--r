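# Latent metabolic-rate model of one fish during a respirometry trial.
#
# rate(t) = true_smr
#           * day_activity_multiplier   (while lights on)
#           * shelter_multiplier        (while the chamber is covered)
#           * day2_multiplier           (after the condition change)
#           * trial_effect_multiplier   (final trial only)
#           * (1 + sum of decaying activity bursts)
#           + post-chase excess, capped at true_mmr.

#' Draw spontaneous activity-burst events for one fish-trial
#'
#' Bursts arrive as an inhomogeneous Poisson process (rate
#' `fish$activity_event_rate` per hour at night, tripled while lights are on)
#' with exponentially distributed amplitudes (mean `config$burst_amp_mean`,
#' expressed as a fraction of baseline) decaying with time constant
#' `fish$activity_decay` minutes.
#'
#' @param fish one row of the cohort `fish` table.
#' @param config a [sim_config()].
#' @param seed integer seed for this fish-trial's burst stream.
#' @return data.frame with columns `time_s`, `amp`.
#' @export
draw_bursts <- function(fish, config, seed) {
  set.seed(seed)
  lam_max <- fish$activity_event_rate * 3 / 3600   # events per second, day rate
  n_max <- rpois(1L, lam_max * config$trial_s)
  if (n_max == 0L) return(data.frame(time_s = numeric(0), amp = numeric(0)))
  t_cand <- sort(runif(n_max, 0, config$trial_s))
  day <- lights_on_at(t_cand, config$start_clock_s, config$lights_on_s, config$lights_off_s)
  keep <- runif(n_max) <= ifelse(day, 1, 1 / 3)     # thinning to the night rate
  t_ev <- t_cand[keep]
  data.frame(time_s = t_ev, amp = rexp(length(t_ev), rate = 1 / config$burst_amp_mean))
}

# Sum of decaying burst excursions at arbitrary times (exact event sum).
burst_excess <- function(t, bursts, decay_s) {
  out <- numeric(length(t))
  if (NROW(bursts) == 0L) return(out)
  for (j in seq_len(nrow(bursts))) {
    i <- which(t >= bursts$time_s[j])
    if (length(i)) out[i] <- out[i] + bursts$amp[j] * exp(-(t[i] - bursts$time_s[j]) / decay_s)
  }
  out
}

# Deterministic baseline (burst- and chase-free), vectorised over t.
baseline_rate <- function(fish, t, schedule_row, config, trial = "initial") {
  day <- lights_on_at(t, config$start_clock_s, config$lights_on_s, config$lights_off_s)
  second_half <- t >= schedule_row$condition_change_s
  sheltered <- if (schedule_row$shelter_first == 1L) !second_half else second_half
  fish$true_smr *
    ifelse(day, config$day_activity_multiplier, 1) *
    ifelse(sheltered, config$shelter_multiplier, 1) *
    ifelse(second_half, config$day2_multiplier, 1) *
    (if (identical(trial, "final")) config$trial_effect_multiplier else 1)
}

#' Instantaneous latent oxygen-uptake rate of a fish
#'
#' Evaluates the latent (noise-free) mass-specific oxygen uptake rate at trial
#' times `t`: the deterministic baseline modulated by photoperiod, shelter
#' cover, trial day and trial, multiplied by the activity-burst process, with
#' the post-chase response jumping to true MMR and decaying back with the
#' configured half-life. The rate never exceeds `fish$true_mmr`.
#'
#' @param fish one row of the cohort `fish` table.
#' @param t numeric vector, seconds since the fish entered the chamber.
#' @param schedule_row one row of the trial schedule (needs `shelter_first`,
#'   `condition_change_s`, `chase_s`).
#' @param config a [sim_config()].
#' @param trial `"initial"` or `"final"`.
#' @param bursts optional burst table from [draw_bursts()]; `NULL` = none.
#' @return mg O2 / kg / h, same length as `t`.
#' @export
instantaneous_mo2 <- function(fish, t, schedule_row, config, trial = "initial",
                              bursts = NULL) {
  if (any(t < 0 | t > config$trial_s)) stop("t outside the trial")
  base <- baseline_rate(fish, t, schedule_row, config, trial)
  rate <- base * (1 + burst_excess(t, bursts, fish$activity_decay * 60))
  tc <- schedule_row$chase_s
  post <- t >= tc
  if (any(post)) {
    base_tc <- baseline_rate(fish, tc, schedule_row, config, trial)
    excess <- (fish$true_mmr - base_tc) * 2^(-(t[post] - tc) / (config$chase_halflife * 60))
    rate[post] <- rate[post] + excess
  }
  pmin(rate, fish$true_mmr)
}

# Realized baseline floor of a fish-trial: the minimum deterministic baseline
# over the four MO2min windows. The floor sits in a nighttime (lights-off)
# stretch of one of the two shelter halves, so it equals
#   true_smr * trial_mult * min(shelter-half-1 factor, shelter-half-2 * day2).
# This is what the 0.2-quantile SMR estimator can recover; the shelter/day-2
# multipliers place it below raw true_smr by construction.
realized_smr <- function(fish, schedule_row, config, trial) {
  sm <- config$shelter_multiplier
  h1 <- if (schedule_row$shelter_first == 1L) sm else 1
  h2 <- (if (schedule_row$shelter_first == 1L) 1 else sm) * config$day2_multiplier
  fish$true_smr * (if (identical(trial, "final")) config$trial_effect_multiplier else 1) *
    min(h1, h2)
}
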