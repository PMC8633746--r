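# Configuration for the synthetic respirometry world.

#' Simulation configuration
#'
#' Builds the parameter set that defines the synthetic respirometry experiment:
#' the chamber schedule (7-min cycles: 2 min flush, 5 min closed measurement),
#' the trial clock, the latent metabolic-rate model of each fish, sensor noise,
#' and microbial background drift. Defaults emulate a study design of 5 batches
#' of 16 chambers, ~45 h trials at 15 degC on a 12L:12D photoperiod, fish of
#' 1.95 +/- 0.57 g, a shelter condition toggled ~21 h into the trial, an
#' exhaustive chase ~43 h in, and 3-week growth under group sizes of 4 or 8.
#'
#' @param n_batches number of respirometry batches (16 chambers each).
#' @param chambers_per_batch chambers (= fish) per batch.
#' @param chamber_volume chamber volume in litres.
#' @param cycle_flush,cycle_measure flush / closed-measurement durations (s).
#' @param sample_interval oxygen sampling interval (s). 1 Hz by default;
#'   coarser sampling is supported and used for large replicate studies.
#' @param trial_duration trial length in hours (fish-in-chamber period).
#' @param lights_on,lights_off photoperiod anchors, "HH:MM".
#' @param start_clock clock time at which fish enter the chambers, "HH:MM".
#' @param condition_change_offset hours after entry at which the plant-shelter
#'   condition over each chamber is toggled.
#' @param chase_offset hours after entry of the 2-min exhaustive chase.
#' @param temp water temperature, degC (held constant).
#' @param o2_sat dissolved-oxygen saturation concentration, mg O2 / L.
#' @param smr_mean,smr_cv lognormal mean and coefficient of variation of true
#'   standard metabolic rate, mg O2 / kg / h.
#' @param mmr_multiplier true MMR as a multiple of true SMR (> 1).
#' @param day_activity_multiplier baseline uplift while lights are on (>= 1).
#' @param shelter_multiplier baseline multiplier while the chamber is covered
#'   by plant shelter (in (0, 1]).
#' @param trial_effect_multiplier baseline multiplier applied to the whole
#'   final trial relative to the initial one.
#' @param day2_multiplier baseline multiplier applied after the condition
#'   change (second trial day).
#' @param activity_event_rate spontaneous activity bursts per hour at night;
#'   tripled while lights are on.
#' @param activity_decay exponential decay time of a burst, minutes.
#' @param burst_amp_mean mean burst amplitude (fraction of baseline; amplitudes
#'   are exponentially distributed).
#' @param chase_halflife decay half-life of the post-chase excess, minutes.
#' @param flush_tau time constant of chamber re-oxygenation during flushing
#'   (s); the relaxation carries `mix_carryover_s` into the measurement phase,
#'   which is what makes excluding the first 30 s of each measurement necessary.
#' @param mix_carryover_s duration of the mixing tail at measure-phase start (s).
#' @param background_start,background_end microbial background slope per
#'   chamber at trial start / end, mg O2 / L / h (negative = consumption).
#' @param noise_sd Gaussian sensor noise on oxygen readings, mg O2 / L.
#' @param mass_mean,mass_sd initial body mass distribution, g.
#' @param sgr_mean_by_group named numeric: mean specific growth rate (% / day)
#'   for group sizes "4" and "8".
#' @param sgr_sd between-fish SD of specific growth rate, % / day.
#' @param growth_days days spent in the social treatment.
#' @param batch_group_sizes group size assigned to each batch (whole-batch
#'   assignment mirroring the original design), or "split" to divide each batch
#'   evenly between the two sizes.
#' @param n_blank_cycles blank (empty-chamber) cycles recorded at each end.
#' @param seed integer seed governing every random draw.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_batches = 1, chambers_per_batch = 4, batch_group_sizes = 4)
#' cfg$cycle_s  # 420
#' @export
sim_config <- function(n_batches = 5,
                       chambers_per_batch = 16,
                       chamber_volume = 0.100,
                       cycle_flush = 120,
                       cycle_measure = 300,
                       sample_interval = 1,
                       trial_duration = 45,
                       lights_on = "07:00",
                       lights_off = "19:00",
                       start_clock = "15:30",
                       condition_change_offset = 21,
                       chase_offset = 43,
                       temp = 15,
                       o2_sat = 10.08,
                       smr_mean = 200,
                       smr_cv = 0.25,
                       mmr_multiplier = 3,
                       day_activity_multiplier = 1.2,
                       shelter_multiplier = 0.92,
                       trial_effect_multiplier = 1.09,
                       day2_multiplier = 0.84,
                       activity_event_rate = 1.5,
                       activity_decay = 2,
                       burst_amp_mean = 0.5,
                       chase_halflife = 10,
                       flush_tau = 30,
                       mix_carryover_s = 30,
                       background_start = -0.01,
                       background_end = -0.06,
                       noise_sd = 0.002,
                       mass_mean = 1.95,
                       mass_sd = 0.57,
                       sgr_mean_by_group = c("4" = 0.64, "8" = 0.50),
                       sgr_sd = 0.23,
                       growth_days = 21,
                       batch_group_sizes = c(4, 8, 8, 4, 8),
                       n_blank_cycles = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$n_batches, "n_batches", 1)
  stopifnot_scalar(cfg$chambers_per_batch, "chambers_per_batch", 1)
  stopifnot_scalar(cfg$chamber_volume, "chamber_volume", 1e-3)
  stopifnot_scalar(cfg$cycle_flush, "cycle_flush", 1)
  stopifnot_scalar(cfg$cycle_measure, "cycle_measure", 30)
  stopifnot_scalar(cfg$sample_interval, "sample_interval", 0.1, 60)
  stopifnot_scalar(cfg$trial_duration, "trial_duration", 1)
  stopifnot_scalar(cfg$mmr_multiplier, "mmr_multiplier", 1 + 1e-9)
  stopifnot_scalar(cfg$day_activity_multiplier, "day_activity_multiplier", 1)
  stopifnot_scalar(cfg$shelter_multiplier, "shelter_multiplier", 1e-9, 1)
  stopifnot_scalar(cfg$trial_effect_multiplier, "trial_effect_multiplier", 1e-9)
  stopifnot_scalar(cfg$day2_multiplier, "day2_multiplier", 1e-9)
  stopifnot_scalar(cfg$noise_sd, "noise_sd", 0)
  stopifnot_scalar(cfg$mass_mean, "mass_mean", 1e-3)
  stopifnot_scalar(cfg$mass_sd, "mass_sd", 0)
  stopifnot_scalar(cfg$smr_mean, "smr_mean", 1e-9)
  stopifnot_scalar(cfg$smr_cv, "smr_cv", 0)
  stopifnot_scalar(cfg$activity_event_rate, "activity_event_rate", 0)
  stopifnot_scalar(cfg$activity_decay, "activity_decay", 1e-3)
  if (!all(c("4", "8") %in% names(cfg$sgr_mean_by_group)))
    stop("sgr_mean_by_group must be named for group sizes \"4\" and \"8\"", call. = FALSE)
  if (!identical(cfg$batch_group_sizes, "split")) {
    if (length(cfg$batch_group_sizes) != cfg$n_batches)
      stop("batch_group_sizes must have one entry per batch (or be \"split\")", call. = FALSE)
    bad <- setdiff(unique(cfg$batch_group_sizes), c(4, 8))
    if (length(bad)) stop("group sizes must be 4 or 8; got ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(cfg$chambers_per_batch %% cfg$batch_group_sizes != 0))
      stop("group sizes must divide chambers_per_batch", call. = FALSE)
  }
  # derived schedule quantities
  cfg$cycle_s <- cfg$cycle_flush + cfg$cycle_measure
  cfg$trial_s <- cfg$trial_duration * 3600
  cfg$n_cycles <- floor(cfg$trial_s / cfg$cycle_s)
  cfg$start_clock_s <- clock_to_s(cfg$start_clock)
  cfg$lights_on_s <- clock_to_s(cfg$lights_on)
  cfg$lights_off_s <- clock_to_s(cfg$lights_off)
  cfg$condition_change_s <- cfg$condition_change_offset * 3600
  cfg$chase_s <- cfg$chase_offset * 3600
  if (cfg$condition_change_s >= cfg$chase_s || cfg$chase_s > cfg$trial_s)
    stop("need condition_change_offset < chase_offset <= trial_duration", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_batches, "batch(es) x", x$chambers_per_batch, "chambers;",
      x$trial_duration, "h trials of", x$cycle_s, "s cycles;",
      x$n_cycles, "cycles/chamber; seed", x$seed, "\n")
  invisible(x)
}
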