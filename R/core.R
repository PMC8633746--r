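# Respirometry core: raw traces -> background-corrected, mass-specific
# oxygen-uptake estimates per measurement cycle, with quality control.

#' Segment a raw trace into measurement windows
#'
#' Extracts one sample window per closed measurement phase (or per blank
#' cycle), removing the first `exclude_initial_s` seconds of each phase, where
#' incomplete mixing after flushing biases the decline. Phases shorter than
#' `exclude_initial_s + 60` s are dropped with a message.
#'
#' @param trace data.frame with at least `time_s, chamber_id, phase,
#'   cycle_index, o2_mg_per_l` (see the raw-trace CSV schema).
#' @param exclude_initial_s seconds discarded at the start of each phase.
#' @param phases which phase labels count as closed measurements.
#' @return list of windows (data.frames of samples), each with attributes
#'   `chamber_id`, `cycle_index`, `phase`; ordered by chamber then time.
#' @export
segment_cycles <- function(trace, exclude_initial_s = 30,
                           phases = c("measure", "blank")) {
  stopifnot(all(c("time_s", "chamber_id", "phase", "cycle_index", "o2_mg_per_l")
                %in% names(trace)))
  dt <- data.table::as.data.table(trace)[phase %in% phases]
  if (nrow(dt) == 0L) return(list())
  data.table::setorder(dt, chamber_id, time_s)
  dt[, `:=`(w_start = min(time_s), w_end = max(time_s)),
     by = c("chamber_id", "cycle_index", "phase")]
  short <- unique(dt[w_end - w_start < exclude_initial_s + 60,
                     c("chamber_id", "cycle_index")])
  if (nrow(short))
    message("segment_cycles: dropped ", nrow(short),
            " measurement phase(s) shorter than ", exclude_initial_s + 60, " s")
  dt <- dt[w_end - w_start >= exclude_initial_s + 60 &
             time_s >= w_start + exclude_initial_s]
  sp <- split(as.data.frame(dt[, c("time_s", "o2_mg_per_l", "chamber_id",
                                   "cycle_index", "phase")]),
              list(dt$chamber_id, dt$cycle_index), drop = TRUE)
  sp <- sp[order(vapply(sp, function(w) w$chamber_id[1L], character(1)),
                 vapply(sp, function(w) w$time_s[1L], numeric(1)))]
  lapply(sp, function(w) {
    attr(w, "chamber_id") <- w$chamber_id[1L]
    attr(w, "cycle_index") <- w$cycle_index[1L]
    attr(w, "phase") <- w$phase[1L]
    w
  })
}

#' Ordinary least-squares fit of the oxygen decline in one window
#'
#' @param window a window from [segment_cycles()] (columns `time_s`,
#'   `o2_mg_per_l`), or any data.frame with those columns.
#' @return one-row data.frame: `cycle_index, t_mid, slope` (mg O2/L/h, signed;
#'   negative = consumption), `intercept, r2, n_points`. A zero-variance
#'   response yields slope 0 with `r2 = 0` by convention (a flat trace carries
#'   no uptake signal and must fail QC).
#' @export
fit_slope <- function(window) {
  t <- window$time_s; y <- window$o2_mg_per_l
  if (length(t) < 2L) stop("fit_slope needs at least 2 samples")
  vt <- stats::var(t)
  if (!is.finite(vt) || vt == 0) stop("fit_slope: zero time variance")
  vy <- stats::var(y)
  if (vy == 0) {
    slope_s <- 0; r2 <- 0; intercept <- y[1L]
  } else {
    slope_s <- stats::cov(t, y) / vt
    intercept <- mean(y) - slope_s * mean(t)
    r2 <- stats::cor(t, y)^2
  }
  data.frame(cycle_index = attr(window, "cycle_index") %||% NA_integer_,
             t_mid = mean(range(t)),
             slope = slope_s * 3600,
             intercept = intercept,
             r2 = r2,
             n_points = length(t))
}

#' Fit every window of a trace (vectorised fast path)
#'
#' Grouped closed-form least squares over all measurement (and blank) windows
#' of a trace; equivalent to [fit_slope()] applied to each window of
#' [segment_cycles()] (enforced by tests).
#'
#' @inheritParams segment_cycles
#' @return data.table of slope fits with `chamber_id`, `phase` and the
#'   [fit_slope()] columns.
#' @export
fit_all_slopes <- function(trace, exclude_initial_s = 30,
                           phases = c("measure", "blank")) {
  dt <- data.table::as.data.table(trace)[phase %in% phases]
  if (nrow(dt) == 0L)
    return(data.table::data.table(chamber_id = character(0), phase = character(0),
                                  cycle_index = integer(0), t_mid = numeric(0),
                                  slope = numeric(0), intercept = numeric(0),
                                  r2 = numeric(0), n_points = integer(0)))
  dt[, w_start := min(time_s), by = c("chamber_id", "cycle_index", "phase")]
  dt[, w_len := max(time_s) - w_start, by = c("chamber_id", "cycle_index", "phase")]
  dt <- dt[w_len >= exclude_initial_s + 60 & time_s >= w_start + exclude_initial_s]
  out <- dt[, {
    vt <- stats::var(time_s)
    vy <- stats::var(o2_mg_per_l)
    if (vy == 0) {
      list(t_mid = mean(range(time_s)), slope = 0, intercept = o2_mg_per_l[1L],
           r2 = 0, n_points = .N)
    } else {
      b <- stats::cov(time_s, o2_mg_per_l) / vt
      list(t_mid = mean(range(time_s)),
           slope = b * 3600,
           intercept = mean(o2_mg_per_l) - b * mean(time_s),
           r2 = stats::cor(time_s, o2_mg_per_l)^2,
           n_points = .N)
    }
  }, by = c("chamber_id", "phase", "cycle_index")]
  data.table::setorder(out, chamber_id, t_mid)
  out[]
}

#' Background (microbial) respiration model of one chamber
#'
#' Averages the slope fits of the blank cycles recorded at each end of the
#' trial and interpolates linearly between the two anchors; outside the anchor
#' times the model is clamped to the endpoint values (the anchors sit at the
#' trial boundaries, so extrapolation has nothing to stand on).
#'
#' @param blank_fits_start,blank_fits_end data.frames of blank-cycle slope
#'   fits (columns `slope`, `t_mid`), normally 3 each.
#' @param n_required how many blank fits each end must have.
#' @return object of class `background_model`.
#' @export
estimate_background <- function(blank_fits_start, blank_fits_end, n_required = 3) {
  if (NROW(blank_fits_start) != n_required || NROW(blank_fits_end) != n_required)
    stop("estimate_background: need exactly ", n_required,
         " blank fits at each end (got ", NROW(blank_fits_start), " / ",
         NROW(blank_fits_end), "); pass zero_background() to skip correction")
  structure(list(slope_start = mean(blank_fits_start$slope),
                 slope_end = mean(blank_fits_end$slope),
                 t_start = mean(blank_fits_start$t_mid),
                 t_end = mean(blank_fits_end$t_mid)),
            class = "background_model")
}

#' A zero-background model (explicit opt-out of correction)
#' @param t_start,t_end anchor times (only cosmetic).
#' @export
zero_background <- function(t_start = 0, t_end = 1) {
  structure(list(slope_start = 0, slope_end = 0, t_start = t_start, t_end = t_end),
            class = "background_model")
}

#' Evaluate a background model at time `t` (clamped linear interpolation)
#' @param bg a `background_model`.
#' @param t numeric vector of trial times (s).
#' @return background slope, mg O2/L/h.
#' @export
background_at <- function(bg, t) {
  stopifnot(inherits(bg, "background_model"))
  if (bg$t_end == bg$t_start) return(rep(bg$slope_start, length(t)))
  w <- pmin(pmax((t - bg$t_start) / (bg$t_end - bg$t_start), 0), 1)
  bg$slope_start + w * (bg$slope_end - bg$slope_start)
}

#' Convert slope fits to oxygen-uptake estimates
#'
#' Subtracts the background slope (in slope units, before volume scaling),
#' multiplies by the effective water volume (chamber volume minus fish volume
#' at a density of 1 kg/L, so mass in g = displaced volume in mL), and divides
#' by mass for the mass-specific rate. Negative corrected rates are kept but
#' flagged, never silently zeroed.
#'
#' @param fits data.frame of slope fits (columns `slope, t_mid, r2, ...`).
#' @param bg a `background_model` for the chamber.
#' @param chamber_volume chamber volume, litres.
#' @param fish_mass fish mass, grams.
#' @return `fits` with added columns `mo2_abs` (mg O2/h), `mo2_mass_specific`
#'   (mg O2/kg/h) and `v_eff`.
#' @export
compute_mo2 <- function(fits, bg, chamber_volume, fish_mass) {
  stopifnot(fish_mass > 0)
  v_eff <- chamber_volume - fish_mass / 1000
  if (v_eff <= 0) stop("effective volume <= 0: fish (", fish_mass,
                       " g) does not fit chamber (", chamber_volume, " L)")
  out <- as.data.frame(fits)
  out$mo2_abs <- -(out$slope - background_at(bg, out$t_mid)) * v_eff
  out$mo2_mass_specific <- out$mo2_abs / (fish_mass / 1000)
  out$v_eff <- v_eff
  out
}

#' Quality-control filter on per-cycle estimates
#'
#' An estimate passes when its decline fit has `r2 > r2_min` (strict, matching
#' the published rule) and its background-corrected rate is non-negative.
#' Idempotent; partitions its input.
#'
#' @param estimates data.frame with columns `r2` and `mo2_mass_specific`.
#' @param r2_min rejection threshold (strict inequality).
#' @return list with `passed` and `rejected` (the latter with a
#'   `reject_reason` column); both carry `qc_pass`.
#' @export
qc_filter <- function(estimates, r2_min = 0.95) {
  est <- as.data.frame(estimates)
  low_r2 <- !(est$r2 > r2_min)
  neg <- est$mo2_mass_specific < 0
  est$qc_pass <- !low_r2 & !neg
  est$reject_reason <- ifelse(est$qc_pass, "",
                              ifelse(low_r2 & neg, "low_r2;negative_rate",
                                     ifelse(low_r2, "low_r2", "negative_rate")))
  list(passed = est[est$qc_pass, , drop = FALSE],
       rejected = est[!est$qc_pass, , drop = FALSE])
}

# ---- trace -> estimates orchestration ---------------------------------------

#' Per-cycle oxygen-uptake estimates for a whole trace
#'
#' Fits every measurement and blank window, builds each chamber's background
#' model from its blank cycles (split at the midpoint of the blank anchor
#' times), converts fish cycles to absolute and mass-specific uptake, labels
#' each estimate with its shelter condition and photoperiod, and applies QC.
#'
#' @param trace raw trace table (schema of the raw-trace CSV).
#' @param schedule schedule table for this trial (one row per chamber).
#' @param meta metadata table (`fish_id, chamber_id, mass_initial_g,
#'   mass_final_g, ...`).
#' @param trial `"initial"` or `"final"` (selects which mass to use).
#' @param chamber_volume chamber volume, litres.
#' @param r2_min QC threshold.
#' @param exclude_initial_s seconds excluded at measure-phase start.
#' @param slopes optionally, a pre-computed slope table (slope-level simulation
#'   fast path) used instead of fitting `trace`.
#' @return data.table with one row per fish cycle: `fish_id, trial,
#'   chamber_id, cycle_index, t_mid_s, shelter_on, photoperiod, slope, r2,
#'   n_points, mo2_abs, mo2_mass_specific, qc_pass, reject_reason`.
#' @export
estimates_from_trace <- function(trace = NULL, schedule, meta, trial = "initial",
                                 chamber_volume = 0.100, r2_min = 0.95,
                                 exclude_initial_s = 30, slopes = NULL) {
  if (is.null(slopes)) {
    if (is.null(trace)) stop("need either a trace or pre-computed slopes")
    slopes <- fit_all_slopes(trace, exclude_initial_s = exclude_initial_s)
  }
  slopes <- data.table::as.data.table(slopes)
  meta <- data.table::as.data.table(meta)
  schedule <- data.table::as.data.table(schedule)
  mass_col <- if (identical(trial, "final")) "mass_final_g" else "mass_initial_g"
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    ch <- meta$chamber_id[i]
    sl <- slopes[chamber_id == ch]
    if (nrow(sl) == 0L) next
    blanks <- sl[phase == "blank"]
    fishcyc <- sl[phase == "measure"]
    mid <- mean(range(blanks$t_mid))
    bg <- estimate_background(blanks[t_mid < mid], blanks[t_mid >= mid],
                              n_required = nrow(blanks) / 2)
    est <- compute_mo2(fishcyc, bg, chamber_volume, meta[[mass_col]][i])
    sr <- schedule[chamber_id == ch]
    if (nrow(sr) != 1L) stop("schedule must have one row for chamber ", ch)
    second_half <- est$t_mid >= sr$condition_change_s
    est$shelter_on <- if (sr$shelter_first == 1L) !second_half else second_half
    start_clock_s <- clock_to_s(sr$start_clock %||% "15:30")
    est$photoperiod <- ifelse(lights_on_at(est$t_mid, start_clock_s,
                                           clock_to_s(sr$lights_on),
                                           clock_to_s(sr$lights_off)),
                              "day", "night")
    est$fish_id <- meta$fish_id[i]
    est$trial <- trial
    out[[i]] <- est
  }
  est <- data.table::rbindlist(out)
  qc <- qc_filter(est, r2_min = r2_min)
  est <- data.table::rbindlist(list(qc$passed, qc$rejected))
  data.table::setorder(est, fish_id, t_mid)
  data.table::setnames(est, "t_mid", "t_mid_s")
  cols <- c("fish_id", "trial", "chamber_id", "cycle_index", "t_mid_s",
            "shelter_on", "photoperiod", "slope", "r2", "n_points",
            "mo2_abs", "mo2_mass_specific", "qc_pass", "reject_reason")
  est[, intersect(cols, names(est)), with = FALSE]
}
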