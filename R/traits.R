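# Metabolic traits: windowed minimum rates, SMR, MMR, aerobic scope,
# allometric mass adjustment, and specific growth rate.

#' Build the MO2min estimation windows of a trial
#'
#' Per chamber: the nighttime window of trial day 1 runs from 5 h after entry
#' (acclimation) to the first lights-on; the day-1 window from lights-on to the
#' condition change; the night-2 window from 5 h after the condition change to
#' the second lights-on; the day-2 window from the second lights-on to the
#' chase. Each window carries the shelter state of its trial half. A chase
#' before the second lights-on truncates (drops) the day-2 window with a
#' warning.
#'
#' @param schedule schedule table of one trial (one row per chamber; columns
#'   `chamber_id, trial, shelter_first, condition_change_s, chase_s, lights_on,
#'   lights_off, start_clock`).
#' @param acclimation_h hours of acclimation after entry / condition change.
#' @return data.table: `chamber_id, trial, photoperiod, trial_day, shelter_on,
#'   start_s, end_s`.
#' @export
build_windows <- function(schedule, acclimation_h = 5) {
  sched <- data.table::as.data.table(schedule)
  out <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    sr <- sched[i, ]
    start_clock_s <- clock_to_s(sr$start_clock %||% "15:30")
    on1 <- nth_lights_on(1, start_clock_s, clock_to_s(sr$lights_on))
    on2 <- on1 + 86400
    sh1 <- sr$shelter_first == 1L
    w <- data.table::data.table(
      chamber_id = sr$chamber_id, trial = sr$trial,
      photoperiod = c("night", "day", "night", "day"),
      trial_day = c(1L, 1L, 2L, 2L),
      shelter_on = c(sh1, sh1, !sh1, !sh1),
      start_s = c(acclimation_h * 3600, on1,
                  sr$condition_change_s + acclimation_h * 3600, on2),
      end_s = c(on1, sr$condition_change_s, on2, sr$chase_s))
    if (any(w$start_s >= w$end_s)) {
      warning("dropping degenerate window(s) for chamber ", sr$chamber_id,
              " (chase before second lights-on?)")
      w <- w[w$start_s < w$end_s, ]
    }
    out[[i]] <- w
  }
  data.table::rbindlist(out)
}

#' Windowed minimum metabolic rate: empirical quantile of cycle estimates
#'
#' The q-quantile with linear interpolation between order statistics on the
#' (n-1) spacing (the convention frozen in this package and enforced against a
#' brute-force order-statistic oracle in the tests). Returns `NA` (invalid)
#' when fewer than `min_cycles` QC-passed estimates are available.
#'
#' @param x numeric vector of QC-passed mass-specific MO2 estimates.
#' @param q quantile (0.2 by default).
#' @param min_cycles minimum number of estimates for a valid value.
#' @return mg O2/kg/h, or `NA_real_`.
#' @export
mo2min_quantile <- function(x, q = 0.2, min_cycles = 10) {
  stopifnot(q >= 0, q <= 1)
  x <- x[is.finite(x)]
  if (length(x) < min_cycles) return(NA_real_)
  unname(stats::quantile(x, probs = q, type = 7))
}

#' Standard metabolic rate: lowest windowed MO2min of a fish-trial
#' @param mo2min_values the (up to 4) windowed estimates; NAs ignored.
#' @return mg O2/kg/h, or `NA_real_` when none are valid.
#' @export
compute_smr <- function(mo2min_values) {
  v <- mo2min_values[is.finite(mo2min_values)]
  if (!length(v)) return(NA_real_)
  min(v)
}

#' Aerobic scope: MMR minus SMR
#' @param mmr,smr mass-specific rates; either `NA` makes the result `NA`.
#' @export
compute_as <- function(mmr, smr) {
  ifelse(is.finite(mmr) & is.finite(smr), mmr - smr, NA_real_)
}

#' Maximum metabolic rate from the post-chase trace
#'
#' Within each of the first `cycles_considered` measurement cycles that start
#' after the chase (first `exclude_initial_s` s excluded), slides a regression
#' window of `window_s` seconds one sample at a time; MMR is the maximum over
#' all windows of the background-corrected, volume-scaled, mass-specific rate.
#'
#' @param post_chase_trace raw trace of one chamber (may include pre-chase
#'   samples; they are ignored).
#' @param bg a `background_model`.
#' @param chamber_volume litres; `fish_mass` grams.
#' @param chase_s chase time, seconds since entry.
#' @param fish_mass fish mass in grams.
#' @param window_s rolling regression window (s).
#' @param cycles_considered how many post-chase cycles to scan (1 = the cycle
#'   of immediate measurement; up to ~8 covers the following hour).
#' @param exclude_initial_s seconds excluded at measure-phase start.
#' @return mg O2/kg/h, or `NA_real_` when no post-chase cycle exists.
#' @export
compute_mmr <- function(post_chase_trace, bg, chamber_volume, fish_mass, chase_s,
                        window_s = 180, cycles_considered = 1,
                        exclude_initial_s = 30) {
  wins <- segment_cycles(post_chase_trace, exclude_initial_s = exclude_initial_s,
                         phases = "measure")
  raw_start <- vapply(wins, function(w) min(w$time_s), numeric(1)) - exclude_initial_s
  wins <- wins[raw_start >= chase_s]
  if (!length(wins)) return(NA_real_)
  wins <- wins[seq_len(min(cycles_considered, length(wins)))]
  v_eff <- chamber_volume - fish_mass / 1000
  if (v_eff <= 0) stop("effective volume <= 0")
  best <- -Inf
  for (w in wins) {
    t <- w$time_s; y <- w$o2_mg_per_l
    n <- length(t)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && t[j + 1L] - t[i] <= window_s) j <- j + 1L
      if (t[j] - t[i] >= window_s - (t[2L] - t[1L])) {   # full-width window
        ts <- t[i:j]; ys <- y[i:j]
        sl <- stats::cov(ts, ys) / stats::var(ts) * 3600
        rate <- -(sl - background_at(bg, mean(range(ts)))) * v_eff / (fish_mass / 1000)
        if (rate > best) best <- rate
      } else break
      i <- i + 1L
    }
  }
  if (is.finite(best)) best else NA_real_
}

#' Allometric scaling exponent from a cohort
#'
#' OLS slope of log absolute MO2 (mg O2/h) on log body mass (g).
#'
#' @param mass_g,mo2_abs positive numeric vectors (n >= 3).
#' @return list: `b`, `intercept`, `n`.
#' @export
estimate_scaling_exponent <- function(mass_g, mo2_abs) {
  ok <- is.finite(mass_g) & is.finite(mo2_abs)
  mass_g <- mass_g[ok]; mo2_abs <- mo2_abs[ok]
  if (length(mass_g) < 3L) stop("need at least 3 (mass, MO2) pairs")
  if (any(mass_g <= 0) || any(mo2_abs <= 0)) stop("masses and MO2 must be positive")
  x <- log(mass_g); y <- log(mo2_abs)
  b <- stats::cov(x, y) / stats::var(x)
  list(b = b, intercept = mean(y) - b * mean(x), n = length(x))
}

#' Adjust a metabolic rate to a common reference mass
#'
#' `MO2_adj = mean_mass^(b-1) * mass^(1-b) * MO2`, with `b` the log-log
#' scaling exponent of absolute MO2 on mass. Applied to mass-specific rates
#' this removes their residual mass dependence; it is the identity when
#' `mass == mean_mass` or `b == 1`.
#'
#' @param mo2 rate(s) to adjust.
#' @param mass individual mass, g.
#' @param mean_mass reference mass, g (1.95 by default).
#' @param b scaling exponent.
#' @export
mass_adjust <- function(mo2, mass, mean_mass = 1.95, b) {
  stopifnot(all(mass > 0), mean_mass > 0)
  mean_mass^(b - 1) * mass^(1 - b) * mo2
}

#' Specific growth rate, % per day
#'
#' `SGR = 100 * [ln(Mf) - ln(Mi)] / t` (natural log; the conventional form,
#' consistent with growth of the observed magnitude over 3 weeks).
#'
#' @param mass_initial,mass_final masses in g (positive).
#' @param t growth period in days (> 0).
#' @export
compute_sgr <- function(mass_initial, mass_final, t) {
  if (any(t <= 0)) stop("growth period must be positive")
  stopifnot(all(mass_initial > 0), all(mass_final > 0))
  100 * (log(mass_final) - log(mass_initial)) / t
}

#' Aggregate per-cycle estimates into the trait set
#'
#' Assigns QC-passed estimates to their MO2min windows, computes the windowed
#' 0.2-quantile minima, SMR (lowest valid windowed minimum), MMR (supplied
#' per fish-trial, e.g. from [compute_mmr()]), aerobic scope, allometrically
#' mass-adjusted variants (scaling exponent estimated per trait from the
#' initial-trial cohort unless `b_fixed` is given), and SGR.
#'
#' @param estimates output of [estimates_from_trace()] (both trials stacked).
#' @param windows output of [build_windows()] (both trials stacked).
#' @param meta metadata table.
#' @param mmr_table data.frame `fish_id` (or `chamber_id`), `trial`, `mmr`
#'   (mass-specific), or `NULL`.
#' @param q quantile for windowed minima.
#' @param min_cycles minimum QC-passed cycles for a valid windowed minimum.
#' @param reference_mass g, for mass adjustment.
#' @param b_fixed optional fixed scaling exponent overriding estimation.
#' @param growth_days days between the two weighings.
#' @return list: `traits` (one row per fish x trial), `mo2min_long` (one row
#'   per fish x trial x window), `scaling` (per-trait exponent fits).
#' @export
compute_traits <- function(estimates, windows, meta, mmr_table = NULL, q = 0.2,
                           min_cycles = 10, reference_mass = 1.95,
                           b_fixed = NULL, growth_days = 21) {
  est <- data.table::as.data.table(estimates)[qc_pass == TRUE]
  win <- data.table::as.data.table(windows)
  meta <- data.table::as.data.table(meta)
  if (!is.null(mmr_table)) {
    mmr_table <- data.table::as.data.table(mmr_table)
    if (!"fish_id" %in% names(mmr_table))
      mmr_table <- merge(mmr_table, meta[, c("fish_id", "chamber_id")], by = "chamber_id")
  }
  keep <- setdiff(c("fish_id", "chamber_id", "batch", "tank_id", "group_size",
                    "shelter_available", "mass_initial_g", "mass_final_g"),
                  setdiff(names(est), "fish_id"))
  est <- merge(est, meta[, keep, with = FALSE], by = "fish_id")

  # assign each QC-passed estimate to its window (non-equi join), then take
  # the windowed quantile minima per fish-trial-window
  win2 <- data.table::copy(win)[, w_id := .I]
  hits <- est[win2, on = .(chamber_id, trial, t_mid_s >= start_s, t_mid_s < end_s),
              nomatch = NULL, .(w_id, mo2_mass_specific)]
  agg <- hits[, .(mo2min = mo2min_quantile(mo2_mass_specific, q = q,
                                           min_cycles = min_cycles),
                  n_cycles = .N), by = w_id]
  long <- merge(win2, agg, by = "w_id", all.x = TRUE)
  long[is.na(n_cycles), n_cycles := 0L]
  long[, c("w_id", "start_s", "end_s") := NULL]
  long <- merge(long, meta, by = "chamber_id")
  long[, mass_g := ifelse(trial == "final", mass_final_g, mass_initial_g)]
  long[, valid := is.finite(mo2min)]

  traits <- long[, .(smr = compute_smr(mo2min), n_windows_valid = sum(valid)),
                 by = c("fish_id", "trial")]
  traits <- merge(traits, meta, by = "fish_id")
  traits[, mass_g := ifelse(trial == "final", mass_final_g, mass_initial_g)]
  if (!is.null(mmr_table)) {
    traits <- merge(traits, mmr_table[, c("fish_id", "trial", "mmr")],
                    by = c("fish_id", "trial"), all.x = TRUE)
  } else traits[, mmr := NA_real_]
  traits[, smr_valid := is.finite(smr)]
  traits[, mmr_valid := is.finite(mmr) & (!smr_valid | mmr >= smr)]
  traits[, mmr := ifelse(mmr_valid, mmr, NA_real_)]
  traits[, aerobic_scope := compute_as(mmr, smr)]
  traits[, as_valid := is.finite(aerobic_scope)]
  traits[, sgr := compute_sgr(mass_initial_g, mass_final_g, growth_days)]

  # scaling exponents from the initial-trial cohort, on absolute MO2
  fit_b <- function(mass, ms_rate) {
    if (!is.null(b_fixed)) return(list(b = b_fixed, intercept = NA_real_, n = NA_integer_))
    ok <- is.finite(ms_rate) & is.finite(mass) & ms_rate > 0
    if (sum(ok) < 3L) return(list(b = 1, intercept = NA_real_, n = sum(ok)))
    estimate_scaling_exponent(mass[ok], ms_rate[ok] * mass[ok] / 1000)
  }
  ti <- traits[trial == "initial"]
  li <- long[trial == "initial" & valid == TRUE]
  scaling <- list(mo2min = fit_b(li$mass_g, li$mo2min),
                  smr = fit_b(ti$mass_g, ti$smr),
                  mmr = fit_b(ti$mass_g, ti$mmr))
  long[, mo2min_adj := mass_adjust(mo2min, mass_g, reference_mass, scaling$mo2min$b)]
  traits[, smr_adj := mass_adjust(smr, mass_g, reference_mass, scaling$smr$b)]
  traits[, mmr_adj := mass_adjust(mmr, mass_g, reference_mass, scaling$mmr$b)]
  traits[, as_adj := compute_as(mmr_adj, smr_adj)]
  traits[, `:=`(b_smr = scaling$smr$b, b_mmr = scaling$mmr$b,
                b_mo2min = scaling$mo2min$b, reference_mass = reference_mass)]
  data.table::setorder(traits, fish_id, trial)
  data.table::setorder(long, fish_id, trial, trial_day, photoperiod)
  list(traits = traits[], mo2min_long = long[], scaling = scaling)
}
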