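# Trial simulation: oxygen traces (or per-cycle slope fits) for every chamber.

#' Build the per-chamber schedule of one respirometry trial
#'
#' Randomizes (with the run seed) whether each chamber starts covered by plant
#' shelter; the order is reversed for the final trial. Records the condition
#' change and chase times and the photoperiod anchors.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a [sim_config()].
#' @param trial `"initial"` or `"final"`.
#' @return data.table: `chamber_id, trial, shelter_first, condition_change_s,
#'   chase_s, lights_on, lights_off, start_clock`.
#' @export
build_schedule <- function(cohort, config, trial = "initial") {
  fish <- cohort$fish
  set.seed(substream_seed(config$seed, "shelter-order"))
  first <- as.integer(runif(nrow(fish)) < 0.5)
  if (identical(trial, "final")) first <- 1L - first
  data.table::data.table(
    chamber_id = fish$chamber_id,
    trial = trial,
    shelter_first = first,
    condition_change_s = config$condition_change_s,
    chase_s = config$chase_s,
    lights_on = config$lights_on,
    lights_off = config$lights_off,
    start_clock = config$start_clock)
}

# ---- trace-level simulation -------------------------------------------------

# Piecewise forward-Euler integration of chamber O2. Segments:
#   flush     : dO2 = ((sat - O2)/tau - uptake + bg) dt   (re-oxygenation)
#   mix tail  : same dynamics for the first `mix_carryover_s` of each
#               measurement (incomplete mixing biases the early slope, which
#               is why the first 30 s are excluded downstream)
#   closed    : dO2 = (-uptake + bg) dt                   (linear decline)
integrate_o2 <- function(t, uptake_per_s, bg_per_s, seg, config) {
  dt <- config$sample_interval
  a_relax <- 1 - dt / config$flush_tau
  if (a_relax <= 0) stop("sample_interval must be < flush_tau")
  o2 <- numeric(length(t))
  o2[1L] <- config$o2_sat
  seg_id <- cumsum(c(TRUE, seg[-1L] != seg[-length(seg)]))
  bounds <- c(0L, cumsum(tabulate(seg_id)))
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k] + 1L; e <- bounds[k + 1L]
    relax <- seg[s] != "closed"
    a <- if (relax) a_relax else 1
    cc <- dt * ((if (relax) config$o2_sat / config$flush_tau else 0) -
                  uptake_per_s[s:e] + bg_per_s[s:e])
    # forward Euler: o2[i+1] = a*o2[i] + cc[i] for i in s..e
    y <- stats::filter(cc, a, method = "recursive", init = o2[s])
    if (e > s) o2[(s + 1L):e] <- y[seq_len(e - s)]
    if (e < length(t)) o2[e + 1L] <- y[e - s + 1L]
  }
  o2
}

# Per-sample layout of one chamber's trace: time, cycle index, phase labels,
# integration segment. Blank cycles flank the fish period on both sides.
trace_layout <- function(config) {
  dt <- config$sample_interval
  nb <- config$n_blank_cycles
  blank_s <- nb * config$cycle_s
  # fish period = complete cycles only, so blank blocks align with the cycle
  # grid (a trailing partial cycle would smear into the first end blank)
  fish_end <- config$n_cycles * config$cycle_s
  t <- seq(-blank_s, fish_end + blank_s - dt, by = dt)
  tt <- (t + blank_s) %% config$cycle_s
  cyc_raw <- floor((t + blank_s) / config$cycle_s)          # 0-based from first blank
  cycle_index <- ifelse(t < 0, cyc_raw - nb,                # -nb..-1 start blanks
                        cyc_raw - nb + 1L)                  # 1.. fish, then end blanks
  is_blank <- t < 0 | t >= fish_end
  in_flush <- tt < config$cycle_flush
  phase <- ifelse(in_flush, "flush", ifelse(is_blank, "blank", "measure"))
  seg <- ifelse(in_flush, "flush",
                ifelse(tt < config$cycle_flush + config$mix_carryover_s, "mix", "closed"))
  list(t = t, cycle_index = as.integer(cycle_index), phase = phase, seg = seg,
       is_blank = is_blank)
}

# Linear microbial background slope (mg O2/L/h) anchored at the midpoints of
# the two blank blocks.
sim_background_slope <- function(t, config) {
  blank_s <- config$n_blank_cycles * config$cycle_s
  t0 <- -blank_s / 2; t1 <- config$n_cycles * config$cycle_s + blank_s / 2
  w <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  config$background_start + w * (config$background_end - config$background_start)
}

sim_chamber_trace <- function(fish, schedule_row, config, trial, bursts, noise = TRUE) {
  lay <- trace_layout(config)
  t <- lay$t
  rate <- numeric(length(t))                                   # mg O2/kg/h
  inside <- !lay$is_blank
  if (any(inside)) {
    ti <- t[inside]
    base <- baseline_rate(fish, ti, schedule_row, config, trial)
    dtg <- config$sample_interval
    imp <- numeric(length(ti))
    if (NROW(bursts) > 0) {
      idx <- pmin(length(ti), floor(bursts$time_s / dtg) + 1L)
      for (j in seq_along(idx)) imp[idx[j]] <- imp[idx[j]] + bursts$amp[j]
    }
    B <- as.numeric(stats::filter(imp, exp(-dtg / (fish$activity_decay * 60)),
                                  method = "recursive"))
    r <- base * (1 + B)
    tc <- schedule_row$chase_s
    post <- ti >= tc
    if (any(post)) {
      base_tc <- baseline_rate(fish, tc, schedule_row, config, trial)
      r[post] <- r[post] + (fish$true_mmr - base_tc) *
        2^(-(ti[post] - tc) / (config$chase_halflife * 60))
    }
    rate[inside] <- pmin(r, fish$true_mmr)
  }
  v_eff <- config$chamber_volume - fish$mass_initial_g / 1000
  if (identical(trial, "final")) v_eff <- config$chamber_volume - fish$mass_final_g / 1000
  if (v_eff <= 0) stop("fish volume exceeds chamber volume in chamber ", fish$chamber_id)
  mass_kg <- (if (identical(trial, "final")) fish$mass_final_g else fish$mass_initial_g) / 1000
  uptake_per_s <- rate * mass_kg / v_eff / 3600                # mg O2/L/s
  bg_per_s <- sim_background_slope(t, config) / 3600
  o2 <- integrate_o2(t, uptake_per_s, bg_per_s, lay$seg, config)
  if (any(o2 <= 0))
    stop("simulated O2 fell to zero in chamber ", fish$chamber_id,
         " (first at t=", t[which(o2 <= 0)[1L]], " s); reduce rates or volume")
  if (noise && config$noise_sd > 0) o2 <- o2 + rnorm(length(o2), 0, config$noise_sd)
  data.table::data.table(
    time_s = t,
    clock_time = s_to_clock(config$start_clock_s + t),
    chamber_id = fish$chamber_id,
    phase = lay$phase,
    cycle_index = lay$cycle_index,
    o2_mg_per_l = o2,
    temp_c = config$temp)
}

# ---- slope-level fast path --------------------------------------------------

# Per-cycle latent mean rate over each measurement window (first
# mix_carryover_s excluded), computed on a uniform coarse grid with the same
# recursive-filter burst evaluation as the trace path. `sub_dt` must divide
# the cycle structure (defaults do: 420/15, 120/15, 30/15).
latent_cycle_means <- function(fish, schedule_row, config, trial, bursts, sub_dt = 15) {
  ncyc <- config$n_cycles
  per <- config$cycle_s / sub_dt
  tg <- seq(0, ncyc * config$cycle_s - sub_dt, by = sub_dt)
  base <- baseline_rate(fish, tg, schedule_row, config, trial)
  B <- numeric(length(tg))
  if (NROW(bursts) > 0) {
    imp <- numeric(length(tg))
    idx <- pmin(length(tg), floor(bursts$time_s / sub_dt) + 1L)
    for (j in seq_along(idx)) imp[idx[j]] <- imp[idx[j]] + bursts$amp[j]
    B <- as.numeric(stats::filter(imp, exp(-sub_dt / (fish$activity_decay * 60)),
                                  method = "recursive"))
  }
  r <- base * (1 + B)
  tc <- schedule_row$chase_s
  post <- tg >= tc
  if (any(post)) {
    base_tc <- baseline_rate(fish, tc, schedule_row, config, trial)
    r[post] <- r[post] + (fish$true_mmr - base_tc) *
      2^(-(tg[post] - tc) / (config$chase_halflife * 60))
  }
  r <- pmin(r, fish$true_mmr)
  m <- matrix(r, nrow = per)                       # columns = cycles
  keep <- (tg[seq_len(per)] %% config$cycle_s) >=
    config$cycle_flush + config$mix_carryover_s    # measure window after mix tail
  data.table::data.table(
    cycle_index = seq_len(ncyc),
    t_mid = (seq_len(ncyc) - 1) * config$cycle_s +
      config$cycle_flush + config$mix_carryover_s +
      (config$cycle_measure - config$mix_carryover_s) / 2,
    latent = colMeans(m[keep, , drop = FALSE]))
}

# OLS noise theory for a slope fitted to a window of W seconds sampled every
# `dt` s with Gaussian O2 noise `sd`: SE(slope per hour) and theoretical R^2.
slope_noise_theory <- function(true_slope_h, window_s, dt, sd) {
  tt <- seq(0, window_s - dt, by = dt)
  vt <- stats::var(tt) * (length(tt) - 1) / length(tt)
  se_h <- if (sd > 0) sd / sqrt(vt * length(tt)) * 3600 else 0
  beta_s <- true_slope_h / 3600
  r2 <- if (sd > 0) beta_s^2 * vt / (beta_s^2 * vt + sd^2) else 1
  list(se_h = se_h, r2 = r2, n = length(tt), vt = vt)
}

sim_chamber_slopes <- function(fish, schedule_row, config, trial, bursts) {
  lat <- latent_cycle_means(fish, schedule_row, config, trial, bursts)
  mass_g <- if (identical(trial, "final")) fish$mass_final_g else fish$mass_initial_g
  v_eff <- config$chamber_volume - mass_g / 1000
  win_s <- config$cycle_measure - config$mix_carryover_s
  true_slope <- -(lat$latent * (mass_g / 1000) / v_eff) + sim_background_slope(lat$t_mid, config)
  th <- slope_noise_theory(mean(true_slope), win_s, config$sample_interval, config$noise_sd)
  obs <- true_slope + rnorm(length(true_slope), 0, th$se_h)
  beta_s <- true_slope / 3600
  r2th <- if (config$noise_sd > 0)
    beta_s^2 * th$vt / (beta_s^2 * th$vt + config$noise_sd^2) else rep(1, length(beta_s))
  r2 <- if (config$noise_sd > 0)
    pmax(0, 1 - (1 - r2th) * rchisq(length(r2th), th$n - 2) / (th$n - 2)) else r2th
  fishcyc <- data.table::data.table(
    chamber_id = fish$chamber_id, phase = "measure", cycle_index = lat$cycle_index,
    t_mid = lat$t_mid, slope = obs, intercept = NA_real_, r2 = r2, n_points = th$n)

  # blank cycles at both ends (no fish): slope = background only
  nb <- config$n_blank_cycles
  fish_end <- config$n_cycles * config$cycle_s
  bmid <- c(-(nb:1) * config$cycle_s, fish_end + (seq_len(nb) - 1) * config$cycle_s) +
    config$cycle_flush + config$mix_carryover_s + win_s / 2
  bslope <- sim_background_slope(bmid, config) + rnorm(2 * nb, 0, th$se_h)
  blanks <- data.table::data.table(
    chamber_id = fish$chamber_id, phase = "blank",
    cycle_index = c(-(nb:1), config$n_cycles + seq_len(nb)),
    t_mid = bmid, slope = bslope, intercept = NA_real_, r2 = 1, n_points = th$n)

  # post-chase MMR: max 180-s rolling mean of the latent rate in the first
  # post-chase measurement cycle, plus slope-level noise mapped to rate units
  first_cyc <- ceiling(schedule_row$chase_s / config$cycle_s) + 1L
  tg <- seq((first_cyc - 1) * config$cycle_s + config$cycle_flush + config$mix_carryover_s,
            (first_cyc - 1) * config$cycle_s + config$cycle_s - 1, by = 5)
  rr <- instantaneous_mo2(fish, pmin(tg, config$trial_s), schedule_row, config, trial, bursts)
  w <- 180 / 5
  cs <- cumsum(c(0, rr))
  roll <- (cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]) / w
  th180 <- slope_noise_theory(mean(-rr * (mass_g / 1000) / v_eff), 180,
                              config$sample_interval, config$noise_sd)
  mmr_noise_rate <- th180$se_h * v_eff / (mass_g / 1000)
  mmr <- data.table::data.table(
    chamber_id = fish$chamber_id, trial = trial,
    mmr = max(roll) + rnorm(1, 0, mmr_noise_rate), r2 = th180$r2)
  list(slopes = rbind(fishcyc, blanks), mmr = mmr)
}

# ---- public entry points ----------------------------------------------------

#' Simulate one respirometry trial for a cohort
#'
#' For every chamber, evolves dissolved oxygen by forward-difference
#' integration of the latent uptake model (closed measurement phases decline
#' linearly; flush phases relax exponentially toward the saturated inflow with
#' a 30 s time constant that carries 30 s into each measurement phase, the
#' "mixing tail"), adds linear microbial background drift and Gaussian sensor
#' noise, and flanks the fish period with blank (empty-chamber) cycles at both
#' ends. `output = "slopes"` is a fast path for large replicate studies that
#' draws the per-cycle slope fits directly from the same latent model using
#' OLS sampling theory, bypassing the 1 Hz trace.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a [sim_config()].
#' @param trial `"initial"` or `"final"`.
#' @param schedule optional pre-built [build_schedule()] table.
#' @param output `"trace"` (raw O2 samples) or `"slopes"` (per-cycle fits).
#' @param chambers optional subset of chamber ids to simulate.
#' @param noise add sensor noise? (`FALSE` gives the noiseless trace used by
#'   recovery tests).
#' @return for `"trace"`: list(trace, schedule); for `"slopes"`:
#'   list(slopes, mmr, schedule).
#' @export
simulate_trial <- function(cohort, config, trial = "initial", schedule = NULL,
                           output = c("trace", "slopes"), chambers = NULL,
                           noise = TRUE) {
  output <- match.arg(output)
  fish <- cohort$fish
  if (!is.null(chambers)) fish <- fish[fish$chamber_id %in% chambers, ]
  if (nrow(fish) == 0L) stop("no chambers to simulate")
  if (is.null(schedule)) schedule <- build_schedule(cohort, config, trial)
  out <- vector("list", nrow(fish)); mmr_out <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    f <- fish[i, ]
    sr <- schedule[schedule$chamber_id == f$chamber_id, ]
    if (nrow(sr) != 1L) stop("schedule must have exactly one row per chamber")
    bursts <- draw_bursts(f, config, substream_seed(config$seed, paste0("bursts-", trial, "-", f$chamber_id)))
    set.seed(substream_seed(config$seed, paste0("noise-", trial, "-", f$chamber_id)))
    if (output == "trace") {
      out[[i]] <- sim_chamber_trace(f, sr, config, trial, bursts, noise = noise)
    } else {
      sl <- sim_chamber_slopes(f, sr, config, trial, bursts)
      out[[i]] <- sl$slopes; mmr_out[[i]] <- sl$mmr
    }
  }
  if (output == "trace")
    list(trace = data.table::rbindlist(out), schedule = schedule)
  else
    list(slopes = data.table::rbindlist(out), mmr = data.table::rbindlist(mmr_out),
         schedule = schedule)
}

#' Simulate a full experiment and write its CSV artifacts
#'
#' Generates the cohort, both trial schedules, and both trials' data (raw
#' traces or slope-level fast path), writing `metadata.csv`,
#' `ground_truth.csv`, `schedule.csv`, and per-trial `raw_trace_<trial>.csv`
#' (or `slope_fits_<trial>.csv` + `mmr_latent_<trial>.csv`).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param output `"trace"` or `"slopes"`.
#' @return invisibly, a list with the in-memory tables and file paths.
#' @export
simulate_experiment <- function(config = sim_config(), dir, output = c("trace", "slopes")) {
  output <- match.arg(output)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  sched <- rbind(build_schedule(cohort, config, "initial"),
                 build_schedule(cohort, config, "final"))
  meta <- cohort$fish[, c("fish_id", "batch", "chamber_id", "tank_id", "group_size",
                          "shelter_available", "mass_initial_g", "mass_final_g")]
  truth <- data.table::copy(cohort$fish)
  for (tr in c("initial", "final")) {
    sr <- sched[sched$trial == tr, ]
    truth[[paste0("smr_realized_", tr)]] <- vapply(seq_len(nrow(truth)), function(i)
      realized_smr(truth[i, ], sr[sr$chamber_id == truth$chamber_id[i], ], config, tr),
      numeric(1))
  }
  data.table::fwrite(meta, file.path(dir, "metadata.csv"))
  data.table::fwrite(truth, file.path(dir, "ground_truth.csv"))
  data.table::fwrite(sched, file.path(dir, "schedule.csv"))
  sims <- list()
  for (tr in c("initial", "final")) {
    sim <- simulate_trial(cohort, config, tr, schedule = sched[sched$trial == tr, ],
                          output = output)
    if (output == "trace") {
      data.table::fwrite(sim$trace, file.path(dir, paste0("raw_trace_", tr, ".csv")))
    } else {
      data.table::fwrite(sim$slopes, file.path(dir, paste0("slope_fits_", tr, ".csv")))
      data.table::fwrite(sim$mmr, file.path(dir, paste0("mmr_latent_", tr, ".csv")))
    }
    sims[[tr]] <- sim
  }
  invisible(list(config = config, cohort = cohort, schedule = sched, sims = sims, dir = dir))
}
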