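# End-to-end orchestration: simulate -> per-cycle MO2 -> traits -> inference,
# with a round-trippable run configuration and machine-readable report.

#' Build and validate a pipeline run configuration
#'
#' @param mode `"simulate"` (generate data, then analyze) or `"analyze"`
#'   (start from existing CSVs given in `paths`).
#' @param out_dir run directory for all outputs.
#' @param seed master seed; every random draw in the run derives from it.
#' @param sim named list of overrides passed to [sim_config()].
#' @param sim_output `"trace"` or `"slopes"` (generator fast path).
#' @param q MO2min quantile in \[0, 1\].
#' @param r2_min QC threshold in \[0, 1\].
#' @param min_cycles minimum QC-passed cycles per valid window.
#' @param exclude_initial_s seconds excluded at measure-phase start.
#' @param mmr_window_s rolling MMR regression window (s).
#' @param mmr_cycles post-chase cycles scanned for MMR.
#' @param alpha backward-elimination threshold.
#' @param adjusted,mass_covariate,chi2_type passed to [run_stats()].
#' @param reference_mass g, for mass adjustment.
#' @param b_fixed optional fixed scaling exponent.
#' @param chamber_volume litres.
#' @param growth_days days between weighings.
#' @param paths named list for analyze mode: `raw_initial`, `raw_final` (trace
#'   CSVs) or `slopes_initial`/`slopes_final` (+ optional `mmr_initial`/
#'   `mmr_final`), plus `schedule`, `meta`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "analyze"), out_dir = tempfile("rtrun"),
                       seed = 1L, sim = list(), sim_output = c("trace", "slopes"),
                       q = 0.2, r2_min = 0.95, min_cycles = 10,
                       exclude_initial_s = 30, mmr_window_s = 180, mmr_cycles = 1,
                       alpha = 0.05, adjusted = TRUE, mass_covariate = FALSE,
                       chi2_type = c("LRT", "Wald"), reference_mass = 1.95,
                       b_fixed = NULL, chamber_volume = 0.100, growth_days = 21,
                       paths = list()) {
  cfg <- list(mode = match.arg(mode), out_dir = out_dir, seed = as.integer(seed),
              sim = sim, sim_output = match.arg(sim_output), q = q,
              r2_min = r2_min, min_cycles = min_cycles,
              exclude_initial_s = exclude_initial_s, mmr_window_s = mmr_window_s,
              mmr_cycles = mmr_cycles, alpha = alpha, adjusted = adjusted,
              mass_covariate = mass_covariate, chi2_type = match.arg(chi2_type),
              reference_mass = reference_mass, b_fixed = b_fixed,
              chamber_volume = chamber_volume, growth_days = growth_days,
              paths = paths)
  stopifnot_scalar(cfg$q, "q", 0, 1)
  stopifnot_scalar(cfg$r2_min, "r2_min", 0, 1)
  stopifnot_scalar(cfg$alpha, "alpha", 0, 1)
  stopifnot_scalar(cfg$min_cycles, "min_cycles", 1)
  stopifnot_scalar(cfg$mmr_window_s, "mmr_window_s", 1)
  stopifnot_scalar(cfg$exclude_initial_s, "exclude_initial_s", 0)
  stopifnot_scalar(cfg$reference_mass, "reference_mass", 1e-3)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (lossless JSON round trip)
#' @param cfg a `run_config`; `path` a file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$sim <- as.list(raw$sim)
  raw$paths <- as.list(raw$paths)
  do.call(run_config, raw)
}

rt_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> per-cycle MO2 estimation -> trait
#' aggregation -> mixed-model inference, writing `mo2_estimates.csv`,
#' `mmr_estimates.csv`, `traits.csv`, `mo2min_long.csv`, `model_table.csv`,
#' `effects.csv`, a rejection log, a structured run log, and `report.json`
#' (QC counts, trait summaries, SGR test, model tables) under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all intermediate tables and results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  res <- list(config = config)

  if (config$mode == "simulate") {
    rt_log(logf, "stage simulate: seed ", config$seed, ", output ", config$sim_output)
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_experiment(scfg, file.path(config$out_dir, "sim"),
                               output = config$sim_output)
    res$sim <- sim
    schedule <- sim$schedule
    meta <- sim$cohort$fish
    get_trial <- function(tr) sim$sims[[tr]]
  } else {
    rt_log(logf, "stage ingest: reading CSV inputs")
    p <- config$paths
    if (is.null(p$schedule) || is.null(p$meta)) stop("analyze mode needs paths$schedule and paths$meta")
    schedule <- data.table::fread(p$schedule)
    meta <- data.table::fread(p$meta)
    get_trial <- function(tr) {
      if (!is.null(p[[paste0("raw_", tr)]]))
        list(trace = data.table::fread(p[[paste0("raw_", tr)]]))
      else if (!is.null(p[[paste0("slopes_", tr)]]))
        list(slopes = data.table::fread(p[[paste0("slopes_", tr)]]),
             mmr = if (!is.null(p[[paste0("mmr_", tr)]]))
               data.table::fread(p[[paste0("mmr_", tr)]]))
      else stop("analyze mode needs paths$raw_", tr, " or paths$slopes_", tr)
    }
  }

  # ---- per-cycle MO2 + MMR --------------------------------------------------
  est_all <- list(); mmr_all <- list()
  trials <- intersect(c("initial", "final"), unique(schedule$trial))
  for (tr in trials) {
    dat <- get_trial(tr)
    sched_tr <- schedule[schedule$trial == tr, ]
    if (!is.null(dat$trace)) {
      rt_log(logf, "stage mo2 (", tr, "): fitting slopes from trace")
      slopes <- fit_all_slopes(dat$trace, exclude_initial_s = config$exclude_initial_s)
      est <- estimates_from_trace(slopes = slopes, schedule = sched_tr, meta = meta,
                                  trial = tr, chamber_volume = config$chamber_volume,
                                  r2_min = config$r2_min,
                                  exclude_initial_s = config$exclude_initial_s)
      mass_col <- if (tr == "final") "mass_final_g" else "mass_initial_g"
      trace_dt <- data.table::as.data.table(dat$trace)
      mmr <- lapply(seq_len(nrow(meta)), function(i) {
        ch <- meta$chamber_id[i]
        bl <- slopes[slopes$chamber_id == ch & slopes$phase == "blank", ]
        mid <- mean(range(bl$t_mid))
        bg <- estimate_background(bl[bl$t_mid < mid, ], bl[bl$t_mid >= mid, ],
                                  n_required = nrow(bl) / 2)
        sr <- sched_tr[sched_tr$chamber_id == ch, ]
        data.frame(fish_id = meta$fish_id[i], trial = tr,
                   mmr = compute_mmr(trace_dt[chamber_id == ch], bg,
                                     config$chamber_volume, meta[[mass_col]][i],
                                     chase_s = sr$chase_s,
                                     window_s = config$mmr_window_s,
                                     cycles_considered = config$mmr_cycles,
                                     exclude_initial_s = config$exclude_initial_s))
      })
      mmr_all[[tr]] <- do.call(rbind, mmr)
    } else {
      rt_log(logf, "stage mo2 (", tr, "): using slope-level input")
      est <- estimates_from_trace(slopes = dat$slopes, schedule = sched_tr,
                                  meta = meta, trial = tr,
                                  chamber_volume = config$chamber_volume,
                                  r2_min = config$r2_min,
                                  exclude_initial_s = config$exclude_initial_s)
      if (!is.null(dat$mmr)) {
        mm <- merge(as.data.frame(dat$mmr), meta[, c("fish_id", "chamber_id")],
                    by = "chamber_id")
        mmr_all[[tr]] <- mm[, c("fish_id", "trial", "mmr")]
      }
    }
    est_all[[tr]] <- est
  }
  estimates <- data.table::rbindlist(est_all)
  mmr_table <- if (length(mmr_all)) do.call(rbind, mmr_all) else NULL
  data.table::fwrite(estimates, file.path(config$out_dir, "mo2_estimates.csv"))
  if (!is.null(mmr_table))
    data.table::fwrite(mmr_table, file.path(config$out_dir, "mmr_estimates.csv"))
  rejected <- estimates[estimates$qc_pass == FALSE, ]
  data.table::fwrite(rejected, file.path(config$out_dir, "qc_rejections.csv"))
  rt_log(logf, "stage mo2: ", nrow(estimates), " estimates, ", nrow(rejected),
         " rejected by QC")

  # ---- traits ---------------------------------------------------------------
  rt_log(logf, "stage traits: windows + quantile minima")
  windows <- data.table::rbindlist(
    lapply(trials, function(tr) build_windows(schedule[schedule$trial == tr, ])))
  tt <- compute_traits(estimates, windows, meta, mmr_table = mmr_table,
                       q = config$q, min_cycles = config$min_cycles,
                       reference_mass = config$reference_mass,
                       b_fixed = config$b_fixed, growth_days = config$growth_days)
  data.table::fwrite(tt$traits, file.path(config$out_dir, "traits.csv"))
  data.table::fwrite(tt$mo2min_long, file.path(config$out_dir, "mo2min_long.csv"))
  res$traits <- tt

  # ---- stats ----------------------------------------------------------------
  rt_log(logf, "stage stats: mixed models (", config$chi2_type, ")")
  st <- run_stats(tt$traits, tt$mo2min_long, adjusted = config$adjusted,
                  mass_covariate = config$mass_covariate, alpha = config$alpha,
                  type = config$chi2_type)
  data.table::fwrite(st$model_table, file.path(config$out_dir, "model_table.csv"))
  data.table::fwrite(st$effects, file.path(config$out_dir, "effects.csv"))
  res$stats <- st

  report <- list(
    seed = config$seed, mode = config$mode,
    qc = list(n_estimates = nrow(estimates), n_rejected = nrow(rejected),
              reject_reasons = as.list(table(rejected$reject_reason))),
    counts = list(n_fish = length(unique(estimates$fish_id)),
                  n_mo2min = sum(tt$mo2min_long$valid),
                  n_mo2min_night = sum(tt$mo2min_long$valid &
                                         tt$mo2min_long$photoperiod == "night"),
                  n_mo2min_day = sum(tt$mo2min_long$valid &
                                       tt$mo2min_long$photoperiod == "day"),
                  n_smr = sum(tt$traits$smr_valid),
                  n_mmr = sum(tt$traits$mmr_valid)),
    trait_summary = lapply(list(smr = tt$traits$smr, mmr = tt$traits$mmr,
                                aerobic_scope = tt$traits$aerobic_scope,
                                sgr = tt$traits$sgr),
                           function(x) list(mean = mean(x, na.rm = TRUE),
                                            sd = stats::sd(x, na.rm = TRUE))),
    sgr_test = st$sgr_test[c("p", "r2_adj")],
    model_table = st$model_table, effects = st$effects)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  rt_log(logf, "done: outputs in ", config$out_dir)
  res$report <- report
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run` (simulate + analyze), `analyze`. A JSON
#' config written by [write_config()] can override every default.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly.
#' @export
respirotraits_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: respirotraits <simulate|run|analyze> [--config FILE] [--out DIR]\n",
        "  [--seed N] [--q 0.2] [--r2-min 0.95] [--exclude-initial-s 30]\n",
        "  [--sim-output trace|slopes] [--raw-initial F] [--raw-final F]\n",
        "  [--schedule F] [--meta F]\n")
    return(invisible(0L))
  }
  cmd <- args[1L]
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "rt_run"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--q", type = "double", default = 0.2),
    optparse::make_option("--r2-min", dest = "r2_min", type = "double", default = 0.95),
    optparse::make_option("--exclude-initial-s", dest = "exclude_initial_s",
                          type = "double", default = 30),
    optparse::make_option("--sim-output", dest = "sim_output", type = "character",
                          default = "trace"),
    optparse::make_option("--raw-initial", dest = "raw_initial", type = "character", default = NULL),
    optparse::make_option("--raw-final", dest = "raw_final", type = "character", default = NULL),
    optparse::make_option("--schedule", type = "character", default = NULL),
    optparse::make_option("--meta", type = "character", default = NULL))),
    args = args[-1L])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else {
    paths <- Filter(Negate(is.null),
                    list(raw_initial = opts$raw_initial, raw_final = opts$raw_final,
                         schedule = opts$schedule, meta = opts$meta))
    run_config(mode = if (cmd == "analyze") "analyze" else "simulate",
               out_dir = opts$out, seed = opts$seed, q = opts$q,
               r2_min = opts$r2_min, exclude_initial_s = opts$exclude_initial_s,
               sim_output = opts$sim_output, paths = paths)
  }
  if (cmd == "simulate") {
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    simulate_experiment(scfg, file.path(cfg$out_dir, "sim"), output = cfg$sim_output)
  } else if (cmd %in% c("run", "analyze")) {
    run_pipeline(cfg)
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
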