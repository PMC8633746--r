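# Cohort simulation: fish ground truth and social-treatment assignment.

#' Simulate a cohort of fish with ground-truth metabolic parameters
#'
#' Draws one fish per chamber for every batch, assigns batches (whole, by
#' default, mirroring the original design; or split evenly) to social groups of
#' 4 or 8 fish housed in 0.048 m^3 tanks with or without plant shelter, and
#' draws each fish's true standard and maximum metabolic rate, activity-burst
#' parameters, initial mass, and 3-week specific growth rate.
#'
#' Growth follows `mass_final = mass_initial * exp(SGR/100 * growth_days)` with
#' SGR drawn normally around the group-size-specific mean and clamped at
#' -0.1 %/day.
#'
#' @param config a [sim_config()].
#' @return list with elements `fish` (one row per fish: identity, batch,
#'   chamber, tank, treatment, masses, true SMR/MMR, burst parameters, true
#'   SGR) and `tanks` (tank-level treatment table with stocking density).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_batches = 1, chambers_per_batch = 4,
#'                                      batch_group_sizes = 4))
#' nrow(cohort$fish)  # 4
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  nb <- config$n_batches
  nc <- config$chambers_per_batch

  # tank layout
  sizes_by_batch <- if (identical(config$batch_group_sizes, "split")) {
    if (nc %% 8 != 0) stop("split assignment needs chambers_per_batch divisible by 8")
    lapply(seq_len(nb), function(b) c(rep(4, (nc / 2) / 4), rep(8, (nc / 2) / 8)))
  } else {
    lapply(seq_len(nb), function(b) rep(config$batch_group_sizes[b], nc / config$batch_group_sizes[b]))
  }

  tank_rows <- list(); fish_rows <- list()
  tank_counter <- 0L; fish_counter <- 0L
  tank_volume_m3 <- 0.048  # 40 x 40 x 30 cm

  sdlog <- sqrt(log(1 + config$smr_cv^2))
  meanlog <- log(config$smr_mean) - sdlog^2 / 2

  for (b in seq_len(nb)) {
    g_sizes <- sizes_by_batch[[b]]
    n_tanks_b <- length(g_sizes)
    shelter_avail <- rep(c(TRUE, FALSE), length.out = n_tanks_b)
    # alternate within each group size so both sizes see both shelter levels
    ord <- order(g_sizes)
    shelter_avail[ord] <- unlist(lapply(split(seq_along(ord), g_sizes[ord]), function(ix)
      rep(c(TRUE, FALSE), length.out = length(ix))), use.names = FALSE)

    tank_ids <- sprintf("t%02d", tank_counter + seq_len(n_tanks_b))
    tank_counter <- tank_counter + n_tanks_b
    tank_rows[[b]] <- data.table::data.table(
      tank_id = tank_ids, batch = b, group_size = as.integer(g_sizes),
      shelter_available = shelter_avail,
      density_fish_m3 = g_sizes / tank_volume_m3)

    # fish randomly allotted to the batch's tanks
    slot_tank <- sample(rep(seq_len(n_tanks_b), times = g_sizes))
    mass <- rnorm(nc, config$mass_mean, config$mass_sd)
    while (any(mass < 0.5)) mass[mass < 0.5] <- rnorm(sum(mass < 0.5), config$mass_mean, config$mass_sd)
    smr <- rlnorm(nc, meanlog, sdlog)
    grp <- as.integer(g_sizes[slot_tank])
    sgr <- pmax(rnorm(nc, config$sgr_mean_by_group[as.character(grp)], config$sgr_sd), -0.1)
    fish_rows[[b]] <- data.table::data.table(
      fish_id = sprintf("f%03d", fish_counter + seq_len(nc)),
      batch = b,
      chamber_id = sprintf("b%dc%02d", b, seq_len(nc)),
      tank_id = tank_ids[slot_tank],
      group_size = grp,
      shelter_available = shelter_avail[slot_tank],
      mass_initial_g = mass,
      sgr_true = sgr,
      mass_final_g = mass * exp(sgr / 100 * config$growth_days),
      true_smr = smr,
      true_mmr = smr * config$mmr_multiplier,
      activity_event_rate = config$activity_event_rate * runif(nc, 0.75, 1.25),
      activity_decay = config$activity_decay)
    fish_counter <- fish_counter + nc
  }
  list(fish = data.table::rbindlist(fish_rows), tanks = data.table::rbindlist(tank_rows))
}
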