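# Shared fixtures, built in code. Heavy objects are memoized for the session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# one batch of four fish, full-length trial
small_cfg <- function(...) {
  sim_config(n_batches = 1, chambers_per_batch = 4, batch_group_sizes = 4, ...)
}

# two batches, both group sizes and shelter levels represented
mixed_cfg <- function(...) {
  sim_config(n_batches = 2, chambers_per_batch = 16, batch_group_sizes = c(4, 8), ...)
}

# hand-built trace: alternating flush/measure cycles at 1 Hz with prescribed
# per-cycle O2 slopes (per hour); linear decline within each measure phase
make_linear_trace <- function(slopes_h, chamber = "c1", flush_s = 120,
                              measure_s = 300, o2_top = 9.5, noise = 0,
                              phase_label = "measure", t0 = 0) {
  rows <- list()
  t <- t0
  for (i in seq_along(slopes_h)) {
    tf <- seq(t, t + flush_s - 1)
    tm <- seq(t + flush_s, t + flush_s + measure_s - 1)
    o2m <- o2_top + slopes_h[i] * (tm - tm[1]) / 3600
    rows[[i]] <- data.frame(
      time_s = c(tf, tm),
      chamber_id = chamber,
      phase = c(rep("flush", length(tf)), rep(phase_label, length(tm))),
      cycle_index = i,
      o2_mg_per_l = c(rep(o2_top, length(tf)), o2m))
    t <- t + flush_s + measure_s
  }
  tr <- do.call(rbind, rows)
  if (noise > 0) tr$o2_mg_per_l <- tr$o2_mg_per_l + rnorm(nrow(tr), 0, noise)
  tr
}

# independent normal-equations OLS oracle (matrix algebra, not lm, not the
# package's cov/var route)
ols_oracle <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope_s = beta[2], r2 = r2)
}

# brute-force order-statistic quantile oracle for the (n-1)-spacing convention
quantile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# memoized small trace-level experiment used by several files
fx_small_sim <- function() memo("small_sim", {
  cfg <- small_cfg(seed = 101, sample_interval = 2)
  cohort <- simulate_cohort(cfg)
  sim <- simulate_trial(cohort, cfg, "initial")
  list(cfg = cfg, cohort = cohort, sim = sim)
})

# memoized fast-path pipeline run with the full treatment structure
fx_pipeline_run <- function() memo("pipeline_run", {
  dir <- file.path(tempdir(), "fxrun")
  cfg <- run_config(mode = "simulate", out_dir = dir, seed = 2024,
                    sim_output = "slopes",
                    sim = list(n_batches = 2, chambers_per_batch = 16,
                               batch_group_sizes = c(4, 8)))
  run_pipeline(cfg)
})
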