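# metabolic_traits: windows, quantile minima, SMR/MMR/AS, scaling, SGR

mk_sched <- function(shelter_first = 0L, cond_h = 21, chase_h = 43,
                     start = "15:30") {
  data.frame(chamber_id = "c1", trial = "initial", shelter_first = shelter_first,
             condition_change_s = cond_h * 3600, chase_s = chase_h * 3600,
             lights_on = "07:00", lights_off = "19:00", start_clock = start)
}

test_that("build_windows: clock arithmetic and window structure", {
  w <- build_windows(mk_sched())
  expect_equal(nrow(w), 4L)
  expect_equal(sum(w$photoperiod == "night"), 2L)
  expect_equal(sum(w$photoperiod == "day"), 2L)
  # entry 15:30 -> acclimation ends 20:30; first lights-on 07:00 = 55800 s
  n1 <- w[w$photoperiod == "night" & w$trial_day == 1, ]
  expect_equal(n1$start_s, 5 * 3600)                 # 20:30
  expect_equal(n1$end_s, 15.5 * 3600)                # 07:00 next day
  d1 <- w[w$photoperiod == "day" & w$trial_day == 1, ]
  expect_equal(c(d1$start_s, d1$end_s), c(55800, 75600))
  # condition change at 13:30 (22 h offset) -> night-2 starts 18:30
  w2 <- build_windows(mk_sched(cond_h = 22))
  n2 <- w2[w2$photoperiod == "night" & w2$trial_day == 2, ]
  expect_equal((15.5 * 3600 + n2$start_s) %% 86400, 18.5 * 3600)
  # shelter labeling follows the trial half
  ws <- build_windows(mk_sched(shelter_first = 1L))
  expect_equal(ws$shelter_on, c(TRUE, TRUE, FALSE, FALSE))
  # chase before the second lights-on drops the day-2 window
  expect_warning(wt <- build_windows(mk_sched(chase_h = 38)), "chase")
  expect_equal(nrow(wt), 3L)
})

test_that("mo2min_quantile: oracle, monotonicity, invariances, validity", {
  expect_equal(mo2min_quantile(rep(7.5, 12), q = 0.2), 7.5)
  expect_equal(mo2min_quantile(rep(7.5, 12), q = 0.9), 7.5)
  expect_equal(mo2min_quantile(1:10, q = 0.2), quantile_oracle(1:10, 0.2))
  set.seed(12)
  for (q in c(0, 0.2, 0.37, 0.8, 1)) {
    x <- rlnorm(25, 5, 0.3)
    expect_equal(mo2min_quantile(x, q = q), quantile_oracle(x, q))
    expect_equal(mo2min_quantile(sample(x), q = q), mo2min_quantile(x, q = q))
  }
  x <- rlnorm(40, 5, 0.3)
  qs <- vapply(seq(0, 1, 0.1), function(q) mo2min_quantile(x, q = q), numeric(1))
  expect_true(all(diff(qs) >= 0))                    # monotone in q
  expect_equal(mo2min_quantile(x, q = 0), min(x))
  expect_true(is.na(mo2min_quantile(rnorm(9), min_cycles = 10)))
})

test_that("compute_smr and compute_as behave as stated", {
  expect_equal(compute_smr(c(100, 90, 95, 110)), 90)
  expect_equal(compute_smr(42), 42)
  expect_equal(compute_smr(c(NA, 80, NA)), 80)
  expect_true(is.na(compute_smr(c(NA_real_, NA_real_))))
  set.seed(3); v <- runif(4, 50, 150)
  expect_equal(compute_smr(v), compute_smr(rev(v)))
  expect_equal(compute_as(300, 100), 200)
  expect_equal(compute_as(100, 100), 0)
  expect_true(is.na(compute_as(300, NA_real_)))
})

test_that("compute_mmr: constant decline equals whole-cycle estimate", {
  tr <- make_linear_trace(rep(-6, 2), t0 = 10 * 420)
  mmr <- compute_mmr(tr, zero_background(), 0.1, 2.0, chase_s = 10 * 420)
  whole <- -(-6) * (0.1 - 0.002) / 0.002
  expect_equal(mmr, whole, tolerance = 1e-9)
  # no post-chase cycle -> invalid
  expect_true(is.na(compute_mmr(tr, zero_background(), 0.1, 2, chase_s = 12 * 420)))
})

test_that("compute_mmr equals the exhaustive lm-window oracle on a spike-decay trace", {
  # O2 decline whose slope decays after the chase: curvature makes window
  # placement matter
  set.seed(21)
  t0 <- 10 * 420
  tm <- seq(t0 + 120, t0 + 419)
  rate <- 400 * 2^(-(tm - t0) / 600) + 80
  o2 <- 9.8 - cumsum(rate * 0.002 / 0.098 / 3600) + rnorm(300, 0, 0.002)
  tr <- rbind(data.frame(time_s = seq(t0, t0 + 119), chamber_id = "c1",
                         phase = "flush", cycle_index = 11L, o2_mg_per_l = 9.8),
              data.frame(time_s = tm, chamber_id = "c1", phase = "measure",
                         cycle_index = 11L, o2_mg_per_l = o2))
  got <- compute_mmr(tr, zero_background(), 0.1, 2.0, chase_s = t0, window_s = 180)

  # oracle: every contiguous 180 s window of the trimmed phase, via lm()
  tt <- tm[tm >= t0 + 150]; yy <- o2[tm >= t0 + 150]
  cand <- c()
  for (i in seq_len(length(tt))) {
    j <- which(tt - tt[i] <= 180)
    j <- j[j >= i]
    if (tt[max(j)] - tt[i] < 179) break
    sl <- unname(coef(lm(yy[i:max(j)] ~ tt[i:max(j)]))[2]) * 3600
    cand <- c(cand, -sl * 0.098 / 0.002)
  }
  expect_equal(got, max(cand), tolerance = 1e-8)
  # scanning more cycles can never reduce MMR
  tr2 <- rbind(tr, make_linear_trace(-3, t0 = 11 * 420))
  tr2$cycle_index[tr2$time_s >= 11 * 420] <- 12L
  m1 <- compute_mmr(tr2, zero_background(), 0.1, 2.0, chase_s = t0, cycles_considered = 1)
  m8 <- compute_mmr(tr2, zero_background(), 0.1, 2.0, chase_s = t0, cycles_considered = 8)
  expect_gte(m8, m1)
})

test_that("estimate_scaling_exponent: exact, isometric, noisy recovery", {
  mass <- seq(0.8, 3.5, length.out = 12)
  expect_equal(estimate_scaling_exponent(mass, 2.3 * mass^0.8)$b, 0.8, tolerance = 1e-12)
  expect_equal(estimate_scaling_exponent(mass, 5 * mass)$b, 1, tolerance = 1e-12)
  set.seed(31)
  m80 <- rlnorm(80, log(1.95), 0.28)
  mo2 <- 2 * m80^0.85 * exp(rnorm(80, 0, 0.15))
  expect_lt(abs(estimate_scaling_exponent(m80, mo2)$b - 0.85), 0.1)
  expect_error(estimate_scaling_exponent(c(1, 2), c(1, 2)), "at least 3")
  expect_error(estimate_scaling_exponent(c(1, 2, -1), c(1, 2, 3)), "positive")
})

test_that("mass_adjust: identities, arithmetic oracle, bijection/composition", {
  expect_equal(mass_adjust(123, mass = 1.95, mean_mass = 1.95, b = 0.8), 123)
  expect_equal(mass_adjust(123, mass = 0.7, mean_mass = 1.95, b = 1), 123)
  expect_equal(mass_adjust(10, mass = 1.00, mean_mass = 1.95, b = 0.8),
               10 * 1.95^(-0.2) * 1.00^0.2, tolerance = 1e-12)
  # adjust to m1 then m1 -> m2 equals adjusting to m2 directly
  set.seed(5)
  mo2 <- runif(10, 80, 300); mass <- runif(10, 0.7, 3.4)
  a1 <- mass_adjust(mo2, mass, 1.5, b = 0.85)
  a12 <- mass_adjust(a1, 1.5, 2.2, b = 0.85)
  expect_equal(a12, mass_adjust(mo2, mass, 2.2, b = 0.85), tolerance = 1e-12)
  # bijection: round trip restores the input
  back <- mass_adjust(a1, 1.5, mean_mass = mass, b = 0.85)
  expect_equal(back, mo2, tolerance = 1e-12)
})

test_that("compute_sgr: exact forms and errors", {
  expect_equal(compute_sgr(2.0, 2.0, 21), 0)
  expect_equal(compute_sgr(1.5, 1.5 * exp(0.21), 21), 1.0, tolerance = 1e-12)
  expect_equal(compute_sgr(1.80, 2.05, 21), 100 * log(2.05 / 1.80) / 21,
               tolerance = 1e-12)
  expect_error(compute_sgr(1.8, 2.0, 0), "positive")
  expect_error(compute_sgr(-1, 2, 21))
})
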