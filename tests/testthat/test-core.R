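# respirometry_core: segmentation, slope fitting, background, MO2, QC

test_that("segment_cycles extracts, trims and drops windows", {
  tr <- make_linear_trace(c(-2, -2, -2))
  w30 <- segment_cycles(tr, exclude_initial_s = 30)
  expect_length(w30, 3L)
  expect_true(all(vapply(w30, function(w) diff(range(w$time_s)), numeric(1)) == 269))
  w0 <- segment_cycles(tr, exclude_initial_s = 0)
  expect_true(all(vapply(w0, nrow, integer(1)) == 300L))

  # truncated final cycle shorter than exclude + 60 s is dropped with a message
  tr_tr <- rbind(tr, within(make_linear_trace(-2, t0 = 3 * 420), cycle_index <- 4L)[1:200, ])
  expect_message(w <- segment_cycles(tr_tr, exclude_initial_s = 30), "dropped 1")
  expect_length(w, 3L)

  # a 150 s measure window (>= 90 s rule) survives
  tr_ok <- rbind(tr, within(make_linear_trace(-2, t0 = 3 * 420), cycle_index <- 4L)[1:270, ])
  expect_length(segment_cycles(tr_ok), 4L)
})

test_that("fit_slope: exact line, degenerate conventions, errors", {
  t <- 0:299
  w <- data.frame(time_s = t, o2_mg_per_l = 9.0 - 2.0 * t / 3600)
  f <- fit_slope(w)
  expect_equal(f$slope, -2.0, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$n_points, 300L)

  flat <- fit_slope(data.frame(time_s = t, o2_mg_per_l = rep(8, 300)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  expect_error(fit_slope(data.frame(time_s = 1, o2_mg_per_l = 9)), "2 samples")
  expect_error(fit_slope(data.frame(time_s = c(5, 5), o2_mg_per_l = c(9, 8))),
               "time variance")
})

test_that("fit_slope matches the normal-equations oracle to 1e-10 relative", {
  set.seed(4711)
  for (rep in 1:5) {
    t <- seq(30, 299)
    y <- 9.4 - runif(1, 0.5, 4) * t / 3600 + rnorm(length(t), 0, 0.01)
    f <- fit_slope(data.frame(time_s = t, o2_mg_per_l = y))
    o <- ols_oracle(t, y)
    expect_equal(f$slope, o$slope_s * 3600, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("fit_all_slopes equals per-window fit_slope on a noisy fixture", {
  set.seed(99)
  tr <- make_linear_trace(runif(6, -4, -1), noise = 0.01)
  fast <- fit_all_slopes(tr, exclude_initial_s = 30)
  wins <- segment_cycles(tr, exclude_initial_s = 30)
  slow <- do.call(rbind, lapply(wins, fit_slope))
  expect_equal(nrow(fast), 6L)
  expect_equal(fast$slope, slow$slope, tolerance = 1e-12)
  expect_equal(fast$r2, slow$r2, tolerance = 1e-12)
  expect_equal(fast$t_mid, slow$t_mid)
})

test_that("estimate_background: anchors, interpolation, clamping, errors", {
  mk <- function(slopes, t_mids) data.frame(slope = slopes, t_mid = t_mids)
  bg_const <- estimate_background(mk(rep(-0.05, 3), c(-900, -500, -100)),
                                  mk(rep(-0.05, 3), c(161800, 162200, 162600)))
  expect_equal(background_at(bg_const, c(0, 5e4, 1.5e5)), rep(-0.05, 3))

  bg <- estimate_background(mk(rep(0, 3), c(-100, 0, 100)),
                            mk(rep(-0.2, 3), c(9e4 - 100, 9e4, 9e4 + 100)))
  expect_equal(background_at(bg, 4.5e4), -0.1)          # midpoint of the line
  expect_equal(background_at(bg, -5e3), 0)              # clamped before start
  expect_equal(background_at(bg, 2e5), -0.2)            # clamped after end

  expect_error(estimate_background(mk(0, 0), mk(rep(0, 3), 1:3)), "exactly 3")
  expect_equal(background_at(zero_background(), c(0, 1e5)), c(0, 0))
})

test_that("compute_mo2: arithmetic oracle, flagging, limits", {
  fits <- data.frame(slope = -2.0, t_mid = 1000, r2 = 1, n_points = 270)
  est <- compute_mo2(fits, zero_background(), chamber_volume = 0.100, fish_mass = 2.0)
  expect_equal(est$mo2_abs, 2.0 * 0.098, tolerance = 1e-12)      # 0.196 mg O2/h
  expect_equal(est$mo2_mass_specific, 98.0, tolerance = 1e-12)   # mg O2/kg/h

  # slope equal to background -> zero, and QC flags it (not > 0 is fine; rule
  # rejects only negative; a zero rate passes r2 but is kept)
  bg <- estimate_background(data.frame(slope = rep(-2, 3), t_mid = 1:3),
                            data.frame(slope = rep(-2, 3), t_mid = 4:6))
  est0 <- compute_mo2(fits, bg, 0.100, 2.0)
  expect_equal(est0$mo2_abs, 0)

  # mass -> 0 limit: mo2_abs -> -slope * chamber_volume
  lim <- compute_mo2(fits, zero_background(), 0.100, 1e-9)
  expect_equal(lim$mo2_abs, 0.2, tolerance = 1e-6)

  expect_error(compute_mo2(fits, zero_background(), 0.100, 150), "volume")
})

test_that("qc_filter: strict threshold, counting, idempotence, partition", {
  est <- data.frame(r2 = c(1, 1, 1), mo2_mass_specific = c(1, 2, 3))
  expect_equal(nrow(qc_filter(est)$passed), 3L)

  # r2 = 0.95 exactly is rejected (strict inequality)
  border <- data.frame(r2 = 0.95, mo2_mass_specific = 1)
  expect_equal(nrow(qc_filter(border, r2_min = 0.95)$passed), 0L)
  expect_equal(qc_filter(border)$rejected$reject_reason, "low_r2")

  set.seed(1)
  mixed <- data.frame(r2 = c(runif(3, 0, 0.94), runif(7, 0.96, 1)),
                      mo2_mass_specific = runif(10, 50, 200))
  qc <- qc_filter(mixed, r2_min = 0.95)
  expect_equal(nrow(qc$passed), 7L)
  expect_equal(nrow(qc$rejected), 3L)
  # partition
  expect_setequal(c(qc$passed$mo2_mass_specific, qc$rejected$mo2_mass_specific),
                  mixed$mo2_mass_specific)
  # idempotence
  qc2 <- qc_filter(qc$passed, r2_min = 0.95)
  expect_equal(nrow(qc2$passed), nrow(qc$passed))
  expect_equal(nrow(qc2$rejected), 0L)
  # negative corrected rate rejected
  neg <- data.frame(r2 = 0.99, mo2_mass_specific = -5)
  expect_equal(qc_filter(neg)$rejected$reject_reason, "negative_rate")
})

test_that("background linearity: constant blank offset cancels exactly", {
  set.seed(7)
  slopes <- data.frame(slope = runif(20, -4, -1), t_mid = seq(1e3, 2e4, length.out = 20),
                       r2 = 1, n_points = 270)
  b <- -0.07
  bg0 <- zero_background()
  bgb <- estimate_background(data.frame(slope = rep(b, 3), t_mid = c(-900, -500, -100)),
                             data.frame(slope = rep(b, 3), t_mid = c(2.1e4, 2.2e4, 2.3e4)))
  est0 <- compute_mo2(slopes, bg0, 0.1, 1.95)
  shifted <- slopes; shifted$slope <- shifted$slope + b
  estb <- compute_mo2(shifted, bgb, 0.1, 1.95)
  expect_equal(estb$mo2_abs, est0$mo2_abs, tolerance = 1e-12)
})
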