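# treatment_stats: LMM fitting, term tests, reduction, R2, effect sizes, SGR

# balanced two-trial / two-condition dataset with known log-scale effects and
# variance components
gen_lmm_data <- function(n_fish = 40, sd_fish = 0.2, sd_batch = 0, sd_resid = 0.05,
                         beta_shelter = 0, beta_trial = 0, seed = 1) {
  set.seed(seed)
  n_batch <- max(2L, n_fish %/% 16L)
  fish <- sprintf("f%03d", seq_len(n_fish))
  batch <- rep(seq_len(n_batch), length.out = n_fish)
  u_f <- rnorm(n_fish, 0, sd_fish); u_b <- rnorm(n_batch, 0, sd_batch)
  g <- expand.grid(fish_id = fish, trial = c("initial", "final"),
                   shelter_on = c(FALSE, TRUE), stringsAsFactors = FALSE)
  g$batch <- batch[match(g$fish_id, fish)]
  g$.lp <- log(150) + u_f[match(g$fish_id, fish)] + u_b[g$batch] +
    beta_trial * (g$trial == "final") + beta_shelter * g$shelter_on +
    rnorm(nrow(g), 0, sd_resid)
  g$y <- exp(g$.lp)
  g$trial <- factor(g$trial, levels = c("initial", "final"))
  g
}

test_that("zero random variance: fixed effects match the OLS oracle", {
  d <- gen_lmm_data(n_fish = 30, sd_fish = 0, sd_batch = 0, sd_resid = 0.1,
                    beta_shelter = -0.08, seed = 2)
  m <- fit_lmm(d, "y", c("trial", "shelter_on"), random = "batch_nested")
  ols <- lm(log(y) ~ trial + shelter_on, data = d)
  expect_equal(unname(lme4::fixef(m$reml)), unname(coef(ols)), tolerance = 1e-6)
  expect_true(m$singular || m$fell_back)
})

test_that("fish-level variance separates conditional from marginal R2", {
  d <- gen_lmm_data(n_fish = 60, sd_fish = 0.3, sd_resid = 0.1,
                    beta_shelter = -0.1, seed = 3)
  m <- fit_lmm(d, "y", c("trial", "shelter_on"))
  r2 <- r2_nakagawa(m)
  expect_gt(r2[["r2_conditional"]], r2[["r2_marginal"]])
  expect_gte(r2[["r2_marginal"]], 0)
  expect_lte(r2[["r2_conditional"]], 1)
})

test_that("balanced two-group design: contrast equals the group mean difference", {
  set.seed(4)
  d <- data.frame(g = rep(c("a", "b"), each = 25), y = exp(rnorm(50, 5, 0.2)))
  m <- fit_lmm(d, "y", "g", random = "none")
  e <- effect_size_pct(m, "g", contrast = c("b", "a"))
  emp <- (exp(mean(log(d$y[d$g == "b"])) - mean(log(d$y[d$g == "a"]))) - 1) * 100
  expect_equal(e$pct, emp, tolerance = 1e-8)
})

test_that("LRT under the null is calibrated (rejection rate near alpha)", {
  set.seed(11)
  rej <- 0L
  for (i in 1:200) {
    d <- data.frame(x = rnorm(40), z = rnorm(40))
    d$y <- exp(0.5 * d$z + rnorm(40, 0, 0.3))
    m <- fit_lmm(d, "y", c("z", "x"), random = "none")
    p <- test_term(m, "x")[["p"]]
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej, qbinom(0.025, 200, 0.05))   # 4
  expect_lte(rej, qbinom(0.975, 200, 0.05))   # 17
})

test_that("a strong shelter effect is detected with high power", {
  hits <- 0L
  for (i in 1:25) {
    d <- gen_lmm_data(n_fish = 80, sd_fish = 0.25, sd_resid = 0.05,
                      beta_shelter = log(0.92), seed = 100 + i)
    m <- fit_lmm(d, "y", c("trial", "shelter_on"))
    hits <- hits + (test_term(m, "shelter_on")[["p"]] < 0.05)
  }
  expect_gte(hits, 20L)   # >= 80%
})

test_that("test_term respects marginality; Wald agrees in order of magnitude", {
  d <- gen_lmm_data(n_fish = 40, sd_fish = 0.2, beta_shelter = log(0.9), seed = 7)
  m <- fit_lmm(d, "y", c("trial", "shelter_on", "trial:shelter_on"))
  expect_error(test_term(m, "shelter_on", marginality = "strict"), "marginality")
  lrt <- test_term(m, "shelter_on")            # type-II: interaction stripped
  wald <- test_term(m, "shelter_on", type = "Wald")
  expect_equal(lrt[["df"]], 1)
  expect_equal(wald[["df"]], 1)
  expect_lt(abs(log10(lrt[["chi2"]] / wald[["chi2"]])), 0.5)
  expect_error(test_term(m, "mass_g"), "not in model")
})

test_that("backward_reduce keeps significant terms and sheds a noise covariate", {
  d <- gen_lmm_data(n_fish = 60, sd_fish = 0.2, sd_resid = 0.05,
                    beta_shelter = log(0.9), beta_trial = log(1.1), seed = 8)
  m <- fit_lmm(d, "y", c("trial", "shelter_on"))
  red <- backward_reduce(m, protected = character(0))
  expect_setequal(red$model$terms, c("trial", "shelter_on"))

  drops <- 0L
  for (i in 1:60) {
    set.seed(300 + i)
    d2 <- gen_lmm_data(n_fish = 30, sd_fish = 0, sd_resid = 0.15,
                       beta_shelter = log(0.8), seed = 300 + i)
    d2$noise <- rnorm(nrow(d2))
    m2 <- fit_lmm(d2, "y", c("shelter_on", "noise"), random = "none")
    red2 <- backward_reduce(m2, protected = "shelter_on")
    drops <- drops + !("noise" %in% red2$model$terms)
  }
  expect_gte(drops, 54L)   # >= 90%

  # elimination respects marginality: the interaction goes before its mains
  d3 <- gen_lmm_data(n_fish = 40, sd_fish = 0.2, seed = 9)
  m3 <- fit_lmm(d3, "y", c("trial", "shelter_on", "trial:shelter_on"))
  red3 <- backward_reduce(m3, protected = character(0))
  if (nrow(red3$trace) > 1)
    expect_equal(red3$trace$term[1], "trial:shelter_on")
})

test_that("r2_nakagawa: degenerate cases, constructed partition, rescaling", {
  d <- gen_lmm_data(n_fish = 40, sd_fish = 0, sd_resid = 0.2,
                    beta_shelter = log(0.8), seed = 10)
  # no random structure at all: conditional and marginal coincide exactly
  m_lm <- fit_lmm(d, "y", c("trial", "shelter_on"), random = "none")
  r2lm <- r2_nakagawa(m_lm)
  expect_equal(r2lm[["r2_conditional"]], r2lm[["r2_marginal"]])
  # mixed fit on fish-free data: spurious variance stays small, order preserved
  m <- fit_lmm(d, "y", c("trial", "shelter_on"))
  r2 <- r2_nakagawa(m)
  expect_gte(r2[["r2_conditional"]], r2[["r2_marginal"]])
  expect_lt(r2[["r2_conditional"]] - r2[["r2_marginal"]], 0.1)

  m0 <- fit_lmm(d, "y", "trial", random = "fish_only")   # trial effect ~ 0 here
  expect_lt(r2_nakagawa(m0)[["r2_marginal"]], 0.05)

  # known partition: fixed 0.2, fish 0.3, residual 0.5 of total
  set.seed(12)
  n <- 2000; fish <- rep(sprintf("f%04d", 1:500), each = 4)
  x <- rnorm(n, 0, sqrt(0.2))
  u <- rnorm(500, 0, sqrt(0.3))[match(fish, unique(fish))]
  y <- x + u + rnorm(n, 0, sqrt(0.5))
  dd <- data.frame(fish_id = fish, x = x, y = y)
  mm <- fit_lmm(dd, "y", "x", random = "fish_only", log_response = FALSE)
  r2p <- r2_nakagawa(mm)
  expect_lt(abs(r2p[["r2_marginal"]] - 0.2), 0.05)
  expect_lt(abs(r2p[["r2_conditional"]] - 0.5), 0.05)

  # invariant to rescaling the response by a constant
  dd$y7 <- dd$y * 7.3
  r2s <- r2_nakagawa(fit_lmm(dd, "y7", "x", random = "fish_only", log_response = FALSE))
  expect_equal(unname(r2s), unname(r2p), tolerance = 1e-6)
})

test_that("effect_size_pct: zero, forced +10%, antisymmetry, empty cells", {
  set.seed(13)
  d <- data.frame(g = rep(c("a", "b"), each = 20))
  d$y <- exp(5 + log(1.10) * (d$g == "b"))            # exact log-scale offset
  m <- fit_lmm(d, "y", "g", random = "none")
  e <- effect_size_pct(m, "g", contrast = c("b", "a"))
  expect_equal(e$pct, 10, tolerance = 1e-8)
  e0 <- effect_size_pct(m, "g", contrast = c("a", "a"))
  expect_equal(e0$pct, 0)
  # antisymmetry: (1 + e_ab/100) * (1 + e_ba/100) = 1
  eba <- effect_size_pct(m, "g", contrast = c("a", "b"))
  expect_equal((1 + e$pct / 100) * (1 + eba$pct / 100), 1, tolerance = 1e-10)

  # missing interaction cell is refused with a listing
  d2 <- expand.grid(g = c("a", "b"), h = c("x", "y"), stringsAsFactors = FALSE)
  d2 <- d2[rep(1:4, each = 5), ]; d2 <- d2[!(d2$g == "b" & d2$h == "y"), ]
  d2$y <- exp(rnorm(nrow(d2), 5, 0.1))
  m2 <- suppressMessages(fit_lmm(d2, "y", c("g", "h", "g:h"), random = "none"))
  expect_error(effect_size_pct(m2, "g"), "empty cells")
})

test_that("sgr_group_test: degenerate, separated, and paper-moment simulations", {
  d_eq <- data.frame(sgr = rep(c(0.4, 0.6), 10), group_size = rep(c(4, 8), each = 10))
  r <- sgr_group_test(d_eq)
  expect_gt(r$p, 0.95)
  expect_lte(r$r2_adj, 0)

  d_sep <- data.frame(sgr = c(rnorm(30, 0, 0.01), rnorm(30, 5, 0.01)),
                      group_size = rep(c(4, 8), each = 30))
  expect_lt(sgr_group_test(d_sep)$p, 1e-10)
  expect_error(sgr_group_test(data.frame(sgr = 1:5, group_size = 4)), "two group")

  # simulate from the published group moments: median adjusted R2 in [0.03, 0.15]
  set.seed(14)
  r2s <- replicate(200, {
    d <- data.frame(sgr = c(rnorm(32, 0.64, 0.27), rnorm(48, 0.50, 0.19)),
                    group_size = rep(c(4, 8), c(32, 48)))
    sgr_group_test(d)$r2_adj
  })
  expect_gt(median(r2s), 0.03)
  expect_lt(median(r2s), 0.15)
})
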