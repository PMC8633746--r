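# Treatment inference: nested linear mixed models, term-wise chi-square tests,
# backward reduction, marginal/conditional R-squared, and percentage effect
# sizes from equal-weight marginal means.

rt_formula <- function(terms, random) {
  rand <- switch(random,
                 batch_nested = "(1 | batch / fish_id)",
                 fish_only = "(1 | fish_id)",
                 stop("unknown random structure: ", random))
  rhs <- if (length(terms)) paste(c(terms, rand), collapse = " + ") else rand
  stats::as.formula(paste(".y ~", rhs))
}

rt_singular <- function(fit, tol = 1e-8) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- vc$vcov[vc$grp == "Residual"]
  any(vc$vcov[vc$grp != "Residual"] < tol * res)
}

#' Fit a linear mixed model for a trait response
#'
#' Gaussian LMM with random intercepts for fish nested in batch (or fish
#' only), fitted by REML for reporting and by ML for likelihood-ratio term
#' tests. The response is log-transformed by default. A singular REML fit
#' (a random-effect variance at zero) under the nested structure triggers a
#' fallback to the fish-only structure, which is recorded on the result.
#'
#' @param data data.frame of complete cases.
#' @param response name of the response column (must be positive when
#'   `log_response`).
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("trial", "shelter_on", "trial:shelter_on")`.
#' @param random `"batch_nested"`, `"fish_only"`, or `"none"` (plain `lm`,
#'   for degenerate designs).
#' @param log_response log-transform the response?
#' @return object of class `rt_lmm`: `reml`, `ml`, `terms`, `random`,
#'   `singular`, `fell_back`, `data`, `log_response`, `response`.
#' @export
fit_lmm <- function(data, response, fixed, random = "batch_nested",
                    log_response = TRUE) {
  d <- as.data.frame(data)
  vars <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  missing_vars <- setdiff(c(response, vars,
                            if (random != "none") "fish_id",
                            if (random == "batch_nested") "batch"), names(d))
  if (length(missing_vars)) stop("missing columns: ", paste(missing_vars, collapse = ", "))
  d <- d[stats::complete.cases(d[, c(response, vars)]), , drop = FALSE]
  for (v in vars) if (is.character(d[[v]]) || is.logical(d[[v]])) d[[v]] <- factor(d[[v]])
  for (v in vars) if (is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) < 2L)
    stop("fixed-effect factor '", v, "' has fewer than 2 levels")
  if (log_response && any(d[[response]] <= 0)) stop("log response requires positive values")
  d$.y <- if (log_response) log(d[[response]]) else d[[response]]
  if (random != "none") d$fish_id <- factor(d$fish_id)
  if (random == "batch_nested") d$batch <- factor(d$batch)

  fell_back <- FALSE
  if (random == "batch_nested" && nlevels(droplevels(d$batch)) < 2L) {
    random <- "fish_only"; fell_back <- TRUE   # a single batch carries no signal
  }
  if (random == "none") {
    f <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + ")))
    reml <- ml <- stats::lm(f, data = d)
    singular <- FALSE
  } else {
    reml <- lme4::lmer(rt_formula(fixed, random), data = d, REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE))
    if (random == "batch_nested" && rt_singular(reml)) {
      random <- "fish_only"; fell_back <- TRUE
      reml <- lme4::lmer(rt_formula(fixed, random), data = d, REML = TRUE,
                         control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE))
    }
    ml <- lme4::lmer(rt_formula(fixed, random), data = d, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE))
    singular <- rt_singular(reml)
  }
  structure(list(reml = reml, ml = ml, terms = fixed, random = random,
                 singular = singular, fell_back = fell_back, data = d,
                 log_response = log_response, response = response),
            class = "rt_lmm")
}

#' @export
print.rt_lmm <- function(x, ...) {
  cat("<rt_lmm>", if (x$log_response) paste0("log(", x$response, ")") else x$response,
      "~", paste(x$terms, collapse = " + "), "| random:", x$random,
      if (x$fell_back) "(fell back from batch_nested: singular)", "\n")
  r2 <- r2_nakagawa(x)
  cat(sprintf("  R2m = %.3f, R2c = %.3f, n = %d\n", r2[["r2_marginal"]],
              r2[["r2_conditional"]], nrow(x$data)))
  invisible(x)
}

refit_ml <- function(model, terms) {
  if (model$random == "none") {
    f <- stats::as.formula(paste(".y ~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
    return(stats::lm(f, data = model$data))
  }
  lme4::lmer(rt_formula(terms, model$random), data = model$data, REML = FALSE,
             control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE))
}

interactions_containing <- function(terms, main) {
  ints <- terms[grepl(":", terms, fixed = TRUE)]
  ints[vapply(strsplit(ints, ":", fixed = TRUE), function(p) main %in% p, logical(1))]
}

#' Likelihood-ratio (or Wald) chi-square test of one model term
#'
#' `type = "LRT"` compares ML fits with and without the term. Marginality is
#' respected: a main effect involved in interactions is tested type-II style,
#' i.e. in the model stripped of those interactions (or, with
#' `marginality = "strict"`, refused with an error). `type = "Wald"` is the
#' type-II Wald chi-square on the term's coefficients, offered for comparison
#' with published values whose flavor is unstated.
#'
#' @param model an `rt_lmm`.
#' @param term one term label present in the model.
#' @param type `"LRT"` or `"Wald"`.
#' @param marginality `"type2"` or `"strict"`.
#' @return named numeric: `chi2`, `df`, `p`.
#' @export
test_term <- function(model, term, type = c("LRT", "Wald"),
                      marginality = c("type2", "strict")) {
  type <- match.arg(type); marginality <- match.arg(marginality)
  if (!term %in% model$terms) stop("term '", term, "' not in model")
  ints <- if (grepl(":", term, fixed = TRUE)) character(0)
          else interactions_containing(model$terms, term)
  if (length(ints) && marginality == "strict")
    stop("removing '", term, "' violates marginality (present in ",
         paste(ints, collapse = ", "), ")")
  base_terms <- setdiff(model$terms, ints)
  big <- if (length(ints)) refit_ml(model, base_terms) else model$ml
  small <- refit_ml(model, setdiff(base_terms, term))

  if (type == "LRT") {
    ll1 <- as.numeric(stats::logLik(big)); ll0 <- as.numeric(stats::logLik(small))
    df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
    chi2 <- max(0, 2 * (ll1 - ll0))
    p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
    return(c(chi2 = chi2, df = df, p = p))
  }
  # type-II Wald on the term's coefficient block of the reduced-base fit
  X <- if (inherits(big, "merMod")) lme4::getME(big, "X") else stats::model.matrix(big)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(stats::as.formula(
    paste("~", paste(base_terms, collapse = "+")))), "term.labels")
  same_term <- function(a, b) setequal(strsplit(a, ":")[[1]], strsplit(b, ":")[[1]])
  idx <- which(asg %in% which(vapply(labs, same_term, logical(1), b = term)))
  if (!length(idx)) return(c(chi2 = 0, df = 0, p = NA_real_))
  beta <- if (inherits(big, "merMod")) lme4::fixef(big) else stats::coef(big)
  V <- as.matrix(stats::vcov(big))
  chi2 <- as.numeric(t(beta[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% beta[idx])
  c(chi2 = chi2, df = length(idx), p = stats::pchisq(chi2, length(idx), lower.tail = FALSE))
}

#' Backward reduction of removable terms
#'
#' Iteratively drops the least-significant removable term with `p >= alpha`,
#' refitting after each drop. Interactions are eligible before their main
#' effects (marginality); terms named in `protected` are never removed.
#'
#' @param model an `rt_lmm`.
#' @param protected character vector of terms kept regardless of p.
#' @param alpha removal threshold.
#' @param type test flavor passed to [test_term()].
#' @return list: `model` (the reduced `rt_lmm`), `trace` (data.frame of the
#'   eliminations with chi2/df/p and action).
#' @export
backward_reduce <- function(model, protected = character(0), alpha = 0.05,
                            type = "LRT") {
  trace <- list(); step <- 0L
  repeat {
    terms <- model$terms
    in_interaction <- vapply(terms, function(tm)
      !grepl(":", tm, fixed = TRUE) && length(interactions_containing(terms, tm)) > 0,
      logical(1))
    removable <- setdiff(terms[!in_interaction], protected)
    if (!length(removable)) break
    tests <- t(vapply(removable, function(tm) test_term(model, tm, type = type),
                      numeric(3)))
    # a zero-df (aliased) term has p = NA: it contributes nothing, drop first
    tests[, "p"][is.na(tests[, "p"])] <- 1
    worst <- which.max(tests[, "p"])
    step <- step + 1L
    if (tests[worst, "p"] < alpha) {
      trace[[step]] <- data.frame(step = step, term = removable[worst],
                                  chi2 = tests[worst, "chi2"], df = tests[worst, "df"],
                                  p = tests[worst, "p"], action = "stop")
      break
    }
    trace[[step]] <- data.frame(step = step, term = removable[worst],
                                chi2 = tests[worst, "chi2"], df = tests[worst, "df"],
                                p = tests[worst, "p"], action = "dropped")
    model <- fit_lmm(model$data, model$response,
                     setdiff(model$terms, removable[worst]),
                     random = if (model$fell_back) "fish_only" else model$random,
                     log_response = model$log_response)
  }
  list(model = model, trace = if (length(trace)) do.call(rbind, trace)
       else data.frame(step = integer(0), term = character(0), chi2 = numeric(0),
                       df = numeric(0), p = numeric(0), action = character(0)))
}

#' Marginal and conditional R-squared of a Gaussian LMM
#'
#' Variance-partition R-squared: the fixed-effect variance is the variance of
#' the fixed-effect linear predictor over the data; the denominator adds all
#' random-intercept variances and the residual variance. `r2_marginal` is the
#' fixed share, `r2_conditional` the fixed-plus-random share.
#'
#' @param model an `rt_lmm` (REML fit is used).
#' @return named numeric: `r2_marginal`, `r2_conditional` (proportions).
#' @export
r2_nakagawa <- function(model) {
  fit <- model$reml
  if (inherits(fit, "merMod")) {
    X <- lme4::getME(fit, "X")
    var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_r <- sum(vc$vcov[vc$grp != "Residual"])
    var_e <- vc$vcov[vc$grp == "Residual"]
  } else {
    var_f <- stats::var(stats::fitted(fit)); var_r <- 0
    var_e <- summary(fit)$sigma^2
  }
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' Percentage effect size between two factor levels (marginal means)
#'
#' Computes estimated marginal means on the model (log) scale by averaging the
#' fixed-effect predictor over a reference grid that weights every level of
#' the other factors equally and fixes numeric covariates at their mean, then
#' back-transforms the contrast: `(exp(emm_a - emm_b) - 1) * 100`.
#'
#' @param model an `rt_lmm` with a log-transformed response.
#' @param factor_name the factor to contrast.
#' @param contrast length-2 character: level `a` compared against level `b`;
#'   default is last level vs first.
#' @return list: `pct`, `contrast`, `emm` (per-level marginal means, model
#'   scale).
#' @export
effect_size_pct <- function(model, factor_name, contrast = NULL) {
  d <- model$data
  vars <- unique(unlist(strsplit(model$terms, ":", fixed = TRUE)))
  if (!factor_name %in% vars) stop("'", factor_name, "' is not in the model")
  grid_vars <- lapply(vars, function(v)
    if (is.factor(d[[v]])) levels(droplevels(d[[v]])) else mean(d[[v]], na.rm = TRUE))
  names(grid_vars) <- vars
  grid <- expand.grid(grid_vars, stringsAsFactors = TRUE)
  for (v in vars) if (is.factor(d[[v]])) grid[[v]] <- factor(grid[[v]], levels = levels(d[[v]]))

  # interactions need every observed cell of the interacting factors
  fvars <- vars[vapply(vars, function(v) is.factor(d[[v]]), logical(1))]
  ints <- model$terms[grepl(":", model$terms, fixed = TRUE)]
  for (tm in ints) {
    p <- intersect(strsplit(tm, ":", fixed = TRUE)[[1]], fvars)
    if (length(p) >= 2) {
      obs <- unique(d[, p, drop = FALSE])
      need <- unique(grid[, p, drop = FALSE])
      miss <- need[!do.call(paste, need) %in% do.call(paste, obs), , drop = FALSE]
      if (nrow(miss)) stop("empty cells for ", tm, ": ",
                           paste(do.call(paste, c(miss, sep = ":")), collapse = ", "))
    }
  }
  tt <- stats::terms(stats::as.formula(paste("~", paste(model$terms, collapse = "+"))))
  X <- stats::model.matrix(tt, data = grid,
                           xlev = lapply(d[fvars], function(f) levels(droplevels(f))))
  beta <- if (inherits(model$reml, "merMod")) lme4::fixef(model$reml) else stats::coef(model$reml)
  pred <- as.numeric(X[, names(beta), drop = FALSE] %*% beta)
  emm <- tapply(pred, grid[[factor_name]], mean)
  levs <- names(emm)
  if (is.null(contrast)) contrast <- c(levs[length(levs)], levs[1L])
  if (!all(contrast %in% levs)) stop("contrast levels not found: ",
                                     paste(setdiff(contrast, levs), collapse = ", "))
  diff <- emm[[contrast[1L]]] - emm[[contrast[2L]]]
  pct <- if (model$log_response) (exp(diff) - 1) * 100 else diff
  list(pct = unname(pct), contrast = paste(contrast[1L], "vs", contrast[2L]),
       emm = emm)
}

#' Group-size effect on specific growth rate
#'
#' Ordinary least-squares regression of SGR on group size (two levels);
#' reports the slope's p-value and the adjusted R-squared.
#'
#' @param sgr_table data.frame with columns `sgr` and `group_size`.
#' @return list: `p`, `r2_adj`, `means` (per-group mean SGR).
#' @export
sgr_group_test <- function(sgr_table) {
  d <- as.data.frame(sgr_table)
  d$group_size <- factor(d$group_size)
  if (nlevels(droplevels(d$group_size)) < 2L) stop("need two group sizes")
  fit <- stats::lm(sgr ~ group_size, data = d)
  s <- summary(fit)
  list(p = s$coefficients[2L, 4L], r2_adj = s$adj.r.squared,
       means = tapply(d$sgr, d$group_size, mean))
}

# ---- model families mirroring the published tables --------------------------

#' Fit, reduce and summarise one trait model family
#'
#' @param data analysis table.
#' @param response response column name.
#' @param fixed full fixed-effect specification (mains + two-way interactions).
#' @param protected terms never dropped.
#' @param random starting random structure.
#' @param alpha elimination threshold.
#' @param type chi-square flavor for the reported table.
#' @return list: `model` (reduced), `table` (per-term chi2/p with R2m/R2c),
#'   `trace`, `effects` (percentage effect sizes for the retained factors).
#' @export
fit_trait_family <- function(data, response, fixed, protected,
                             random = "batch_nested", alpha = 0.05, type = "LRT") {
  full <- fit_lmm(data, response, fixed, random = random)
  red <- backward_reduce(full, protected = protected, alpha = alpha, type = type)
  m <- red$model
  tests <- t(vapply(m$terms, function(tm) test_term(m, tm, type = type), numeric(3)))
  r2 <- r2_nakagawa(m)
  tab <- data.frame(response = response, effect = m$terms,
                    chi2 = tests[, "chi2"], df = tests[, "df"], p = tests[, "p"],
                    r2_marginal = r2[["r2_marginal"]],
                    r2_conditional = r2[["r2_conditional"]],
                    random = m$random, row.names = NULL)
  fvars <- Filter(function(v) is.factor(m$data[[v]]),
                  unique(unlist(strsplit(m$terms, ":", fixed = TRUE))))
  effects <- lapply(fvars, function(v) {
    e <- effect_size_pct(m, v)
    data.frame(response = response, factor = v, contrast = e$contrast, pct = e$pct)
  })
  list(model = m, table = tab, trace = red$trace,
       effects = if (length(effects)) do.call(rbind, effects)
       else data.frame(response = character(0), factor = character(0),
                       contrast = character(0), pct = numeric(0)))
}

#' Run the full inference layer on a trait table
#'
#' Reproduces the structure of the published analysis: LMMs for nighttime and
#' daytime windowed minima (trial, trial day, shelter cover and two-way
#' interactions; optional mass covariate), and for SMR/MMR/AS (trial, group
#' size, shelter availability, interactions), each backward-reduced with the
#' family's treatment terms protected, plus the SGR group comparison.
#'
#' @param traits,mo2min_long outputs of [compute_traits()].
#' @param adjusted use the mass-adjusted responses?
#' @param mass_covariate add body mass as a removable covariate?
#' @param alpha elimination threshold.
#' @param type chi-square flavor.
#' @return list with per-family results, a stacked `model_table`, stacked
#'   `effects`, and `sgr_test`.
#' @export
run_stats <- function(traits, mo2min_long, adjusted = TRUE, mass_covariate = FALSE,
                      alpha = 0.05, type = "LRT") {
  long <- as.data.frame(mo2min_long); tr <- as.data.frame(traits)
  resp_min <- if (adjusted) "mo2min_adj" else "mo2min"
  mains_min <- c("trial", "trial_day", "shelter_on", if (mass_covariate) "mass_g")
  fixed_min <- c(mains_min, utils::combn(mains_min, 2, paste, collapse = ":"))
  fam <- list()
  for (pp in c("night", "day")) {
    d <- long[long$photoperiod == pp & long$valid, ]
    d$trial <- factor(d$trial, levels = c("initial", "final"))
    d$trial_day <- factor(d$trial_day)
    fam[[paste0(pp, "_mo2min")]] <-
      fit_trait_family(d, resp_min, fixed_min, protected = c("trial", "shelter_on"),
                       alpha = alpha, type = type)
  }
  mains_tr <- c("trial", "group_size", "shelter_available", if (mass_covariate) "mass_g")
  fixed_tr <- c(mains_tr, utils::combn(mains_tr, 2, paste, collapse = ":"))
  tr$trial <- factor(tr$trial, levels = c("initial", "final"))
  tr$group_size <- factor(tr$group_size)
  resp_map <- c(smr = if (adjusted) "smr_adj" else "smr",
                mmr = if (adjusted) "mmr_adj" else "mmr",
                aerobic_scope = if (adjusted) "as_adj" else "aerobic_scope")
  for (nm in names(resp_map)) {
    d <- tr[is.finite(tr[[resp_map[[nm]]]]), ]
    fam[[nm]] <- fit_trait_family(d, resp_map[[nm]], fixed_tr,
                                  protected = c("trial", "group_size", "shelter_available"),
                                  alpha = alpha, type = type)
  }
  sgr_tab <- unique(tr[, c("fish_id", "sgr", "group_size")])
  list(families = fam,
       model_table = do.call(rbind, lapply(fam, `[[`, "table")),
       effects = do.call(rbind, lapply(fam, `[[`, "effects")),
       sgr_test = sgr_group_test(sgr_tab))
}
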