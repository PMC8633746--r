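---
title: "Methods: from oxygen traces to metabolic traits and treatment inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to metabolic traits and treatment inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(respirotraits)
```

## The measurement model

Intermittent-flow respirometry alternates two phases in a small sealed
chamber: a *flush* phase (2 min of every 7-min cycle by default) in which the
chamber is refreshed with oxygenated water, and a closed *measurement* phase
(5 min) in which dissolved oxygen declines through the animal's respiration.
The oxygen uptake rate over one cycle is

$$\dot{M}\mathrm{O}_2 = -\left(b_{\mathrm{cycle}} - b_{\mathrm{bg}}(t)\right)
  \cdot V_{\mathrm{eff}},$$

where $b_{\mathrm{cycle}}$ is the ordinary-least-squares slope of oxygen
concentration against time over the measurement window (mg O~2~ L^-1^ h^-1^,
negative for consumption), $b_{\mathrm{bg}}(t)$ is the microbial background
slope, and $V_{\mathrm{eff}}$ is the chamber volume minus the fish's volume at
a density of 1 kg L^-1^ (so a 2 g fish displaces 2 mL). Division by body mass
in kg gives the mass-specific rate (mg O~2~ kg^-1^ h^-1^).

Design choices frozen here:

* **First 30 s of each measurement excluded** (`exclude_initial_s = 30`).
  Incomplete mixing after the flush biases the early slope; the synthetic
  generator reproduces this by carrying the flush relaxation 30 s into the
  measurement phase, which makes the exclusion rule testable rather than
  ornamental.
* **Background** is the mean of three blank-cycle slopes at each end of the
  trial, interpolated linearly in between and *clamped* (not extrapolated)
  outside the anchors — the anchors already sit at the trial boundaries.
  Background is subtracted in slope units before volume scaling.
* **Quality control**: a cycle passes only if its decline fit has
  $R^2 > 0.95$ (strict inequality) and its background-corrected rate is
  non-negative. A flat (zero-variance) trace is assigned $R^2 = 0$ so it
  cannot pass. Rejections are logged, never silently dropped.

## Traits

* **Windowed minima** ($\dot{M}\mathrm{O}_{2\min}$): the empirical 0.2
  quantile of QC-passed cycle estimates inside a window, with linear
  interpolation between order statistics on the $(n-1)$-spacing convention
  (R's type 7). The convention is not pinned by the method literature; this
  package freezes it and tests it against a brute-force order-statistic
  oracle. A window needs at least `min_cycles = 10` surviving cycles —
  windows hold roughly 45–130 cycles, so 10 is permissive while guarding
  degenerate windows.
* **Windows**: per trial half (shelter condition), a nighttime window from
  5 h after entry (or 5 h after the condition change) to lights-on, and a
  daytime window from lights-on to the condition change (or the chase). Four
  windows per fish-trial, each labelled with its shelter state: at most
  2 night + 2 day minima.
* **SMR** is the lowest valid windowed minimum of the trial; **MMR** is the
  steepest background-corrected 180-s rolling regression (one-sample step,
  never crossing a flush gap) within the first measurement cycle after the
  exhaustive chase (configurable up to ~8 cycles, which can only increase the
  maximum); **AS = MMR − SMR** exactly, so AS + SMR = MMR row-by-row.
* **Allometric adjustment**:
  $\dot{M}\mathrm{O}_{2,\mathrm{adj}} = \bar{m}^{\,b-1} m^{\,1-b}
  \dot{M}\mathrm{O}_2$ with reference mass $\bar{m} = 1.95$ g. The exponent
  $b$ is the log–log OLS slope of absolute $\dot{M}\mathrm{O}_2$ on mass,
  estimated per trait from the initial-trial cohort (a fixed user value is
  accepted). Applied to mass-specific rates this is the identity at
  $m = \bar{m}$ or $b = 1$, is a bijection for fixed $(\bar{m}, b)$, and
  composes across reference masses.
* **SGR** $= 100\,[\ln M_f - \ln M_i]/t$ % day^-1^ with $t = 21$ growth days.
  Natural log: growth of the observed magnitude (~0.5–0.65 % day^-1^ over
  three weeks) is conventionally ln-based, and the analytic check
  $M_f = M_i e^{0.21}, t = 21 \Rightarrow$ exactly 1.0 % day^-1^ holds.

## Inference

Trait responses are log-transformed and fitted with Gaussian linear mixed
models (`lme4`): windowed minima against trial (initial/final), trial day
(1/2) and shelter cover plus two-way interactions; SMR/MMR/AS against trial,
group size (4/8) and shelter availability in the home tank plus two-way
interactions. Random intercepts are fish nested in batch; a singular fit
(any random variance below 1e-8 of the residual) falls back to fish-only,
mirroring how the original analysis dropped batch for MMR and AS.

* **Term tests** are maximum-likelihood likelihood-ratio chi-squares by
  default. Marginality is respected: a main effect inside an interaction is
  tested type-II style, in the model stripped of those interactions. A
  type-II Wald chi-square is offered behind a flag because the published
  tables do not state their flavor.
* **Backward reduction** drops the least significant removable term with
  $p \ge \alpha$ (interactions before their main effects; the family's
  treatment terms are protected) and refits until stable, logging the trace.
* **Variance-partition $R^2$**: marginal $= \sigma^2_f / (\sigma^2_f +
  \Sigma\sigma^2_r + \sigma^2_e)$ and conditional $= (\sigma^2_f +
  \Sigma\sigma^2_r) / (\cdot)$, with $\sigma^2_f$ the variance of the
  fixed-effect predictor over the data; invariant to rescaling the response.
* **Effect sizes** in percent come from marginal means on the log scale with
  equal weights over the other factors' levels and covariates at their mean:
  $(\exp(\mathrm{emm}_a - \mathrm{emm}_b) - 1)\times 100$, satisfying
  $(1 + e_{ab}/100)(1 + e_{ba}/100) = 1$.
* **SGR group test**: plain OLS of SGR on group size; slope p-value and
  adjusted $R^2$.

## The synthetic world

The generator exists so that every stage can be validated against known
ground truth. Its defaults state one world:

| Parameter | Default | Meaning |
|---|---|---|
| design | 5 batches x 16 chambers | 80 fish, two ~45 h trials |
| tanks | 8 of 4 fish, 6 of 8 fish | 83 / 166 fish m^-3^ in 0.048 m^3^ |
| mass | 1.95 ± 0.57 g | initial body mass |
| SMR | lognormal, mean 200, CV 0.25 | mg O~2~ kg^-1^ h^-1^ at 15 °C |
| MMR | 3 x SMR | chase-elicited ceiling |
| day activity | x 1.2 | lights on 07:00–19:00 |
| shelter cover | x 0.92 | while the chamber is covered |
| trial day 2 | x 0.84 | after the condition change (~21 h) |
| final trial | x 1.09 | carry-over across 3 weeks |
| bursts | 1.5 h^-1^ night, x3 day; decay 2 min; amp ~ Exp(0.5) | spontaneous activity |
| growth | SGR ~ N(0.64, 0.23) vs N(0.50, 0.23) % day^-1^ | group size 4 vs 8 |
| background | −0.01 → −0.06 mg O~2~ L^-1^ h^-1^ | linear microbial drift |
| sensor noise | 0.002 mg O~2~ L^-1^ | Gaussian, per 1 Hz sample |

SMR magnitude, burst structure, noise and background levels are not stated by
the source design; they were fixed once at values a respirometry lab would
call typical for a ~2 g cyprinid at 15 °C (SMR a few hundred mg O~2~ kg^-1^
h^-1^, optode noise of a few thousandths of mg L^-1^, background drift growing
over a two-day trial) and are *not* revisited. Oxygen stays above 80% air
saturation (saturation fixed at 10.08 mg L^-1^; no solubility model) by
construction of these defaults.

Chamber oxygen evolves by forward-difference integration: closed phases
decline linearly through uptake plus background; flush phases relax
exponentially toward saturated inflow with a 30 s time constant, carried 30 s
into the measurement as a mixing tail. The chase is an instantaneous jump of
the latent rate to true MMR decaying with a 10 min half-life — a stand-in for
the physical 2-min chase. The trial clock is anchored at 15:30 so the
acclimation window ends at 20:30 and the first lights-on falls 15.5 h in.
Per-chamber shelter order is randomized from the run seed and reversed
between trials; a single master seed fans out to per-chamber sub-streams so
every artifact is byte-reproducible.

A **slope-level fast path** (`output = "slopes"`) draws per-cycle slope fits
directly from the latent model using OLS sampling theory (slope standard
error and theoretical $R^2$ from the noise level and window geometry) instead
of integrating a 1 Hz trace. Replicate-heavy validation (20-cohort effect
recovery, 200-replicate null calibration) runs on this path for compute
budget; the trace path is held to it by a noiseless end-to-end test requiring
recovery of the latent rate within 0.5% per cycle and by the exact OLS
oracle tests.

### What a green test does and does not establish

The generator reproduces the *structure* the analysis assumes — multiplicative
circadian/shelter/trial modulation, burst contamination that the 0.2 quantile
is designed to shed, linear background, a chase event, growth under two group
sizes. It deliberately omits within-individual day-to-day biological
variation beyond bursts, instrument drift/spikes, and temperature wobble.
Consequences worth knowing:

* Conditional $R^2$ of models fitted to synthetic data approaches 1 (real
  data sit near 0.4–0.6); green recovery tests validate the estimators, not
  realistic variance partitions.
* Because the deterministic shelter (x 0.92) and day-2 (x 0.84) multipliers
  set the achievable floor of a trial *below* a fish's nominal SMR, estimator
  bias is assessed against the realized floor
  $\mathrm{SMR} \times \min(h_1, h_2 \times 0.84)$ (with $h_i$ the shelter
  factor of each trial half), which the ground-truth table exports as
  `smr_realized_*`. No estimator could be within ±5% of the *nominal* SMR in
  this world; the realized floor is the designed target of the 0.2-quantile
  estimator.
* On the mass-*adjusted* response the null likelihood-ratio test for the
  shelter term is markedly conservative in this world: the estimated scaling
  exponent injects small correlated fish-by-trial deviations, and with the
  world's near-zero residual these dominate the pooled residual while leaving
  the shelter contrast untouched. On the raw mass-specific response the test
  is calibrated (5% without bursts) and mildly conservative with bursts
  (~1% rejection), which is why calibration checks use the raw response. On
  real data, whose residual variance is orders of magnitude larger, the
  distinction is immaterial.

## Numerical choices and degenerate inputs

* Slope of a zero-variance window: 0 with $R^2 = 0$ (forces QC rejection).
* Corrected rates below zero are flagged, not zeroed.
* `t = 0` growth periods, non-positive masses, chambers smaller than the
  fish, missing blank blocks (without an explicit zero-background opt-out),
  and out-of-range pipeline parameters (`q`, `r2_min`, `alpha`) are errors,
  not warnings.
* Aliased (zero-df) model terms test as $p = \mathrm{NA}$ and are removed
  first during backward reduction.
* A single-batch dataset silently uses the fish-only random structure (one
  level carries no batch signal).
* Seeds derived from the master seed stay below $2^{31}$.

## Known limitations

* No instrument-file ingestion (FireSting and kin): the documented CSV schema
  is the contract.
* No EPOC, SDA, or alternative SMR estimators (MLND, low-10%); no Bayesian
  fitting, random slopes, or repeatability analysis.
* MMR recovery inherits the chase-decay model: the rolling 3-min regression
  reads ~60–75% of the true excess above baseline at the default half-life,
  as it would on real decaying post-chase traces; no acceptance number
  depends on absolute MMR recovery.
* The archived field dataset behind the original study is not redistributed
  here; `analyze` mode consumes its CSV conversion when available (see the
  acceptance suite).
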