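Package: respirotraits
Title: Intermittent-Flow Respirometry Traits and Social-Treatment Inference
Version: 0.1.0
Authors@R: person("respirotraits", "maintainers", role = c("aut", "cre"),
    email = "maintainers@respirotraits.org")
Description: Pipeline from raw intermittent-flow respirometry oxygen traces to
    individual metabolic traits of small fish and to mixed-model inference about
    social-treatment effects. Converts per-cycle oxygen-decline slopes into
    background-corrected, mass-specific oxygen uptake rates; estimates windowed
    minimum metabolic rates (0.2 quantile), standard metabolic rate, maximum
    metabolic rate from a rolling post-chase regression, aerobic scope,
    allometrically mass-adjusted rates, and specific growth rate; and fits
    nested linear mixed models with likelihood-ratio term tests,
    marginal/conditional R-squared, and percentage effect sizes from
    equal-weight marginal means. Includes a synthetic-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
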