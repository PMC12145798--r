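Package: jointhelocals
Title: Home-Away Trait Shifts in Invasive Plants and the Join-the-Locals Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for cross-regional comparisons of leaf
    defense traits between the home and away ranges of invasive plants.
    Provides a hierarchical Bayesian random-slope model of home-away trait
    shifts with posterior imputation of missing trait values, Gelman-Rubin
    convergence diagnostics and Bayesian marginal/conditional R2; the
    "join the locals" bootstrap test comparing invader trait shifts to
    native-community regional differences; principal components analysis of
    trait syndromes with mixed models on component scores; one-way ANOVA
    with Tukey HSD compact letter displays and Welch t tests for regional
    and growth-form comparisons; and a synthetic trait-table generator that
    reproduces the hierarchical structure of a three-region,
    44-species field design for testing every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
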