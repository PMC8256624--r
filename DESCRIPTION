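Package: dosemono
Title: Monotonicity of Toxicity and Response Across Dose-Finding Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for asking whether dose-limiting toxicity (DLT) and
    objective response (OR) probabilities rise monotonically with dose in
    phase I oncology trials. Decomposes partially ordered (multi-agent)
    dose sets into fully orderable analysis series, fits four-parameter
    sigmoidal Emax curves to per-dose binomial outcome counts by maximum
    likelihood and by Bayesian posterior sampling under weakly informative
    priors, and summarises each fit by its curve height: the fitted event
    probability at the highest dose minus that at the lowest. Includes a
    deterministic grid-quadrature posterior as an independent cross-check
    of the sampler, grouped reporting of curve heights with fitted-curve
    and dot-plot figures, and a seedable synthetic-trial generator with
    known ground-truth curves for recovery and null experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
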