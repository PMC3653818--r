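Package: epiregistry
Title: Descriptive Statistics, Trends, Projections and Relative Survival
    for Disease Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for population-based disease registries:
    crude, age-specific, directly age-standardized, truncated and cumulative
    incidence or mortality rates; estimated annual percent change (EAPC) of
    standardized rates via Gaussian log-linear regression; projection of
    future case counts with Poisson and negative-binomial log-linear
    age-period models (age-specific slopes or age-drift) selected by AIC;
    standardized incidence/mortality ratios with exact Poisson confidence
    intervals; decomposition of the net change in cases between two periods
    or areas into risk, population-size and population-structure components;
    and cohort relative survival combining Kaplan-Meier observed survival
    with Hakulinen expected survival from general-population life tables.
    Includes delimited-file readers and validators for registry data
    schemas, a synthetic-registry generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
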