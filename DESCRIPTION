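Package: socmort
Title: Bayesian Mortality Models with Time-Varying Social Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating age-specific adult mortality in wild animal
    populations where social covariates change over the life course, ages are
    uncertain, and individuals can leave the study population unobserved.
    Implements a Gompertz proportional-hazards model with time-varying
    covariates, a latent out-migration (emigration versus death) mixture for
    unknown-fate individuals, Metropolis-Hastings sampling with within-sampler
    truncated-normal imputation of missing covariates, dyadic sociality indices
    built from grooming records, dominance hierarchies ordered by minimizing
    wins below the diagonal of the win-loss matrix, an agent-based dispersal
    simulator for prior elicitation, and a synthetic-data generator so the full
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
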