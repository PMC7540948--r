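# socmort

Bayesian estimation of age-specific adult mortality with **time-varying
social covariates**, for wild-population studies where ages are uncertain
and individuals can leave the study population unobserved.

Long-term primate field studies ask whether animals with stronger social
bonds or higher dominance rank live longer — in both sexes. The male side
of that question is hard: males immigrate with only bracketed birth-date
estimates and disappear with unknown fate (death or emigration?).
`socmort` implements the full analysis pipeline for this setting:

* **Social covariates from raw records** — a dyadic sociality index (DSI)
  built from grooming events corrected for observation effort and z-scored
  within dyad type and life-year, with each animal's bond strength taken as
  the mean over its top 3 partners; and proportional dominance ranks from
  monthly win-loss matrices ordered by minimizing wins below the diagonal.
* **A Gompertz proportional-hazards mortality model** conditioned on
  maturity (age 5 for females, 7 for males), with hazard
  `h(x | w_x) = a e^{bx} e^{kappa . w_x}`, a discrete per-life-year
  cumulative hazard `H(x|W) = sum_t h(t | w_t)`, survival `S = e^{-H}`,
  and left-truncated, right-censored likelihood contributions.
* **A latent out-migration mixture** for unknown-fate males: each
  disappearance is explained as either an unobserved death,
  `(1 - gamma_j) f(x|W)`, or an emigration at a gamma-distributed age,
  `gamma_j g_j(x) S(x|W)`, with separate classes for natal and immigrant
  males and priors elicited from an agent-based dispersal simulation.
* **Metropolis-Hastings within MCMC** that re-derives age-sex covariate
  moments each iteration, imputes missing covariates from truncated
  normals bounded by their stratum range, samples birth dates inside their
  brackets, Gibbs-draws the latent emigration states, and reports medians,
  68%/95% credible intervals, Gelman-Rubin R-hat, and the hazard-effect
  translation `100 (1 - e^{kappa})` (% hazard change per +1 SD).
* **A synthetic-data generator** that reproduces the statistical structure
  of a 35-year two-sex study cohort (265 females, 277 males; immigrant
  males with 2-year birth brackets; disappearances mixing true emigrants
  with undetected deaths), so every stage is testable without field data.

## A worked example

```r
library(socmort)

cfg <- sim_config(seed = 1)          # default: the emulated study cohort
pop <- simulate_population(cfg)

prior <- default_prior_spec(abm_dispersal_priors(abm_config(seed = 3)))
fit <- run_chains(
  assemble_model_data(pop$individuals, pop$covariates, "M"),
  chain_config(n_chains = 4, n_iter = 2500, burn_in = 600, seed = 2),
  prior)
summarize_posterior(fit)[1:4, c("parameter", "median", "ci95_lo", "ci95_hi", "rhat", "effect_pct")]
```

```
        parameter  median  ci95_lo ci95_hi   rhat effect_pct
1               a  0.0293  0.01701 0.04934 1.0003         NA
2               b  0.1464  0.07115 0.21594 1.0005         NA
3     kappa_dsi_f -0.2522 -0.55050 0.06154 1.0029      22.29
4 kappa_prop_rank  0.1251 -0.18079 0.44537 0.9999     -13.33
```

Read: the male baseline hazard roughly doubles every `log(2)/0.146 ~ 4.7`
adult years; one standard deviation of extra bond strength with females
cuts the hazard by ~22%, and one SD of age-standardized rank *raises* it
by ~13% (`effect_pct` is the percent hazard *reduction*, so negative
values are increases) — the sign pattern the cohort was simulated under,
with credible intervals this wide at n = 277 males. `run_pipeline()` wraps the
same steps (including the metrics stage from raw grooming/agonism CSVs)
and writes posterior draws, summary tables and a reproducibility manifest.

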