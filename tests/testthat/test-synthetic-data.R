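# Synthetic cohort generator, interaction simulator and the agent-based
# dispersal prior machinery.

test_that("covariate trajectories follow the age profile and AR(1) structure", {
  cfg0 <- sim_config(ar_sd = 0, seed = 1)
  set.seed(1)
  tr <- simulate_covariate_trajectories(cfg0, "M", n_years = 10)
  t <- 0:9
  profile <- 1 - cfg0$peak_curv * (t - cfg0$peak_t)^2
  expect_equal(tr[, "dsi_f"], profile)
  expect_equal(tr[, "prop_rank"], plogis(profile))
  expect_true(all(tr[, "prop_rank"] >= 0 & tr[, "prop_rank"] <= 1))

  # lag-1 autocorrelation of deviations tracks the configured phi
  for (phi in c(0, 0.9)) {
    cfg <- sim_config(ar_phi = phi, ar_sd = 0.5, peak_curv = 0, seed = 1)
    set.seed(42)
    long <- simulate_covariate_trajectories(cfg, "M", n_years = 8000)
    dev <- long[, "dsi_f"] - 1
    ac <- cor(dev[-1], dev[-length(dev)])
    expect_lt(abs(ac - phi), 0.05)
  }
})

test_that("lifespan inversion reproduces closed-form exponential results", {
  set.seed(11)
  # constant hazard a: ages are Exp(a)
  p <- mortality_params(0.5, 1e-9, kappa = 0)
  W <- matrix(0, 1, 1)
  x <- vapply(1:20000, function(i) simulate_lifespan(p, W), 0)
  expect_lt(abs(mean(x) - 2), 3 * 2 / sqrt(20000))

  # doubling a halves the mean lifespan
  p2 <- mortality_params(1.0, 1e-9, kappa = 0)
  x2 <- vapply(1:20000, function(i) simulate_lifespan(p2, W), 0)
  expect_lt(abs(mean(x) / mean(x2) - 2), 0.1)
})

test_that("simulated survival matches the model survival function", {
  set.seed(12)
  p <- mortality_params(0.05, 0.2, kappa = 0.4)
  W <- matrix(rep(c(0.5, -0.2, 0, 0.3), 10), 40, 1)
  n <- 8000
  x <- vapply(1:n, function(i) simulate_lifespan(p, W), 0)
  for (age in c(1.5, 4, 8)) {
    S_model <- survival_prob(cumulative_hazard(p, W, age))
    S_emp <- mean(x > age)
    expect_lt(abs(S_emp - S_model), 4 * sqrt(S_model * (1 - S_model) / n))
  }
})

test_that("population simulation honours its switches", {
  # no out-migration and certain detection: no unknown fates
  cfg <- sim_config(n_females = 40, n_males = 40, study_years = 15,
                    outm = outmig_params(c(0, 0), c(2, 2), c(1, 1)),
                    death_detect_m = 1, seed = 3)
  pop <- simulate_population(cfg)
  expect_false(any(pop$individuals$fate == "unknown"))

  # longer windows turn censorings into observed deaths
  frac_death <- vapply(c(12, 60), function(L) {
    cfg2 <- sim_config(n_females = 60, n_males = 5, study_years = L,
                       outm = outmig_params(c(0, 0), c(2, 2), c(1, 1)),
                       death_detect_m = 1, immigrant_fraction = 0, seed = 4)
    mean(simulate_population(cfg2)$individuals$fate == "death")
  }, 0)
  expect_gt(frac_death[2], frac_death[1])
  expect_gt(frac_death[2], 0.5)

  # registry invariants hold and brackets contain the true birth
  pop <- small_sim()$pop
  ind <- pop$individuals
  expect_true(all(as.Date(ind$birth_min) <= as.Date(ind$birth_max)))
  expect_true(all(as.Date(ind$birth_max) <= as.Date(ind$entry_date)))
  expect_true(all(as.Date(ind$entry_date) <= as.Date(ind$last_date)))
  tr <- pop$truth[match(ind$id, pop$truth$id), ]
  expect_true(all(as.Date(ind$birth_min) <= as.Date(tr$birth) + 1))
  expect_true(all(pop$covariates$prop_rank >= 0 &
                    pop$covariates$prop_rank <= 1, na.rm = TRUE))
})

test_that("unknown-fate frequency matches a brute-force competing-risk check", {
  # special case with closed-form pieces: constant hazard (b ~ 0, kappa = 0),
  # natal males only, no censoring pressure (long window)
  a <- 0.15
  cfg <- sim_config(n_females = 5, n_males = 600, study_years = 500,
                    mort_m = mortality_params(a, 1e-9, c(dsi_f = 0, prop_rank = 0)),
                    outm = outmig_params(c(0.6, 0.6), c(2.5, 2.5), c(1.5, 1.5)),
                    immigrant_fraction = 0, death_detect_m = 1,
                    entry_growth = 1, seed = 9)
  pop <- simulate_population(cfg)
  got <- mean(pop$individuals$fate[pop$individuals$sex == "M"] == "unknown")
  # independent Monte-Carlo with base R draws only
  set.seed(99)
  n <- 2e5
  death <- rexp(n, a)
  mig <- ifelse(runif(n) < 0.6, rgamma(n, 2.5, 1.5), Inf)
  want <- mean(mig < death)
  expect_lt(abs(got - want), 4 * sqrt(want * (1 - want) / 600))
})

test_that("interaction simulation carries the latent structure", {
  pop <- small_sim()$pop
  # near-deterministic contests: ranks recover the latent order exactly
  si <- simulate_interactions(pop$individuals, n_groups = 1, steepness = Inf,
                              monthly_contests = 30, seed = 5)
  ag <- si$agonism
  fem <- unique(c(ag$winner, ag$loser))
  fem <- fem[substr(fem, 1, 1) == "F"]
  w <- build_rank_matrix(ag[substr(ag$winner, 1, 1) == "F", ], ids = fem)
  r <- ordinal_ranks(w)
  expect_equal(r$objective, 0)
  # multiple zero-cost orderings exist for never-met pairs; the recovered
  # ranks must still track latent strength almost perfectly
  expect_gt(cor(r$ordinal[fem], rank(-si$latent$strength[fem]),
                method = "spearman"), 0.9)

  # grooming rates increase with the latent bond: positive rank correlation
  si2 <- simulate_interactions(pop$individuals, n_groups = 1,
                               bond_effect = 1.5, base_rate = 6, seed = 6)
  rates <- compute_dyadic_rates(si2$grooming, si2$effort, pop$individuals)
  key <- paste(pmin(rates$focal, rates$partner),
               pmax(rates$focal, rates$partner))
  bond <- si2$latent$bond
  bkey <- paste(pmin(bond$id_a, bond$id_b), pmax(bond$id_a, bond$id_b))
  m <- match(key, bkey)
  ok <- !is.na(m)
  expect_gt(cor(rates$raw_rate[ok], bond$bond[m[ok]], method = "spearman"),
            0.5)

  # no bond effect: correlation collapses
  si3 <- simulate_interactions(pop$individuals, n_groups = 1,
                               bond_effect = 0, base_rate = 6, seed = 7)
  rates3 <- compute_dyadic_rates(si3$grooming, si3$effort, pop$individuals)
  key3 <- paste(pmin(rates3$focal, rates3$partner),
                pmax(rates3$focal, rates3$partner))
  bond3 <- si3$latent$bond
  bkey3 <- paste(pmin(bond3$id_a, bond3$id_b), pmax(bond3$id_a, bond3$id_b))
  m3 <- match(key3, bkey3)
  ok3 <- !is.na(m3)
  expect_lt(abs(cor(rates3$raw_rate[ok3], bond3$bond[m3[ok3]],
                    method = "spearman")), 0.15)
})

test_that("agent-based dispersal priors reflect the group geography", {
  # no non-study groups: nobody can leave
  pr0 <- abm_dispersal_priors(abm_config(n_study_groups = 4,
                                         n_nonstudy_groups = 0, seed = 2))
  expect_equal(unname(pr0$leave_fraction["natal"]), 0)
  expect_lt(pr0$gp_beta$natal[1] / sum(pr0$gp_beta$natal), 0.1)

  # many equal-sized study and non-study pools: leaving fraction ~ 0.5
  pr1 <- abm_dispersal_priors(abm_config(n_study_groups = 50,
                                         n_nonstudy_groups = 50,
                                         n_agents = 20000, seed = 3))
  expect_lt(abs(pr1$leave_fraction[["natal"]] - 0.5), 0.02)

  # degenerate age sample: prior centred at that age with vanishing variance
  pr2 <- abm_dispersal_priors(abm_config(natal_ages = rep(2, 5), seed = 4))
  mu_mean <- pr2$gam_shape$natal[["mu"]] / pr2$gam_rate$natal[["mu"]]
  mu_var <- pr2$gam_shape$natal[["mu"]] / pr2$gam_rate$natal[["mu"]]^2
  expect_equal(mu_mean, 2, tolerance = 1e-6)
  expect_lt(mu_var, 1e-4)
})

test_that("the synthetic registry reproduces the reference tallies", {
  reg <- synthetic_cohort_registry()
  expect_equal(nrow(reg), 542L)
  expect_silent(load_individuals(reg, quiet = TRUE))
  comp <- cohort_composition(reg)
  expect_equal(comp$by_sex$n, c(265L, 277L))
  expect_equal(comp$by_sex$n_death, c(129L, 41L))
  expect_equal(comp$by_sex$n_censored, c(136L, 129L))
  expect_equal(comp$by_sex$n_unknown, c(0L, 107L))
  expect_equal(comp$known_birth$count, 340L)
})
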