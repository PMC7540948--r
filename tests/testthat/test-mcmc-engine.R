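# Sampler building blocks, diagnostics and summaries.

test_that("the MH kernel samples a standard normal target", {
  set.seed(101)
  target <- function(x) dnorm(x, log = TRUE)
  x <- 0
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    x <- mh_update(x, target, scale = 2.4)$value
    draws[i] <- x
  }
  # 3 Monte Carlo standard errors with a generous effective-sample deflation
  expect_lt(abs(mean(draws)), 3 * 1 / sqrt(20000 / 10))
  expect_lt(abs(var(draws) - 1), 3 * sqrt(2 / (20000 / 10)))
})

test_that("a vanishing proposal scale accepts almost everything and stays put", {
  set.seed(102)
  target <- function(x) dnorm(x, log = TRUE)
  acc <- 0; x <- 0.5
  for (i in 1:500) {
    r <- mh_update(x, target, scale = 1e-8)
    acc <- acc + r$accepted; x <- r$value
  }
  expect_gt(acc / 500, 0.999)
  expect_lt(abs(x - 0.5), 1e-4)
  expect_error(mh_update(Inf, target, 1), "finite")
})

test_that("log-scale proposals respect the positive domain with the Jacobian", {
  set.seed(103)
  # target: Exp(1) on (0, Inf); with the Jacobian the chain must reproduce
  # its mean 1 and P(X < log 2) = 0.5
  target <- function(x) if (x <= 0) -Inf else -x
  x <- 1; draws <- numeric(20000)
  for (i in seq_along(draws)) {
    x <- mh_update(x, target, scale = 1.5, log_scale = TRUE)$value
    draws[i] <- x
  }
  expect_lt(abs(mean(draws) - 1), 0.06)
  expect_lt(abs(mean(draws < log(2)) - 0.5), 0.03)
})

test_that("birth updates stay inside the bracket and match a flat target", {
  set.seed(104)
  b <- 0.5
  draws <- numeric(4000)
  for (i in seq_along(draws)) {
    b <- update_birth_age(0, 1, b, function(x) 0)   # flat likelihood
    draws[i] <- b
  }
  expect_true(all(draws >= 0 & draws <= 1))
  ks <- suppressWarnings(ks.test(unique(draws), "punif"))
  expect_gt(ks$p.value, 0.001)

  # degenerate bracket is never updated
  expect_equal(update_birth_age(2, 2, 2, function(x) 0), 2)

  # likelihood favouring older age (earlier birth) shifts mass down-bracket
  set.seed(105)
  b <- 0.5; s <- 0
  for (i in 1:2000) {
    b <- update_birth_age(0, 1, b, function(x) -8 * x)
    s <- s + b
  }
  expect_lt(s / 2000, 0.35)
})

test_that("out-migration states are Bernoulli draws of their posteriors", {
  set.seed(106)
  expect_equal(update_outmig_states(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_equal(update_outmig_states(c(1, 1)), c(1L, 1L))
  o <- replicate(4000, update_outmig_states(0.5))
  expect_lt(abs(mean(o) - 0.5), 0.03)
  expect_error(update_outmig_states(1.2), "\\[0, 1\\]")
})

test_that("truncated-normal imputation respects stratum bounds", {
  set.seed(107)
  obs <- data.frame(sex = "M", covariate = "dsi_f", life_year = 0L,
                    value = c(-1, -0.3, 0, 0.4, 1))
  m <- age_sex_moments(obs)
  filled <- impute_missing_covariates(
    rbind(obs, data.frame(sex = "M", covariate = "dsi_f", life_year = 0L,
                          value = rep(NA_real_, 10000))), m)
  imp <- filled$value[filled$imputed]
  expect_true(all(imp >= -1 & imp <= 1))
  expect_lt(abs(mean(imp) - mean(obs$value)), 0.05)

  # zero-spread stratum collapses to its mean
  obs0 <- data.frame(sex = "M", covariate = "prop_rank", life_year = 2L,
                     value = c(0.4, 0.4, 0.4))
  f0 <- impute_missing_covariates(
    rbind(obs0, data.frame(sex = "M", covariate = "prop_rank", life_year = 2L,
                           value = NA_real_)), age_sex_moments(obs0))
  expect_equal(f0$value[4], 0.4)

  # fully observed input is a no-op
  f1 <- impute_missing_covariates(obs, m)
  expect_equal(f1$value, obs$value)
  expect_false(any(f1$imputed))

  # singleton stratum falls back to pooling across ages within sex
  pool <- rbind(obs,
                data.frame(sex = "M", covariate = "dsi_f", life_year = 9L,
                           value = 0.2),
                data.frame(sex = "M", covariate = "dsi_f", life_year = 9L,
                           value = NA_real_))
  fp <- impute_missing_covariates(pool, age_sex_moments(pool))
  expect_true(fp$value[nrow(fp)] >= -1 & fp$value[nrow(fp)] <= 1)
})

test_that("linear interpolation fills interior gaps and extrapolates flat", {
  expect_equal(impute_linear(c(0, NA, 1)), c(0, 0.5, 1))
  expect_equal(impute_linear(c(NA, NA, 0.8, 0.4)), c(0.8, 0.8, 0.8, 0.4))
  expect_equal(impute_linear(c(0.1, 0.2)), c(0.1, 0.2))
  expect_error(impute_linear(c(NA_real_, NA_real_)), "all-missing")
})

test_that("R-hat flags disagreement and clears agreement", {
  set.seed(108)
  iid <- lapply(1:4, function(i) rnorm(10000))
  expect_gt(rhat(iid), 0.999)
  expect_lt(rhat(iid), 1.01)

  plateaus <- list(rep(0, 100) + rnorm(100, sd = 0.01),
                   rep(10, 100) + rnorm(100, sd = 0.01))
  expect_gt(rhat(plateaus), 10)

  # hand-computed two-chain case
  ch <- list(c(1, 2, 3), c(2, 3, 4))
  W <- mean(c(var(c(1, 2, 3)), var(c(2, 3, 4))))
  B <- 3 * var(c(2, 3))
  expect_equal(rhat(ch), sqrt(((3 - 1) / 3 * W + B / 3) / W))

  expect_equal(rhat(list(rep(2, 50), rep(2, 50))), Inf)
  expect_error(rhat(list(rnorm(10))), "2 chains")
})

test_that("posterior summaries use interpolated quantiles and effect translation", {
  ps <- structure(list(
    draws = list(cbind(kappa_dsi_f = rep(log(0.72), 50), a = 1:50),
                 cbind(kappa_dsi_f = rep(log(0.72), 50), a = 51:100)),
    rhat = c(kappa_dsi_f = 1, a = 1)), class = "posterior_set")
  s <- summarize_posterior(ps)
  a_row <- s[s$parameter == "a", ]
  expect_equal(a_row$median, 50.5)
  expect_equal(a_row$ci95_lo, 3.475)
  expect_equal(a_row$ci95_hi, 97.525)
  k_row <- s[s$parameter == "kappa_dsi_f", ]
  expect_equal(k_row$effect_pct, 28, tolerance = 1e-9)

  # symmetric kappa draws give a ~0% effect
  set.seed(109)
  sym <- rnorm(4000)
  ps2 <- structure(list(draws = list(cbind(kappa_x = sym), cbind(kappa_x = -sym)),
                        rhat = c(kappa_x = 1)), class = "posterior_set")
  expect_lt(abs(summarize_posterior(ps2)$effect_pct), 5)
})

test_that("chains are reproducible and the zero-retention edge warns", {
  sim <- small_sim()
  dat <- assemble_model_data(sim$pop$individuals, sim$pop$covariates, "F")
  cc <- chain_config(n_chains = 2, n_iter = 120, burn_in = 40, seed = 17)
  ps1 <- run_chains(dat, cc)
  ps2 <- run_chains(dat, cc)
  expect_identical(ps1$draws, ps2$draws)
  expect_identical(ps1$o_mean, ps2$o_mean)

  cc0 <- chain_config(n_chains = 1, n_iter = 30, burn_in = 30, seed = 1)
  expect_warning(ch <- run_chain(dat, cc0, chain_seed = 5), "no retained")
  expect_equal(nrow(ch$draws), 0L)
  expect_error(chain_config(n_iter = 100, burn_in = 200), "exceed")
})

test_that("a short fit on clean synthetic data tracks the true parameters", {
  cfg <- sim_config(n_females = 250, n_males = 5, study_years = 30,
                    missingness = 0, natal_bracket_frac = 0, seed = 77)
  pop <- simulate_population(cfg)
  dat <- assemble_model_data(pop$individuals, pop$covariates, "F")
  ps <- run_chains(dat, chain_config(n_chains = 2, n_iter = 700, burn_in = 250,
                                     seed = 21))
  s <- summarize_posterior(ps)
  a_hat <- s$median[s$parameter == "a"]
  b_hat <- s$median[s$parameter == "b"]
  expect_gt(a_hat, cfg$mort$F$a / 3); expect_lt(a_hat, cfg$mort$F$a * 3)
  expect_gt(b_hat, cfg$mort$F$b / 3); expect_lt(b_hat, cfg$mort$F$b * 3)
  # the strongly negative bond coefficient comes out negative
  expect_lt(s$median[s$parameter == "kappa_dsi_f"], 0)
})
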