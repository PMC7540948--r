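# Gompertz proportional-hazards mortality with time-varying covariates,
# left truncation at maturity, right-censoring, and a latent natal/immigrant
# out-migration mixture for unknown-fate individuals.
#
# All ages are x = age - alpha (years since maturity). The cumulative hazard
# uses the model's discrete 1-year approximation: the hazard is evaluated at
# the left endpoint of each life-year and the last, fractional step is
# h(floor(x) | w_floor(x)) * (x - floor(x)).

#' Gompertz mortality parameters with proportional covariate effects
#'
#' @param a baseline mortality (per year, > 0).
#' @param b Gompertz rate (per year, > 0): log-hazard slope with age.
#' @param kappa named numeric vector of proportional-hazards coefficients
#'   (log hazard ratio per +1 SD of each standardized covariate).
#' @return an object of class `mortality_params`.
#' @export
mortality_params <- function(a, b, kappa) {
  check(is.numeric(a) && length(a) == 1 && a > 0, "a must be a single value > 0")
  check(is.numeric(b) && length(b) == 1 && b > 0, "b must be a single value > 0")
  check(is.numeric(kappa) && all(is.finite(kappa)), "kappa must be finite")
  structure(list(a = a, b = b, kappa = kappa), class = "mortality_params")
}

#' @export
print.mortality_params <- function(x, ...) {
  cat("Gompertz PH parameters: a =", signif(x$a, 4), " b =", signif(x$b, 4), "\n")
  cat("kappa:", paste(names(x$kappa), signif(x$kappa, 4), sep = " = ",
                      collapse = ", "), "\n")
  invisible(x)
}

#' Out-migration mixture parameters
#'
#' Bernoulli probabilities of ever out-migrating and gamma distributions of
#' ages (years since maturity) at out-migration, for the natal (`j = 1`,
#' individuals present in the study population at maturity) and immigrant
#' (`j = 2`, individuals who entered after maturity) classes.
#'
#' @param gamma_prob,gam_shape,gam_rate length-2 numeric vectors named
#'   `c("natal", "immigrant")`; probabilities in \[0, 1\], shapes and rates
#'   > 0.
#' @return an object of class `outmig_params`.
#' @export
outmig_params <- function(gamma_prob, gam_shape, gam_rate) {
  nm <- c("natal", "immigrant")
  gamma_prob <- stats::setNames(rep_len(gamma_prob, 2), nm)
  gam_shape <- stats::setNames(rep_len(gam_shape, 2), nm)
  gam_rate <- stats::setNames(rep_len(gam_rate, 2), nm)
  check(all(gamma_prob >= 0 & gamma_prob <= 1), "gamma_prob must lie in [0, 1]")
  check(all(gam_shape > 0) && all(gam_rate > 0), "gamma shape/rate must be > 0")
  structure(list(gamma_prob = gamma_prob, gam_shape = gam_shape,
                 gam_rate = gam_rate), class = "outmig_params")
}

#' Gompertz baseline hazard
#'
#' `mu(x) = a * exp(b * x)`: mortality risk increasing exponentially with
#' adult age.
#'
#' @param a,b Gompertz baseline and rate parameters (> 0).
#' @param x age in years since maturity (>= 0); vectorized.
#' @return hazard (per year).
#' @export
gompertz_hazard <- function(a, b, x) {
  check(all(a > 0) && all(b > 0), "Gompertz parameters must be > 0")
  check(all(x >= 0), "age since maturity must be >= 0")
  a * exp(b * x)
}

#' Hazard with time-varying covariates
#'
#' `h(x | w_x) = mu(x) * exp(kappa . w_x)`: proportional scaling of the
#' Gompertz baseline by the current covariate vector.
#'
#' @param params [mortality_params()].
#' @param w_x covariate vector at age `x` (same length as `kappa`).
#' @param x age since maturity.
#' @return hazard (per year).
#' @export
hazard_tv <- function(params, w_x, x) {
  check(length(w_x) == length(params$kappa),
        "covariate vector length %d does not match kappa length %d",
        length(w_x), length(params$kappa))
  check(all(is.finite(w_x)), "covariates must be finite")
  gompertz_hazard(params$a, params$b, x) * exp(sum(params$kappa * w_x))
}

#' Discrete cumulative hazard over life-years
#'
#' Approximates `H(x | W)` by summing per-life-year hazards: one full step
#' `h(t | w_t)` for each whole life-year below `x`, plus a fractional final
#' step `h(floor(x) | w_floor(x)) * (x - floor(x))`, evaluating the hazard at
#' the left endpoint of every step.
#'
#' @param params [mortality_params()].
#' @param W covariate matrix, row `t + 1` = covariate vector of life-year `t`;
#'   must supply every integer `t <= floor(x)` (missing values are an error:
#'   imputation must have filled them).
#' @param x real age since maturity (>= 0).
#' @return dimensionless cumulative hazard.
#' @export
cumulative_hazard <- function(params, W, x) {
  check(x >= 0, "age since maturity must be >= 0")
  if (x == 0) return(0)
  W <- rbind(W)
  k <- floor(x)
  need <- if (x > k) k + 1L else k
  check(nrow(W) >= need && !anyNA(W[seq_len(need), , drop = FALSE]),
        "covariate matrix must cover life-years 0..%d without missing values", need - 1L)
  t_full <- seq_len(k) - 1L
  H <- 0
  if (k >= 1) {
    lp <- as.vector(W[t_full + 1L, , drop = FALSE] %*% params$kappa)
    H <- sum(gompertz_hazard(params$a, params$b, t_full) * exp(lp))
  }
  if (x > k) {
    lp <- sum(params$kappa * W[k + 1L, ])
    H <- H + gompertz_hazard(params$a, params$b, k) * exp(lp) * (x - k)
  }
  H
}

#' Survival probability and death density
#'
#' `S(x | W) = exp(-H(x | W))` and the probability density of ages at death
#' given the covariate history. The density evaluates the hazard at the left
#' endpoint of the death's life-year, `f(x | W) = h(floor(x) | w_floor(x)) *
#' S(x | W)`: with the piecewise-constant discrete cumulative hazard this is
#' exactly `-dS/dx`, so the density, the survival function and the inverse
#' simulator ([simulate_lifespan()]) are mutually consistent.
#'
#' @param H cumulative hazard (>= 0); vectorized.
#' @return `survival_prob()`: probability in (0, 1\].
#' @export
survival_prob <- function(H) {
  check(all(H >= 0), "cumulative hazard must be >= 0")
  exp(-H)
}

#' @rdname survival_prob
#' @inheritParams cumulative_hazard
#' @return `death_density()`: density of ages at death (per year).
#' @export
death_density <- function(params, W, x) {
  W <- rbind(W)
  # at an exact integer age the open life-year's covariate row may be absent;
  # the previous year's value carries over (measure-zero boundary case)
  idx <- min(floor(x) + 1L, nrow(W))
  h <- hazard_tv(params, W[idx, ], floor(x))
  h * survival_prob(cumulative_hazard(params, W, x))
}

#' Density of ages at out-migration
#'
#' Gamma density of the age (since maturity) at out-migration for the natal
#' or immigrant class.
#'
#' @param z age since maturity (>= 0); vectorized.
#' @param j `"natal"` or `"immigrant"`.
#' @param params [outmig_params()].
#' @return density (per year).
#' @export
outmig_density <- function(z, j = c("natal", "immigrant"), params) {
  j <- match.arg(j)
  check(all(z >= 0), "age at out-migration must be >= 0")
  stats::dgamma(z, shape = params$gam_shape[[j]], rate = params$gam_rate[[j]])
}

#' Log-likelihood contribution of one individual
#'
#' Left-truncated at the entry age, with the fate-specific terminal term:
#' \describe{
#'   \item{death}{`log f(x_last | W) - log S(x_entry | W)`}
#'   \item{censored}{`log S(x_last | W) - log S(x_entry | W)`}
#'   \item{unknown, o = 0 (died)}{`log(1 - gamma_prob[j])` plus the death
#'     term, with death taken at the last-seen age}
#'   \item{unknown, o = 1 (out-migrated)}{`log gamma_prob[j] +
#'     log g_j(x_last) + log S(x_last | W) - log S(x_entry | W)`: the
#'     individual survived to departure and then left}
#' }
#' `gamma_prob[j]` is the Bernoulli mixture weight of the two explanations of
#' a disappearance; it parameterizes unknown-fate records only. Records with
#' known fate carry no out-migration terms: a death or censoring event says
#' nothing about whether the animal would have emigrated later, and letting
#' such records pull on the mixture weight makes the weight unidentifiable
#' from the disappearance ages it has to explain.
#'
#' @param fate `"death"`, `"censored"` or `"unknown"`.
#' @param origin `"natal"` or `"immigrant"` (selects the out-migration class
#'   `j`).
#' @param x_entry,x_last entry and last-seen ages since maturity
#'   (`x_entry = max(entry age, alpha) - alpha`).
#' @param W covariate matrix over life-years (see [cumulative_hazard()]).
#' @param mort [mortality_params()].
#' @param outm [outmig_params()] or `NULL` to disable out-migration (females).
#' @param o latent out-migration indicator (0/1), required when
#'   `fate = "unknown"`.
#' @return log-probability.
#' @export
individual_loglik <- function(fate, origin, x_entry, x_last, W, mort,
                              outm = NULL, o = NA) {
  check(x_last >= x_entry, "last-seen age before entry age: data error")
  fate <- match.arg(fate, c("death", "censored", "unknown"))
  lS_entry <- -cumulative_hazard(mort, W, x_entry)
  if (fate == "death") {
    return(log(death_density(mort, W, x_last)) - lS_entry)
  }
  if (fate == "censored") {
    return(-cumulative_hazard(mort, W, x_last) - lS_entry)
  }
  check(!is.null(outm), "unknown fate requires out-migration parameters")
  check(o %in% c(0, 1), "unknown fate requires a latent o indicator")
  gp <- outm$gamma_prob[[origin]]
  if (o == 1) {
    log(gp) + log(outmig_density(x_last, origin, outm)) -
      cumulative_hazard(mort, W, x_last) - lS_entry
  } else {
    log(1 - gp) + log(death_density(mort, W, x_last)) - lS_entry
  }
}

#' Conditional posterior probability of the out-migrated state
#'
#' For an unknown-fate individual, weighs the likelihood of out-migration at
#' the last-seen age against the likelihood of death:
#' `p = A / (A + B)` with `A = gamma_prob[j] * g_j(x_last) * S(x_last | W)`
#' and `B = (1 - gamma_prob[j]) * f(x_last | W)`.
#'
#' @inheritParams individual_loglik
#' @return probability that `o = 1`; 0.5 with a warning when both branch
#'   likelihoods vanish.
#' @export
state_posterior_prob <- function(origin, x_last, W, mort, outm) {
  gp <- outm$gamma_prob[[origin]]
  S <- survival_prob(cumulative_hazard(mort, W, x_last))
  A <- gp * outmig_density(x_last, origin, outm) * S
  B <- (1 - gp) * death_density(mort, W, x_last)
  if (A == 0 && B == 0) {
    warning("degenerate support: both out-migration and death likelihoods are 0")
    return(0.5)
  }
  A / (A + B)
}

#' Prior specification for the mortality and out-migration parameters
#'
#' Vague priors for the mortality side: wide half-normal priors on `a`
#' (scale 1) and `b` (scale 0.5) over (0, Inf), and zero-mean normal priors
#' with standard deviation 10 on each `kappa` entry. The out-migration side
#' takes its hyperparameters from the agent-based dispersal simulator
#' ([abm_dispersal_priors()]): Beta pseudo-counts for `gamma_prob` and
#' truncated-normal priors on the gamma shape and rate centred at the
#' moment-matched values. Defaults are uninformative (`Beta(1, 1)`, wide
#' centres) when no simulator output is supplied.
#'
#' @param abm optional output of [abm_dispersal_priors()].
#' @param a_scale,b_scale,kappa_sd prior scales.
#' @return a `prior_spec` list.
#' @export
default_prior_spec <- function(abm = NULL, a_scale = 1, b_scale = 0.5,
                               kappa_sd = 10) {
  spec <- list(
    a_scale = a_scale, b_scale = b_scale, kappa_sd = kappa_sd,
    gp_beta = list(natal = c(1, 1), immigrant = c(1, 1)),
    gam_shape = list(natal = c(mu = 2, sd = 10), immigrant = c(mu = 2, sd = 10)),
    gam_rate = list(natal = c(mu = 1, sd = 10), immigrant = c(mu = 1, sd = 10)))
  if (!is.null(abm)) {
    spec$gp_beta <- abm$gp_beta
    spec$gam_shape <- abm$gam_shape
    spec$gam_rate <- abm$gam_rate
  }
  class(spec) <- "prior_spec"
  spec
}

#' Joint log prior density
#'
#' Sum of the independent log prior densities of all mortality and (when
#' enabled) out-migration parameters; `-Inf` outside parameter domains.
#'
#' @param mort [mortality_params()] (or a list with `a`, `b`, `kappa`).
#' @param outm [outmig_params()] or `NULL`.
#' @param prior_spec [default_prior_spec()].
#' @return log prior density (unnormalized where truncation constants are
#'   parameter-free).
#' @export
log_prior <- function(mort, outm = NULL, prior_spec = default_prior_spec()) {
  if (mort$a <= 0 || mort$b <= 0) return(-Inf)
  lp <- stats::dnorm(mort$a, 0, prior_spec$a_scale, log = TRUE) + log(2) +
    stats::dnorm(mort$b, 0, prior_spec$b_scale, log = TRUE) + log(2) +
    sum(stats::dnorm(mort$kappa, 0, prior_spec$kappa_sd, log = TRUE))
  if (!is.null(outm)) {
    for (j in c("natal", "immigrant")) {
      gp <- outm$gamma_prob[[j]]
      if (gp < 0 || gp > 1) return(-Inf)
      if (outm$gam_shape[[j]] <= 0 || outm$gam_rate[[j]] <= 0) return(-Inf)
      bb <- prior_spec$gp_beta[[j]]
      lp <- lp + stats::dbeta(gp, bb[1], bb[2], log = TRUE) +
        stats::dnorm(outm$gam_shape[[j]], prior_spec$gam_shape[[j]]["mu"],
                     prior_spec$gam_shape[[j]]["sd"], log = TRUE) +
        stats::dnorm(outm$gam_rate[[j]], prior_spec$gam_rate[[j]]["mu"],
                     prior_spec$gam_rate[[j]]["sd"], log = TRUE)
    }
  }
  unname(lp)
}
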