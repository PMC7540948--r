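# Metropolis-Hastings sampling of all parameters and latent quantities, with
# within-sampler imputation of missing covariates, convergence diagnostics and
# posterior summaries.
#
# The likelihood is evaluated on a flat grid with one row per (individual,
# life-year): cumulative-hazard differences decompose into per-row terms
# h(t | w_t) * overlap([t, t+1), [x_entry, x_last]), which vectorizes the
# whole cohort into a single rowsum().

#' Chain configuration
#'
#' @param n_chains number of parallel chains (default 8).
#' @param n_iter iterations per chain (default 5000).
#' @param burn_in initial burn-in iterations discarded (default 1000).
#' @param thin retain every `thin`-th post-burn-in draw (default 1, no
#'   thinning).
#' @param seed integer seed; per-chain seeds are derived deterministically.
#' @param proposal_scales optional named list overriding default proposal
#'   scales (`a`, `b`, `kappa`, `gp`, `gam_shape`, `gam_rate`).
#' @param adapt adapt proposal scales toward 25-45% acceptance during
#'   burn-in only (Robbins-Monro), frozen afterwards.
#' @return a `chain_config` list.
#' @export
chain_config <- function(n_chains = 8, n_iter = 5000, burn_in = 1000,
                         thin = 1, seed = 1L, proposal_scales = NULL,
                         adapt = TRUE) {
  check(burn_in <= n_iter, "burn_in must not exceed n_iter")
  check(n_chains >= 1 && thin >= 1, "invalid chain configuration")
  scales <- list(a = 0.15, b = 0.15, kappa = 0.15, gp = 0.6,
                 gam_shape = 0.25, gam_rate = 0.25)
  scales[names(proposal_scales)] <- proposal_scales
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed),
                 proposal_scales = scales, adapt = isTRUE(adapt)),
            class = "chain_config")
}

#' Assemble registry and covariates into model-ready data for one sex
#'
#' Converts dates to the decimal-year axis, attaches each covariate
#' observation to a calendar anchor (`year_mid`, the midpoint of the
#' life-year it was measured in) so life-year indices can be recomputed under
#' any imputed birth date, and validates fates. Individuals whose whole
#' bracket implies exit before maturity are dropped with a message.
#'
#' @param individuals registry data frame ([load_individuals()]).
#' @param covariates covariate table (`id, sex, life_year, dsi_f, dsi_m,
#'   prop_rank`, optionally `year_mid`; without `year_mid` the anchor is
#'   reconstructed from `life_year` and the bracket-midpoint birth).
#' @param sex `"F"` or `"M"`.
#' @param alpha ages at maturity.
#' @param out_migration enable the out-migration mixture (default: males
#'   only).
#' @return a `model_data` list consumed by [run_chains()].
#' @export
assemble_model_data <- function(individuals, covariates, sex,
                                alpha = default_alpha(),
                                out_migration = identical(sex, "M")) {
  ind <- individuals[individuals$sex == sex, , drop = FALSE]
  check(nrow(ind) > 0, "no individuals of sex %s", sex)
  al <- alpha[[sex]]
  check(out_migration || !any(ind$fate == "unknown"),
        "fate 'unknown' present but out-migration is disabled for sex %s", sex)

  bmin <- date_to_years(ind$birth_min)
  bmax <- date_to_years(ind$birth_max)
  entry <- date_to_years(ind$entry_date)
  last <- date_to_years(ind$last_date)
  check(all(bmin <= bmax + 1e-9) && all(bmax <= entry + 1e-9) &&
          all(entry <= last + 1e-9),
        "registry violates birth_min <= birth_max <= entry <= last")
  # the latest admissible birth must leave a positive adult observation span
  bmax <- pmin(bmax, last - al - 1e-6)
  drop <- bmax < bmin
  if (any(drop)) {
    message(sum(drop), " individuals exit before maturity and are dropped")
    keep <- !drop
    ind <- ind[keep, , drop = FALSE]
    bmin <- bmin[keep]; bmax <- bmax[keep]
    entry <- entry[keep]; last <- last[keep]
  }

  covs <- cov_names(sex)
  cv <- covariates[covariates$sex == sex & covariates$id %in% ind$id, ,
                   drop = FALSE]
  idx <- match(cv$id, ind$id)
  if (!is.null(cv$year_mid) && !all(is.na(cv$year_mid))) {
    ym <- date_to_years(cv$year_mid)
  } else {
    ym <- (bmin[idx] + bmax[idx]) / 2 + al + cv$life_year + 0.5
  }
  obs <- do.call(rbind, lapply(seq_along(covs), function(c) {
    val <- cv[[covs[c]]]
    keep <- !is.na(val)
    data.frame(ind = idx[keep], cov = c, year_mid = ym[keep],
               value = val[keep])
  }))
  if (is.null(obs)) obs <- data.frame(ind = integer(), cov = integer(),
                                      year_mid = numeric(), value = numeric())
  for (c in seq_along(covs)) {
    check(any(obs$cov == c),
          "no observed data at all for covariate %s within sex %s",
          covs[c], sex)
  }
  structure(list(
    sex = sex, alpha_s = al, out_migration = out_migration,
    n = nrow(ind), covs = covs, ncov = length(covs),
    id = ind$id, fate = ind$fate, origin = ind$origin,
    bmin = bmin, bmax = bmax, entry_y = entry, last_y = last,
    obs = obs), class = "model_data")
}

# ---- internal state machinery --------------------------------------------

# life-year grid and exposure widths under a given vector of birth dates
exposure_state <- function(data, births) {
  al <- data$alpha_s
  x_entry <- pmax(data$entry_y - births - al, 0)
  x_last <- data$last_y - births - al
  K <- ifelse(x_last > 0, floor(x_last), -1)
  ng <- as.integer(pmax(K + 1, 0))
  gi <- rep.int(seq_len(data$n), ng)
  gt <- sequence(ng) - 1L
  offset <- cumsum(c(0L, ng))[seq_len(data$n)]
  width <- pmin(gt + 1, x_last[gi]) - pmax(gt, x_entry[gi])
  width[width < 0] <- 0
  list(x_entry = x_entry, x_last = x_last, K = K, ng = ng, gi = gi, gt = gt,
       offset = offset, width = width, last_slot = offset + ng)
}

# map covariate observations onto grid slots under the current births
map_obs <- function(data, births, es) {
  t_obs <- floor(data$obs$year_mid - births[data$obs$ind] - data$alpha_s)
  valid <- t_obs >= 0 & t_obs <= es$K[data$obs$ind]
  slot <- es$offset[data$obs$ind] + t_obs + 1L
  list(t_obs = t_obs, valid = valid, slot = slot)
}

# stratified moments of observed covariates, computed under the current
# birth-date mapping: per (covariate, life-year) stratum mean/sd/min/max/count
# of raw values plus pooled z-ranges per covariate for the age-independent
# fallback. Pure lookup table: build_W() can apply it under any mapping.
z_moments <- function(data, om) {
  v <- which(om$valid)
  key <- (data$obs$cov[v] - 1L) * 1000L + as.integer(om$t_obs[v])
  val <- data$obs$value[v]
  uk <- sort(unique(key))
  f <- match(key, uk)
  cnt <- tabulate(f, length(uk))
  m <- as.vector(rowsum(val, f)) / cnt
  s <- sqrt(as.vector(rowsum((val - m[f])^2, f)) / cnt)
  sp <- split(val, f)   # numeric grouping: levels sort numerically, same as uk
  lo <- vapply(sp, min, 0)
  hi <- vapply(sp, max, 0)
  degen <- cnt < 2 | s == 0
  z <- (val - m[f]) / s[f]
  z[degen[f]] <- 0
  zlo <- ifelse(degen, 0, (lo - m) / s)
  zhi <- ifelse(degen, 0, (hi - m) / s)
  pool_lo <- pool_hi <- numeric(data$ncov)
  for (c in seq_len(data$ncov)) {
    zc <- z[data$obs$cov[v] == c]
    pool_lo[c] <- if (length(zc)) min(zc) else 0
    pool_hi[c] <- if (length(zc)) max(zc) else 0
  }
  list(keys = uk, cov = (uk %/% 1000L) + 1L, t = uk %% 1000L,
       count = cnt, m = m, s = s, zlo = zlo, zhi = zhi, degen = degen,
       pool_lo = pool_lo, pool_hi = pool_hi)
}

# look up stratum indices for (cov, t) pairs; pairs outside the observed
# strata take the nearest life-year of the same covariate (minimal
# age-independent generalization for cells a shifted birth exposes)
stratum_index <- function(zm, cov, t) {
  i <- match((cov - 1L) * 1000L + as.integer(t), zm$keys)
  un <- which(is.na(i))
  for (k in un) {
    cand <- which(zm$cov == cov[k])
    if (length(cand)) i[k] <- cand[which.min(abs(zm$t[cand] - t[k]))]
  }
  i
}

# standardized covariate matrix over the grid: observed cells get their
# z-scores under the supplied moment table, missing cells one
# truncated-normal imputation each (stratum [min, max] bounds; strata with
# count <= 1 fall back to pooling across ages)
build_W <- function(data, es, om, zm) {
  W <- matrix(NA_real_, length(es$gi), data$ncov)
  v <- which(om$valid)
  if (length(v)) {
    cv <- data$obs$cov[v]
    i <- stratum_index(zm, cv, om$t_obs[v])
    ok <- !is.na(i) & !zm$degen[pmax(i, 1L)]
    z <- ifelse(ok, (data$obs$value[v] - zm$m[pmax(i, 1L)]) / zm$s[pmax(i, 1L)], 0)
    W[cbind(om$slot[v], cv)] <- z
  }
  miss <- which(is.na(W), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    i <- stratum_index(zm, miss[, 2L], es$gt[miss[, 1L]])
    ok <- !is.na(i) & zm$count[pmax(i, 1L)] >= 2 & !zm$degen[pmax(i, 1L)]
    lo <- ifelse(ok, zm$zlo[pmax(i, 1L)], zm$pool_lo[miss[, 2L]])
    hi <- ifelse(ok, zm$zhi[pmax(i, 1L)], zm$pool_hi[miss[, 2L]])
    W[miss] <- rtruncnorm(nrow(miss), 0, 1, lo, hi)
  }
  W
}

# Per-individual marginal log-likelihood with the latent out-migration state
# integrated out (Rao-Blackwellized): the two o branches of an unknown-fate
# record are summed analytically, so parameter updates never depend on the
# sampled indicators and cannot be trapped by a mislabelled configuration.
#
# death:    -[H(x_last) - H(x_entry)] + log h(K | w_K)
# censored: -[H(x_last) - H(x_entry)]
# unknown:  -[H(x_last) - H(x_entry)]
#             + log( gp * g(x_last) + (1 - gp) * h(K | w_K) )
# gp is the per-class Bernoulli mixture weight of the two explanations of a
# disappearance; known-fate records carry no out-migration terms
marginal_ll_vec <- function(data, es, W, a, b, kappa, outm) {
  lp <- b * es$gt + as.vector(W %*% kappa)
  cum <- numeric(data$n)
  if (length(es$gi)) {
    rs <- rowsum(a * exp(lp) * es$width, es$gi)
    cum[as.integer(rownames(rs))] <- rs
  }
  ll <- -cum
  # terminal hazard at the left endpoint of the final life-year: the exact
  # density -dS/dx of the piecewise-constant discrete hazard
  log_h_last <- rep(-Inf, data$n)
  nz <- which(es$ng > 0L)
  ls <- es$last_slot[nz]
  log_h_last[nz] <- log(a) + b * es$gt[ls] +
    as.vector(W[ls, , drop = FALSE] %*% kappa)

  death <- data$fate == "death"
  ll[death] <- ll[death] + log_h_last[death]
  if (!data$out_migration) return(ll)
  unk <- which(data$fate == "unknown")
  if (length(unk)) {
    ji <- ifelse(data$origin[unk] == "immigrant", "immigrant", "natal")
    gp <- outm$gamma_prob[ji]
    g <- stats::dgamma(pmax(es$x_last[unk], 1e-12),
                       shape = outm$gam_shape[ji], rate = outm$gam_rate[ji])
    ll[unk] <- ll[unk] + log(gp * g + (1 - gp) * exp(log_h_last[unk]))
  }
  ll
}

# ---- exported sampler building blocks ------------------------------------

#' One Metropolis-Hastings update of a scalar parameter
#'
#' Gaussian random-walk proposal; for positive-domain parameters the walk is
#' on the log scale and the Jacobian ratio enters the acceptance probability.
#' Returns the current value on rejection.
#'
#' @param current current value (log-posterior must be finite there).
#' @param log_post function of one argument returning the log-posterior.
#' @param scale proposal standard deviation.
#' @param log_scale propose on the log scale (positive parameters).
#' @return list with `value`, `accepted`, and `log_post` at the returned
#'   value.
#' @export
mh_update <- function(current, log_post, scale, log_scale = FALSE) {
  lp0 <- log_post(current)
  check(is.finite(lp0), "log-posterior not finite at the current value")
  if (log_scale) {
    prop <- current * exp(scale * stats::rnorm(1))
    ratio <- log_post(prop) - lp0 + log(prop) - log(current)
  } else {
    prop <- current + scale * stats::rnorm(1)
    ratio <- log_post(prop) - lp0
  }
  if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
    list(value = prop, accepted = TRUE, log_post = lp0 + ratio)
  } else {
    list(value = current, accepted = FALSE, log_post = lp0)
  }
}

#' One Metropolis-Hastings update of an imputed birth date
#'
#' Proposes uniformly within the birth bracket and accepts against the
#' individual's likelihood (the caller's `loglik` must account for the age,
#' life-year binning and covariate-stratum shifts a new birth implies). A
#' degenerate bracket is never updated.
#'
#' @param birth_min,birth_max bracket endpoints (decimal years).
#' @param current current imputed birth (inside the bracket).
#' @param loglik function of a candidate birth returning its log-likelihood.
#' @return the new imputed birth, always inside the bracket.
#' @export
update_birth_age <- function(birth_min, birth_max, current, loglik) {
  if (birth_max - birth_min <= 0) return(current)
  prop <- stats::runif(1, birth_min, birth_max)
  r <- loglik(prop) - loglik(current)
  if (is.finite(r) && log(stats::runif(1)) < r) prop else current
}

#' Gibbs draw of latent out-migration states
#'
#' Each unknown-fate individual's indicator is drawn independently from
#' Bernoulli of its conditional posterior probability
#' ([state_posterior_prob()]); as a Gibbs step it is always accepted.
#'
#' @param prob vector of conditional probabilities of `o = 1`.
#' @return integer vector of 0/1 states.
#' @export
update_outmig_states <- function(prob) {
  check(all(prob >= 0 & prob <= 1), "state probabilities must lie in [0, 1]")
  stats::rbinom(length(prob), 1L, prob)
}

#' Truncated-normal imputation of missing covariate values
#'
#' Each missing cell is filled with one draw from a truncated normal defined
#' by its (sex, covariate, life-year) stratum's mean, standard deviation,
#' minimum and maximum; draws always lie within the stratum `[min, max]`.
#' Strata with fewer than two observed values fall back to pooling across
#' ages within sex (imputation independent of age).
#'
#' @param values long data frame `sex, covariate, life_year, value` with `NA`
#'   for missing cells.
#' @param moments [age_sex_moments()] of the observed values.
#' @return `values` with missing cells filled and a logical `imputed` column.
#' @export
impute_missing_covariates <- function(values, moments) {
  miss <- is.na(values$value)
  values$imputed <- miss
  if (!any(miss)) return(values)
  obs <- values[!miss, , drop = FALSE]
  mkey <- paste(moments$sex, moments$covariate, moments$life_year, sep = "\r")
  vkey <- paste(values$sex, values$covariate, values$life_year, sep = "\r")
  i <- match(vkey[miss], mkey)
  usable <- !is.na(i) & moments$count[pmax(i, 1L)] >= 2
  m <- moments$mean[i]; s <- moments$sd[i]
  lo <- moments$min[i]; hi <- moments$max[i]
  if (any(!usable)) {
    # age-independent fallback: pooled moments within (sex, covariate)
    pkey <- paste(values$sex, values$covariate, sep = "\r")[miss][!usable]
    pools <- split(obs$value, paste(obs$sex, obs$covariate, sep = "\r"))
    check(all(pkey %in% names(pools)),
          "no observed data at all for a covariate within a sex")
    m[!usable] <- vapply(pools[pkey], mean, 0)
    s[!usable] <- vapply(pools[pkey], pop_sd, 0)
    lo[!usable] <- vapply(pools[pkey], min, 0)
    hi[!usable] <- vapply(pools[pkey], max, 0)
  }
  values$value[miss] <- rtruncnorm(sum(miss), m, s, lo, hi)
  values
}

#' Linear-interpolation imputation of one covariate trajectory
#'
#' Alternate imputation operator: interior gaps are linearly interpolated
#' between the nearest observed life-years; leading and trailing gaps take
#' the nearest observed value (constant extrapolation).
#'
#' @param trajectory numeric vector over consecutive life-years, `NA` for
#'   missing.
#' @return the filled vector.
#' @export
impute_linear <- function(trajectory) {
  obs <- which(!is.na(trajectory))
  check(length(obs) > 0, "cannot interpolate an all-missing trajectory")
  if (length(obs) == 1L) return(rep(trajectory[obs], length(trajectory)))
  stats::approx(obs, trajectory[obs], xout = seq_along(trajectory),
                rule = 2)$y
}

# ---- the chain ------------------------------------------------------------

#' Run one MCMC chain
#'
#' Per iteration: (1) re-derive age-sex covariate moments under the current
#' imputed births, (2) impute missing covariates from truncated normals,
#' (3) Gibbs-update latent out-migration states, (4) Metropolis-Hastings
#' update of uncertain birth dates (uniform proposals within the bracket;
#' the grid is rebuilt and newly exposed cells re-imputed after acceptance),
#' (5) Metropolis-Hastings updates of `a`, `b`, `kappa` and the
#' out-migration parameters. Proposal scales adapt during burn-in only.
#'
#' @param data [assemble_model_data()] output.
#' @param config [chain_config()].
#' @param chain_seed integer seed for this chain.
#' @param prior_spec [default_prior_spec()].
#' @param init optional named list overriding initial values (`a`, `b`,
#'   `kappa`, `outm`).
#' @return list with `draws` (matrix, one row per retained iteration),
#'   `acceptance` (per parameter), `o_mean` and `birth_mean` (posterior means
#'   of the latent states), and `scales` (final proposal scales).
#' @export
run_chain <- function(data, config, chain_seed,
                      prior_spec = default_prior_spec(), init = NULL) {
  set.seed(chain_seed)
  n <- data$n
  ncov <- data$ncov
  sc <- config$proposal_scales

  uncertain <- (data$bmax - data$bmin) > 1e-8
  unknown <- data$fate == "unknown"
  ji <- ifelse(data$origin == "immigrant", "immigrant", "natal")

  # overdispersed initial values centred on a crude death-rate estimate
  es0 <- exposure_state(data, (data$bmin + data$bmax) / 2)
  crude <- (sum(data$fate == "death") + 0.5 * sum(unknown) + 1) /
    max(sum(es0$width), 1)
  a <- crude * exp(stats::rnorm(1, -0.3, 0.4))
  b <- exp(stats::rnorm(1, log(0.1), 0.4))
  kappa <- stats::rnorm(ncov, 0, 0.2)
  births <- (data$bmin + data$bmax) / 2
  births[uncertain] <- stats::runif(sum(uncertain), data$bmin[uncertain],
                                    data$bmax[uncertain])
  o <- rep(0L, n)
  o[unknown] <- stats::rbinom(sum(unknown), 1L, 0.5)
  outm <- NULL
  if (data$out_migration) {
    gp0 <- vapply(prior_spec$gp_beta, function(x) x[1] / sum(x), 0)
    outm <- outmig_params(
      gamma_prob = pmin(pmax(gp0 + stats::runif(2, -0.1, 0.1), 0.02), 0.98),
      gam_shape = vapply(prior_spec$gam_shape, function(x) x[["mu"]], 0) *
        exp(stats::rnorm(2, 0, 0.2)),
      gam_rate = vapply(prior_spec$gam_rate, function(x) x[["mu"]], 0) *
        exp(stats::rnorm(2, 0, 0.2)))
  }
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("a", "b", "kappa", "outm"))) {
      assign(nm, init[[nm]])
    }
  }

  par_names <- c("a", "b", paste0("kappa_", data$covs))
  if (data$out_migration) {
    par_names <- c(par_names,
                   "gamma_prob_natal", "gamma_prob_immigrant",
                   "gam_shape_natal", "gam_shape_immigrant",
                   "gam_rate_natal", "gam_rate_immigrant")
  }
  scalar_scales <- c(a = sc$a, b = sc$b, ab_joint = sc$a,
                     stats::setNames(rep(sc$kappa, ncov),
                                     paste0("kappa_", data$covs)))
  if (data$out_migration) {
    scalar_scales <- c(scalar_scales,
                       gamma_prob_natal = sc$gp, gamma_prob_immigrant = sc$gp,
                       gam_shape_natal = sc$gam_shape,
                       gam_shape_immigrant = sc$gam_shape,
                       gam_rate_natal = sc$gam_rate,
                       gam_rate_immigrant = sc$gam_rate,
                       gam_joint_natal = sc$gam_shape,
                       gam_joint_immigrant = sc$gam_shape)
  }
  acc_count <- stats::setNames(numeric(length(scalar_scales)),
                               names(scalar_scales))

  n_ret <- if (config$n_iter > config$burn_in)
    floor((config$n_iter - config$burn_in) / config$thin) else 0L
  if (n_ret == 0L) warning("no retained draws: n_iter does not exceed burn_in")
  draws <- matrix(NA_real_, n_ret, length(par_names),
                  dimnames = list(NULL, par_names))
  o_sum <- numeric(n); birth_sum <- numeric(n); n_acc_iters <- 0L
  ret <- 0L

  mort_prior <- function(a, b, kappa) {
    if (a <= 0 || b <= 0) return(-Inf)
    stats::dnorm(a, 0, prior_spec$a_scale, log = TRUE) +
      stats::dnorm(b, 0, prior_spec$b_scale, log = TRUE) +
      sum(stats::dnorm(kappa, 0, prior_spec$kappa_sd, log = TRUE))
  }

  for (iter in seq_len(config$n_iter)) {
    # (1)+(2) moments under current births, standardization, imputation
    es <- exposure_state(data, births)
    om <- map_obs(data, births, es)
    zm <- z_moments(data, om)
    W <- build_W(data, es, om, zm)

    # (3) Gibbs update of out-migration states
    if (data$out_migration && any(unknown)) {
      u <- which(unknown & es$ng > 0L)
      ls <- es$last_slot[u]
      h_last <- a * exp(b * es$x_last[u] +
                          as.vector(W[ls, , drop = FALSE] %*% kappa))
      g <- stats::dgamma(es$x_last[u], shape = outm$gam_shape[ji[u]],
                         rate = outm$gam_rate[ji[u]])
      gp <- outm$gamma_prob[ji[u]]
      A <- gp * g; B <- (1 - gp) * h_last   # shared S(x_last) cancels
      p <- ifelse(A + B > 0, A / (A + B), 0.5)
      o[u] <- update_outmig_states(p)
    }

    # (4) birth-age updates (vectorized over individuals; their likelihood
    # contributions are independent given the parameters and moments)
    if (any(uncertain)) {
      prop <- births
      u <- which(uncertain)
      prop[u] <- stats::runif(length(u), data$bmin[u], data$bmax[u])
      es2 <- exposure_state(data, prop)
      om2 <- map_obs(data, prop, es2)
      W2 <- build_W(data, es2, om2, zm)
      ll1 <- marginal_ll_vec(data, es, W, a, b, kappa, outm)
      ll2 <- marginal_ll_vec(data, es2, W2, a, b, kappa, outm)
      r <- ll2 - ll1
      acc <- uncertain & is.finite(r) & log(stats::runif(n)) < r
      if (any(acc)) {
        births[acc] <- prop[acc]
        es <- exposure_state(data, births)
        om <- map_obs(data, births, es)
        zm <- z_moments(data, om)
        W <- build_W(data, es, om, zm)
      }
    }

    # (5) parameter updates against the o-marginalized posterior
    outm_prior <- function(om_) {
      if (is.null(om_)) return(0)
      lp <- 0
      for (j in c("natal", "immigrant")) {
        if (om_$gamma_prob[[j]] <= 0 || om_$gamma_prob[[j]] >= 1 ||
            om_$gam_shape[[j]] <= 0 || om_$gam_rate[[j]] <= 0) return(-Inf)
        bb <- prior_spec$gp_beta[[j]]
        lp <- lp + stats::dbeta(om_$gamma_prob[[j]], bb[1], bb[2], log = TRUE) +
          stats::dnorm(om_$gam_shape[[j]], prior_spec$gam_shape[[j]][["mu"]],
                       prior_spec$gam_shape[[j]][["sd"]], log = TRUE) +
          stats::dnorm(om_$gam_rate[[j]], prior_spec$gam_rate[[j]][["mu"]],
                       prior_spec$gam_rate[[j]][["sd"]], log = TRUE)
      }
      lp
    }
    mort_total <- function(a_, b_, k_, om_ = outm) {
      pr <- mort_prior(a_, b_, k_) + outm_prior(om_)
      if (!is.finite(pr)) return(-Inf)
      sum(marginal_ll_vec(data, es, W, a_, b_, k_, om_)) + pr
    }
    cur <- mort_total(a, b, kappa)
    if (!is.finite(cur)) {
      stop(sprintf("chain diverged at iteration %d (non-finite posterior)", iter))
    }
    adapt_now <- config$adapt && iter <= config$burn_in
    bump <- function(name, accepted) {
      acc_count[name] <<- acc_count[name] + accepted
      if (adapt_now) {
        scalar_scales[name] <<-
          scalar_scales[name] * exp(0.6 / sqrt(iter) * (accepted - 0.3))
      }
    }

    prop_a <- a * exp(scalar_scales["a"] * stats::rnorm(1))
    lp <- mort_total(prop_a, b, kappa)
    if (is.finite(lp) &&
        log(stats::runif(1)) < lp - cur + log(prop_a) - log(a)) {
      a <- prop_a; cur <- lp; bump("a", 1)
    } else bump("a", 0)

    prop_b <- b * exp(scalar_scales["b"] * stats::rnorm(1))
    lp <- mort_total(a, prop_b, kappa)
    if (is.finite(lp) &&
        log(stats::runif(1)) < lp - cur + log(prop_b) - log(b)) {
      b <- prop_b; cur <- lp; bump("b", 1)
    } else bump("b", 0)

    # joint anti-correlated (a, b) move along the posterior ridge
    z <- scalar_scales["ab_joint"] * stats::rnorm(1)
    prop_a <- a * exp(z); prop_b <- b * exp(-z)
    lp <- mort_total(prop_a, prop_b, kappa)
    if (is.finite(lp) && log(stats::runif(1)) < lp - cur) {
      a <- prop_a; b <- prop_b; cur <- lp; bump("ab_joint", 1)
    } else bump("ab_joint", 0)

    for (c in seq_len(ncov)) {
      nm <- paste0("kappa_", data$covs[c])
      kp <- kappa
      kp[c] <- kappa[c] + scalar_scales[nm] * stats::rnorm(1)
      lp <- mort_total(a, b, kp)
      if (is.finite(lp) && log(stats::runif(1)) < lp - cur) {
        kappa <- kp; cur <- lp; bump(nm, 1)
      } else bump(nm, 0)
    }

    if (data$out_migration) {
      for (j in c("natal", "immigrant")) {
        nm <- paste0("gamma_prob_", j)
        cand <- outm
        cur_p <- outm$gamma_prob[[j]]
        cand$gamma_prob[[j]] <- stats::plogis(
          stats::qlogis(cur_p) + scalar_scales[nm] * stats::rnorm(1))
        lp <- mort_total(a, b, kappa, cand)
        prop_p <- cand$gamma_prob[[j]]
        ratio <- lp - cur +
          log(prop_p * (1 - prop_p)) - log(cur_p * (1 - cur_p))
        if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
          outm <- cand; cur <- lp; bump(nm, 1)
        } else bump(nm, 0)

        for (what in c("gam_shape", "gam_rate")) {
          nm <- paste0(what, "_", j)
          cand <- outm
          cand[[what]][[j]] <- outm[[what]][[j]] *
            exp(scalar_scales[nm] * stats::rnorm(1))
          lp <- mort_total(a, b, kappa, cand)
          ratio <- lp - cur + log(cand[[what]][[j]]) - log(outm[[what]][[j]])
          if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
            outm <- cand; cur <- lp; bump(nm, 1)
          } else bump(nm, 0)
        }

        # joint move along the constant-mean (shape, rate) ridge
        nm <- paste0("gam_joint_", j)
        z <- scalar_scales[nm] * stats::rnorm(1)
        cand <- outm
        cand$gam_shape[[j]] <- outm$gam_shape[[j]] * exp(z)
        cand$gam_rate[[j]] <- outm$gam_rate[[j]] * exp(z)
        lp <- mort_total(a, b, kappa, cand)
        if (is.finite(lp) && log(stats::runif(1)) < lp - cur + 2 * z) {
          outm <- cand; cur <- lp; bump(nm, 1)
        } else bump(nm, 0)
      }
    }

    if (iter > config$burn_in) {
      n_acc_iters <- n_acc_iters + 1L
      o_sum <- o_sum + o
      birth_sum <- birth_sum + births
      if ((iter - config$burn_in) %% config$thin == 0L) {
        ret <- ret + 1L
        row <- c(a, b, kappa)
        if (data$out_migration) {
          row <- c(row, outm$gamma_prob, outm$gam_shape, outm$gam_rate)
        }
        draws[ret, ] <- row
      }
    }
  }

  list(draws = draws,
       acceptance = acc_count / config$n_iter,
       o_mean = if (n_acc_iters > 0) o_sum / n_acc_iters else rep(NA_real_, n),
       birth_mean = if (n_acc_iters > 0) birth_sum / n_acc_iters else births,
       scales = scalar_scales)
}

#' Run multiple chains and collect a posterior set
#'
#' Per-chain seeds are derived deterministically from `config$seed`, so the
#' whole posterior set is reproducible bit for bit.
#'
#' @inheritParams run_chain
#' @return a `posterior_set`: per-chain draw matrices, acceptance rates,
#'   per-parameter potential scale reduction factors, and latent-state
#'   posterior means.
#' @export
run_chains <- function(data, config, prior_spec = default_prior_spec()) {
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_chain(data, config, chain_seed = config$seed + 7919L * ch, prior_spec)
  })
  par_names <- colnames(chains[[1]]$draws)
  rh <- if (length(chains) >= 2) {
    vapply(par_names, function(p) {
      rhat(lapply(chains, function(x) x$draws[, p]))
    }, 0)
  } else {
    stats::setNames(rep(NA_real_, length(par_names)), par_names)
  }
  o_mean <- rowMeans(vapply(chains, `[[`, numeric(data$n), "o_mean"))
  birth_mean <- rowMeans(vapply(chains, `[[`, numeric(data$n), "birth_mean"))
  structure(list(
    draws = lapply(chains, `[[`, "draws"),
    acceptance = vapply(chains, `[[`,
                        numeric(length(chains[[1]]$acceptance)), "acceptance"),
    rhat = rh, o_mean = o_mean, birth_mean = birth_mean,
    id = data$id, sex = data$sex, config = config),
    class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat("Posterior set:", length(x$draws), "chains x", nrow(x$draws[[1]]),
      "retained draws (sex", x$sex, ")\n")
  cat("max R-hat:", signif(max(x$rhat), 4), "\n")
  invisible(x)
}

#' Potential scale reduction factor (Gelman-Rubin R-hat)
#'
#' Classic (split-free) multi-chain diagnostic on post-burn-in draws:
#' `sqrt(((n - 1)/n * W + B/n) / W)` with within-chain variance `W` and
#' between-chain variance `B = n * var(chain means)`. Use
#' `split = TRUE` for the split-chain variant.
#'
#' @param chains list of numeric vectors (>= 2 chains, >= 2 draws each).
#' @param split halve each chain before computing (detects within-chain
#'   drift).
#' @return the statistic; `Inf` when the within-chain variance is zero.
#' @export
rhat <- function(chains, split = FALSE) {
  check(length(chains) >= 2, "need at least 2 chains")
  if (split) {
    chains <- unlist(lapply(chains, function(x) {
      h <- floor(length(x) / 2)
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
  }
  n <- min(lengths(chains))
  check(n >= 2, "need at least 2 draws per chain")
  chains <- lapply(chains, function(x) x[seq_len(n)])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary table
#'
#' Per parameter: median, central 68% and 95% credible intervals (linear
#' interpolation between order statistics), R-hat, and for each
#' proportional-hazards coefficient the hazard-effect translation
#' `100 * (1 - exp(kappa))` — the percent reduction in the mortality hazard
#' per +1 SD of the covariate (negative values are hazard increases).
#'
#' @param ps a `posterior_set` from [run_chains()].
#' @return data frame with one row per parameter.
#' @export
summarize_posterior <- function(ps) {
  pooled <- do.call(rbind, ps$draws)
  check(nrow(pooled) > 0, "no retained draws to summarize")
  qs <- function(x) stats::quantile(x, c(0.5, 0.16, 0.84, 0.025, 0.975),
                                    type = 7, names = FALSE)
  out <- do.call(rbind, lapply(colnames(pooled), function(p) {
    q <- qs(pooled[, p])
    data.frame(parameter = p, median = q[1], ci68_lo = q[2], ci68_hi = q[3],
               ci95_lo = q[4], ci95_hi = q[5], rhat = unname(ps$rhat[p]),
               effect_pct = if (startsWith(p, "kappa_"))
                 100 * (1 - exp(q[1])) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
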