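# Independent oracles and fixture builders shared across tests. These are
# deliberately written with different algorithms from the package code paths
# they check.

# closed form of the discrete left-endpoint cumulative hazard with constant
# zero covariates: geometric series over whole life-years plus the
# fractional last step
gompertz_H_closed <- function(a, b, x) {
  k <- floor(x)
  H <- if (k >= 1) a * (exp(b * k) - 1) / (exp(b) - 1) else 0
  H + a * exp(b * k) * (x - k)
}

# exhaustive minimum of wins-below-diagonal by depth-first recursion
# (independent of the package's permutation-matrix search)
oracle_min_wins <- function(wins) {
  n <- nrow(wins)
  best <- Inf
  recurse <- function(ord, rest) {
    if (length(rest) == 0L) {
      m <- wins[ord, ord, drop = FALSE]
      tot <- sum(m[lower.tri(m)])
      if (tot < best) best <<- tot
      return(invisible())
    }
    for (k in rest) recurse(c(ord, k), setdiff(rest, k))
  }
  recurse(integer(0), seq_len(n))
  best
}

# registry row builder
mk_ind <- function(id, sex, birth, entry, last, fate = "censored",
                   origin = "natal", birth_max = birth) {
  data.frame(id = id, sex = sex, birth_min = birth, birth_max = birth_max,
             entry_date = entry, last_date = last, fate = fate,
             origin = origin, stringsAsFactors = FALSE)
}

# population standard deviation (mirrors the declared convention)
psd <- function(x) sqrt(mean((x - mean(x))^2))

# a small simulated population shared by several expensive tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_females = 60, n_males = 60, study_years = 18,
                        seed = 421)
      cache <<- list(cfg = cfg, pop = simulate_population(cfg))
    }
    cache
  }
})
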