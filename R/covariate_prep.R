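# Per-individual life-year trajectories and age-sex standardization of
# covariates. Life-year t = 0 is the age class [alpha, alpha + 1); all model
# ages are real-valued years since alpha, age classes half-open [t, t + 1).

#' Adult life-year exposure of one individual
#'
#' Intersects an individual's one-year age classes (birthday to birthday) with
#' the observed adult interval `[max(entry age, alpha), exit age]`. The first
#' and last classes may be fractional: a year of life can be incomplete on the
#' left (reaching adulthood, immigrating, or onset of observation mid-year)
#' and on the right (death or censoring).
#'
#' @param birth birth date (ISO-8601 / `Date`) or decimal years.
#' @param entry,last entry and last-seen dates (same conventions).
#' @param alpha age at maturity in years (5 females, 7 males).
#' @return data frame with columns `life_year` (t = 0 is `[alpha, alpha+1)`)
#'   and `fraction` (of the year observed); zero rows if the individual exits
#'   before maturity.
#' @export
build_life_years <- function(birth, entry, last, alpha) {
  num <- function(x) if (is.numeric(x)) x else date_to_years(x)
  birth <- num(birth); entry <- num(entry); last <- num(last)
  check(entry <= last + 1e-12, "entry date after last-seen date")
  lo <- max(entry - birth, alpha) - alpha
  hi <- last - birth - alpha
  if (hi <= lo || hi <= 0) {
    return(data.frame(life_year = integer(), fraction = numeric()))
  }
  lo <- max(lo, 0)
  t <- seq.int(floor(lo), ceiling(hi) - 1L)
  frac <- pmin(t + 1, hi) - pmax(t, lo)
  keep <- frac > 1e-12
  data.frame(life_year = as.integer(t[keep]), fraction = frac[keep])
}

#' Stratified covariate moments by sex, covariate and life-year
#'
#' Mean, standard deviation (population convention), minimum, maximum and
#' count of the observed covariate values in each (sex, covariate, life-year)
#' stratum. These moments parameterize both the standardization and the
#' truncated-normal imputation inside the sampler; inside the MCMC they are
#' recomputed under the current imputed birth dates.
#'
#' @param values long data frame with columns `sex`, `covariate`, `life_year`,
#'   `value`; only observed (non-`NA`) values enter.
#' @return data frame with one row per populated stratum and columns `sex`,
#'   `covariate`, `life_year`, `mean`, `sd`, `min`, `max`, `count`.
#' @export
age_sex_moments <- function(values) {
  values <- values[!is.na(values$value), , drop = FALSE]
  if (nrow(values) == 0L) {
    return(data.frame(sex = character(), covariate = character(),
                      life_year = integer(), mean = numeric(), sd = numeric(),
                      min = numeric(), max = numeric(), count = integer()))
  }
  key <- paste(values$sex, values$covariate, values$life_year, sep = "\r")
  sp <- split(values$value, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  data.frame(
    sex = vapply(parts, `[`, "", 1L),
    covariate = vapply(parts, `[`, "", 2L),
    life_year = as.integer(vapply(parts, `[`, "", 3L)),
    mean = vapply(sp, mean, 0),
    sd = vapply(sp, pop_sd, 0),
    min = vapply(sp, min, 0),
    max = vapply(sp, max, 0),
    count = vapply(sp, length, 0L),
    row.names = NULL)
}

#' Standardize covariate values by sex and age
#'
#' Each observed value becomes its z-score within its (sex, covariate,
#' life-year) stratum, so covariates represent deviations from sex- and
#' age-typical values. Strata with zero spread or fewer than two values map
#' to 0 with a warning.
#'
#' @param values long data frame as in [age_sex_moments()].
#' @param moments output of [age_sex_moments()] computed on the same observed
#'   set.
#' @return `values` with a `z` column added (`NA` where `value` is `NA`).
#' @export
age_sex_standardize <- function(values, moments) {
  mkey <- paste(moments$sex, moments$covariate, moments$life_year, sep = "\r")
  vkey <- paste(values$sex, values$covariate, values$life_year, sep = "\r")
  i <- match(vkey, mkey)
  m <- moments$mean[i]; s <- moments$sd[i]; cnt <- moments$count[i]
  degenerate <- !is.na(values$value) & (is.na(i) | s == 0 | cnt < 2)
  z <- (values$value - m) / s
  z[degenerate] <- 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " values in degenerate strata (count < 2 or zero sd) standardized to 0")
  }
  values$z <- z
  values
}

#' @rdname age_sex_standardize
#' @param z_values output of [age_sex_standardize()]; the `z` column is mapped
#'   back to the original scale using the stored moments (identity on observed
#'   values from non-degenerate strata).
#' @export
age_sex_unstandardize <- function(z_values, moments) {
  mkey <- paste(moments$sex, moments$covariate, moments$life_year, sep = "\r")
  vkey <- paste(z_values$sex, z_values$covariate, z_values$life_year, sep = "\r")
  i <- match(vkey, mkey)
  z_values$value_back <- z_values$z * moments$sd[i] + moments$mean[i]
  z_values
}
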