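# Internal helpers shared across modules.

# Days per year used for all date <-> decimal-year conversions.
YEAR_DAYS <- 365.25

#' Convert ISO-8601 date strings to decimal years
#'
#' Dates are mapped onto a continuous time axis in units of years
#' (1970-01-01 = 0), so that age arithmetic can be done with plain
#' subtraction. The inverse is [years_to_date()].
#'
#' @param x character vector of ISO-8601 dates (or `Date`).
#' @return numeric vector of decimal years.
#' @keywords internal
date_to_years <- function(x) {
  as.numeric(as.Date(x)) / YEAR_DAYS
}

#' @rdname date_to_years
#' @keywords internal
years_to_date <- function(x) {
  as.Date(round(x * YEAR_DAYS), origin = "1970-01-01")
}

# Population (n-denominator) standard deviation. Strata of dyads or of
# observed covariate values are treated as complete populations, not samples,
# so all standardization in the package uses this convention.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Truncated-normal draws by inversion; vectorized over all arguments.
# Degenerate cases: sd = 0 collapses to the mean (clamped into [lo, hi]);
# lo = hi collapses to that point.
rtruncnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  out <- numeric(n)
  deg <- sd <= 0 | lo >= hi
  if (any(deg)) out[deg] <- pmin(pmax(mean[deg], lo[deg]), hi[deg])
  if (any(!deg)) {
    i <- which(!deg)
    plo <- stats::pnorm(lo[i], mean[i], sd[i])
    phi <- stats::pnorm(hi[i], mean[i], sd[i])
    u <- stats::runif(length(i), plo, phi)
    out[i] <- stats::qnorm(u, mean[i], sd[i])
    # inversion can overshoot in extreme tails; clamp to the support
    out[i] <- pmin(pmax(out[i], lo[i]), hi[i])
  }
  out
}

# stopifnot() with a formatted message
check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}
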