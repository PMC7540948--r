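# Social-bond (DSI) and social-status (dominance rank) covariates built from
# raw grooming and agonistic interaction records.

#' Age at maturity, by sex
#'
#' Adult analyses condition on reaching maturity: age 5 for females (around
#' menarche) and age 7 for males (the earliest age at which males hold a rank
#' among adult males). All model ages are measured in years since this age.
#'
#' @return named numeric vector `c(F = 5, M = 7)`.
#' @export
default_alpha <- function() c(F = 5, M = 7)

# Midpoint birth time (decimal years) per individual, used to bin interactions
# into life-years. Covariates are treated as data: interactions are binned once
# under the bracket midpoint, not re-binned inside the sampler.
birth_mid_years <- function(individuals) {
  bm <- (date_to_years(individuals$birth_min) + date_to_years(individuals$birth_max)) / 2
  names(bm) <- individuals$id
  bm
}

sex_lookup <- function(individuals) {
  s <- as.character(individuals$sex)
  names(s) <- individuals$id
  s
}

#' Dyadic grooming rates corrected for observation effort
#'
#' Pools grooming events within each dyad (direction ignored), assigns them to
#' the focal individual's life-years, divides by the supplied co-residency
#' effort, and mean-normalizes the resulting rates within each
#' (dyad type, life-year) stratum so the population-mean dyad has rate 1.
#'
#' The effort table defines the universe of dyad-years: dyads with positive
#' effort and zero grooming enter with rate 0. Grooming events that fall in no
#' positive-effort dyad-year are rejected with a warning. Male-male dyads are
#' excluded (adult males do not regularly groom each other in the study
#' system).
#'
#' @param grooming data frame with columns `date`, `actor`, `recipient`,
#'   `group` (ISO-8601 dates).
#' @param effort data frame with columns `id_a` (focal), `id_b` (partner),
#'   `life_year` (focal's age class, 0 = first adult year), `effort`
#'   (co-residency observation effort, > 0).
#' @param individuals individual registry (see [load_individuals()]); supplies
#'   sexes and bracket-midpoint birth dates.
#' @param alpha named ages at maturity, default [default_alpha()].
#' @return data frame with columns `focal`, `partner`, `life_year`,
#'   `dyad_type` (`"FF"` or `"FM"`), `n_events`, `effort`, `raw_rate`.
#' @export
compute_dyadic_rates <- function(grooming, effort, individuals,
                                 alpha = default_alpha()) {
  sex <- sex_lookup(individuals)
  bm <- birth_mid_years(individuals)
  if (nrow(effort) == 0L) {
    return(data.frame(focal = character(), partner = character(),
                      life_year = integer(), dyad_type = character(),
                      n_events = integer(), effort = numeric(),
                      raw_rate = numeric()))
  }
  check(all(effort$effort > 0, na.rm = TRUE) && !anyNA(effort$effort),
        "effort must be positive and non-missing for every dyad-year")

  sa <- sex[effort$id_a]; sb <- sex[effort$id_b]
  dyad_type <- ifelse(sa == "F" & sb == "F", "FF",
               ifelse(sa == "M" & sb == "M", "MM", "FM"))
  if (any(dyad_type == "MM")) {
    warning(sum(dyad_type == "MM"), " male-male dyad-years dropped (no male-male DSI)")
  }
  keep <- dyad_type != "MM"
  effort <- effort[keep, , drop = FALSE]
  dyad_type <- dyad_type[keep]

  # focal life-year window on the decimal-year axis
  w0 <- bm[effort$id_a] + alpha[sex[effort$id_a]] + effort$life_year
  w1 <- w0 + 1

  pair_of <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  gy <- date_to_years(grooming$date)
  gsplit <- split(gy, pair_of(grooming$actor, grooming$recipient))
  epair <- pair_of(effort$id_a, effort$id_b)
  n_events <- vapply(seq_len(nrow(effort)), function(i) {
    y <- gsplit[[epair[i]]]
    if (is.null(y)) 0L else sum(y >= w0[i] & y < w1[i])
  }, integer(1))

  # each grooming event can be counted once per focal (i.e. twice per pair);
  # events never covered by any focal's effort window are rejected
  covered <- logical(nrow(grooming))
  gp <- pair_of(grooming$actor, grooming$recipient)
  for (i in seq_len(nrow(effort))) {
    hit <- gp == epair[i] & gy >= w0[i] & gy < w1[i]
    covered <- covered | hit
  }
  if (any(!covered)) {
    warning(sum(!covered),
            " grooming records fall outside every positive-effort dyad-year and were rejected")
  }

  rate <- n_events / effort$effort
  stratum <- paste(dyad_type, effort$life_year)
  mean_rate <- ave(rate, stratum, FUN = mean)
  raw_rate <- ifelse(mean_rate > 0, rate / mean_rate, 0)
  if (any(mean_rate == 0)) {
    warning("strata with no grooming at all: raw rates left at 0")
  }

  data.frame(focal = effort$id_a, partner = effort$id_b,
             life_year = as.integer(effort$life_year),
             dyad_type = dyad_type, n_events = n_events,
             effort = effort$effort, raw_rate = raw_rate,
             row.names = NULL)
}

#' Standardize dyadic rates into the dyadic sociality index
#'
#' Z-score transformation of `raw_rate` within each (dyad type, life-year)
#' stratum, separately for female-female and female-male dyads, using the
#' sample (n-1 denominator) standard deviation, so `sd()` of every
#' standardized stratum is exactly 1. Strata of size 1 or with zero variance
#' yield `dsi_z = 0` with a warning.
#'
#' @param indices output of [compute_dyadic_rates()].
#' @return the same data frame with a `dsi_z` column added.
#' @export
standardize_dsi <- function(indices) {
  if (nrow(indices) == 0L) {
    indices$dsi_z <- numeric(0)
    return(indices)
  }
  stratum <- paste(indices$dyad_type, indices$life_year)
  m <- ave(indices$raw_rate, stratum, FUN = mean)
  s <- ave(indices$raw_rate, stratum,
           FUN = function(x) if (length(x) < 2) 0 else stats::sd(x))
  n <- ave(indices$raw_rate, stratum, FUN = length)
  degenerate <- n < 2 | s == 0
  z <- ifelse(degenerate, 0, (indices$raw_rate - m) / s)
  if (any(degenerate)) {
    warning("degenerate DSI strata (size 1 or zero variance) set to dsi_z = 0")
  }
  indices$dsi_z <- z
  indices
}

#' Bond strength of one focal with top grooming partners
#'
#' Mean of the `k` largest standardized DSI values among the focal's partners
#' of the given sex, within one life-year. With fewer than `k` partners the
#' mean of all of them is used; with none the covariate is missing (`NA`).
#'
#' @param indices rows of a standardized DSI table ([standardize_dsi()])
#'   restricted to the focal's life-year of interest.
#' @param focal focal individual id.
#' @param partner_sex `"F"` or `"M"`.
#' @param k number of top partners, default 3.
#' @param sex named character vector mapping id to sex.
#' @return a single numeric value, `NA` if the focal has no such partners.
#' @export
focal_bond_strength <- function(indices, focal, partner_sex, k = 3, sex) {
  check(k >= 1, "k must be >= 1")
  rows <- indices[indices$focal == focal &
                    sex[indices$partner] == partner_sex, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_real_)
  z <- sort(rows$dsi_z, decreasing = TRUE)
  mean(z[seq_len(min(k, length(z)))])
}

# DSI covariates for every focal and life-year present in the standardized
# index table: DSI_F and DSI_M for females, DSI_F only for males.
dsi_covariates <- function(indices, individuals, k = 3) {
  sex <- sex_lookup(individuals)
  if (nrow(indices) == 0L) {
    return(data.frame(id = character(), life_year = integer(),
                      dsi_f = numeric(), dsi_m = numeric()))
  }
  keys <- unique(indices[, c("focal", "life_year")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    id <- keys$focal[i]; ly <- keys$life_year[i]
    sub <- indices[indices$focal == id & indices$life_year == ly, , drop = FALSE]
    dsi_f <- focal_bond_strength(sub, id, "F", k, sex)
    dsi_m <- if (sex[id] == "F") focal_bond_strength(sub, id, "M", k, sex) else NA_real_
    data.frame(id = id, life_year = ly, dsi_f = dsi_f, dsi_m = dsi_m)
  })
  do.call(rbind, out)
}

#' Build a pairwise win matrix from decided agonistic interactions
#'
#' @param agonism data frame with columns `winner`, `loser` (and optionally
#'   `decided`, in which case undecided rows are dropped).
#' @param ids optional id universe; defaults to all ids appearing.
#' @return square integer matrix, entry (i, j) = wins of i over j.
#' @export
build_rank_matrix <- function(agonism, ids = NULL) {
  if (!is.null(agonism$decided)) {
    agonism <- agonism[as.logical(agonism$decided), , drop = FALSE]
  }
  if (is.null(ids)) ids <- sort(unique(c(agonism$winner, agonism$loser)))
  n <- length(ids)
  w <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(agonism) > 0L) {
    tab <- table(factor(agonism$winner, ids), factor(agonism$loser, ids))
    w <- w + unclass(tab)
    dimnames(w) <- list(ids, ids)
  }
  diag(w) <- 0L
  w
}

# wins strictly below the diagonal after reordering rows/cols by `ord`
wins_below_diagonal <- function(wins, ord) {
  m <- wins[ord, ord, drop = FALSE]
  sum(m[lower.tri(m)])
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 only
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- k
    rest <- seq_len(n)[-k]
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Ordinal dominance ranks by minimizing wins below the diagonal
#'
#' Finds an ordering of individuals whose reordered win matrix minimizes the
#' total number of wins below the diagonal (losses of higher- to lower-ranked
#' animals). For groups of up to 8 the optimum is found by exhaustive search
#' over all orderings; for larger groups by iterative pairwise-swap descent
#' started from the previous month's ordering (or from wins-minus-losses
#' order), which never returns a worse total than its start.
#'
#' Ties among minimizing orderings are broken by smallest total rank
#' displacement from `previous`, then by lexicographic id order, making the
#' result deterministic and stable across months.
#'
#' @param wins square win matrix with id dimnames ([build_rank_matrix()]).
#' @param previous optional previous ordering (character vector of ids,
#'   top first) used for warm starts and tie-breaking.
#' @return list with `order` (ids, rank 1 = top), `ordinal` (named integer
#'   ranks) and `objective` (wins below the diagonal).
#' @export
ordinal_ranks <- function(wins, previous = NULL) {
  ids <- rownames(wins)
  n <- length(ids)
  check(n >= 1, "empty rank matrix")
  check(all(wins >= 0) && all(diag(wins) == 0),
        "win matrix must be non-negative with zero diagonal")
  if (n == 1L) {
    return(list(order = ids, ordinal = stats::setNames(1L, ids), objective = 0))
  }

  prev_pos <- rep(NA_real_, n)
  if (!is.null(previous)) {
    prev_pos <- match(ids, previous)
  }

  if (n <= 8L) {
    perms <- all_perms(n)
    obj <- numeric(nrow(perms))
    for (i in seq_len(n)) {        # objective as a sum over below-diagonal pairs
      for (j in seq_len(n)) {
        if (i > j) obj <- obj + wins[cbind(perms[, i], perms[, j])]
      }
    }
    best <- which(obj == min(obj))
    cand <- perms[best, , drop = FALSE]
    if (length(best) > 1L) {
      disp <- apply(cand, 1L, function(p) {
        pos <- order(p)  # pos[id index] = rank
        d <- abs(pos - prev_pos)
        sum(d, na.rm = TRUE)
      })
      cand <- cand[disp == min(disp), , drop = FALSE]
      if (nrow(cand) > 1L) {
        key <- apply(cand, 1L, function(p) paste(ids[p], collapse = "\r"))
        cand <- cand[order(key)[1L], , drop = FALSE]
      }
    }
    ord <- cand[1L, ]
  } else {
    if (!is.null(previous)) {
      start_ids <- c(intersect(previous, ids), setdiff(ids, previous))
      ord <- match(start_ids, ids)
      # new ids appended in wins-minus-losses order
    } else {
      score <- rowSums(wins) - colSums(wins)
      ord <- order(-score, ids)
    }
    # insertion-move descent: repeatedly move one individual to the position
    # that lowers the objective most. Insertion deltas aggregate wins over
    # every pair crossed, so sparse matrices (dyads that never met) do not
    # strand the search the way single swaps do; only strictly improving
    # moves are taken, so the result is never worse than the start.
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        o <- ord[i]
        others <- ord[-i]
        diffs <- wins[o, others] - wins[others, o]
        S <- c(0, cumsum(diffs))            # S[k+1]: o placed after k others
        delta <- S - S[i]
        k_best <- which.min(delta)
        if (delta[k_best] < -1e-9) {
          ord <- append(others, o, after = k_best - 1L)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }

  order_ids <- ids[ord]
  ordinal <- stats::setNames(match(ids, order_ids), ids)
  list(order = order_ids, ordinal = ordinal,
       objective = wins_below_diagonal(wins, ord))
}

#' Proportional dominance rank
#'
#' Fraction of same-sex adults in the group dominated by the focal:
#' `(n - r) / (n - 1)`, 1 for the top-ranked and 0 for the bottom-ranked
#' animal. With a single adult (`n = 1`) the quantity is undefined and `NA`
#' is returned (the imputation layer handles it).
#'
#' @param r ordinal rank(s), 1 = top.
#' @param n group size(s).
#' @return numeric in \[0, 1\], or `NA` when `n = 1`.
#' @export
proportional_rank <- function(r, n) {
  check(all(r >= 1 & r <= n), "ordinal rank outside 1..n: corrupted ordering")
  out <- (n - r) / (n - 1)
  out[rep_len(n, length(out)) == 1] <- NA_real_
  out
}

#' Mean of monthly proportional ranks within a life-year
#'
#' @param monthly numeric vector of monthly proportional ranks (may be shorter
#'   than 12 for partial life-years).
#' @return arithmetic mean of the available values; `NA` if empty.
#' @export
annual_rank <- function(monthly) {
  monthly <- monthly[!is.na(monthly)]
  if (length(monthly) == 0L) return(NA_real_)
  mean(monthly)
}

# Monthly proportional ranks per (group, sex): individuals appearing in a
# month's decided same-sex contests are ranked by ordinal_ranks() with the
# previous month's ordering as warm start / tie-break.
monthly_ranks <- function(agonism, individuals) {
  sex <- sex_lookup(individuals)
  if (!is.null(agonism$decided)) {
    agonism <- agonism[as.logical(agonism$decided), , drop = FALSE]
  }
  same <- sex[agonism$winner] == sex[agonism$loser]
  if (any(!same)) warning(sum(!same), " mixed-sex agonistic records dropped")
  agonism <- agonism[same, , drop = FALSE]
  if (nrow(agonism) == 0L) {
    return(data.frame(id = character(), group = character(), sex = character(),
                      month = character(), month_mid = numeric(),
                      ordinal = integer(), n = integer(), prop_rank = numeric()))
  }
  agonism$month <- format(as.Date(agonism$date), "%Y-%m")
  agonism$sex <- sex[agonism$winner]
  cells <- unique(agonism[, c("group", "sex", "month")])
  cells <- cells[order(cells$group, cells$sex, cells$month), , drop = FALSE]
  prev <- list()
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sub <- agonism[agonism$group == cl$group & agonism$sex == cl$sex &
                     agonism$month == cl$month, , drop = FALSE]
    wins <- build_rank_matrix(sub)
    key <- paste(cl$group, cl$sex)
    ra <- ordinal_ranks(wins, previous = prev[[key]])
    prev[[key]] <- ra$order
    n <- length(ra$order)
    mid <- date_to_years(as.Date(paste0(cl$month, "-15")))
    out[[i]] <- data.frame(id = names(ra$ordinal), group = cl$group,
                           sex = cl$sex, month = cl$month, month_mid = mid,
                           ordinal = as.integer(ra$ordinal), n = n,
                           prop_rank = proportional_rank(as.integer(ra$ordinal), n),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

# Annual rank covariate: mean of the monthly proportional ranks falling in
# each life-year of the focal (bracket-midpoint birth).
rank_covariates <- function(monthly, individuals, alpha = default_alpha()) {
  if (nrow(monthly) == 0L) {
    return(data.frame(id = character(), life_year = integer(),
                      prop_rank = numeric()))
  }
  bm <- birth_mid_years(individuals)
  sex <- sex_lookup(individuals)
  ly <- floor(monthly$month_mid - bm[monthly$id] - alpha[sex[monthly$id]])
  keep <- !is.na(ly) & ly >= 0
  monthly <- monthly[keep, , drop = FALSE]; ly <- ly[keep]
  key <- paste(monthly$id, ly, sep = "\r")
  agg <- tapply(monthly$prop_rank, key, annual_rank)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1L),
             life_year = as.integer(vapply(parts, `[`, "", 2L)),
             prop_rank = as.numeric(agg), row.names = NULL)
}

#' Full covariate table from raw interaction records
#'
#' Runs the metrics stage end to end: dyadic grooming rates, DSI
#' standardization, top-`k` bond strengths, monthly dominance hierarchies and
#' annual proportional ranks, merged into one table of per-individual,
#' per-life-year covariates.
#'
#' @inheritParams compute_dyadic_rates
#' @param agonism data frame with columns `date`, `winner`, `loser`, `group`,
#'   `decided`.
#' @param k top-partner count for DSI covariates, default 3.
#' @return data frame `id, sex, life_year, dsi_f, dsi_m, prop_rank` with `NA`
#'   for missing values (males have no `dsi_m`).
#' @export
interaction_covariates <- function(grooming, agonism, effort, individuals,
                                   k = 3, alpha = default_alpha()) {
  idx <- standardize_dsi(compute_dyadic_rates(grooming, effort, individuals, alpha))
  dsi <- dsi_covariates(idx, individuals, k)
  rnk <- rank_covariates(monthly_ranks(agonism, individuals), individuals, alpha)
  cov <- merge(dsi, rnk, by = c("id", "life_year"), all = TRUE)
  sex <- sex_lookup(individuals)
  cov$sex <- sex[cov$id]
  cov[order(cov$id, cov$life_year),
      c("id", "sex", "life_year", "dsi_f", "dsi_m", "prop_rank")]
}
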