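# Dyadic sociality index construction and dominance-rank ordering.

inds3 <- rbind(
  mk_ind("A", "F", "2000-01-01", "2005-01-01", "2012-01-01"),
  mk_ind("B", "F", "2000-01-01", "2005-01-01", "2012-01-01"),
  mk_ind("C", "F", "2000-01-01", "2005-01-01", "2012-01-01"),
  mk_ind("D", "F", "2000-01-01", "2005-01-01", "2012-01-01"))

# grooming events for a dyad inside the focal's life-year ly
groom_events <- function(a, b, n, year = "2005") {
  if (n == 0) return(NULL)
  data.frame(date = sprintf("%s-06-%02d", year, seq_len(n)),
             actor = a, recipient = b, group = 1)
}

test_that("dyadic rates are effort-corrected and mean-normalized", {
  # dyad with 6 events over effort 2 where the same-type mean rate is 1.5
  groom <- groom_events("A", "B", 6)
  eff <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"),
                    life_year = 0L, effort = c(2, 2))
  r <- compute_dyadic_rates(groom, eff, inds3)
  expect_equal(r$raw_rate[r$focal == "A"], 2.0)   # (6/2) / 1.5
  expect_equal(r$raw_rate[r$focal == "C"], 0)

  # counts {4, 2, 0} at equal effort 1 -> rates {2, 1, 0} after normalization
  groom <- rbind(groom_events("A", "B", 4), groom_events("A", "C", 2))
  eff <- data.frame(id_a = "A", id_b = c("B", "C", "D"),
                    life_year = 0L, effort = 1)
  r <- compute_dyadic_rates(groom, eff, inds3)
  expect_equal(r$raw_rate, c(2, 1, 0))

  # identical counts and efforts -> all rates exactly 1
  groom <- rbind(groom_events("A", "B", 3), groom_events("C", "D", 3))
  eff <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"),
                    life_year = 0L, effort = 1)
  expect_equal(compute_dyadic_rates(groom, eff, inds3)$raw_rate, c(1, 1))
})

test_that("grooming outside any effort window is rejected with a warning", {
  groom <- rbind(groom_events("A", "B", 2),
                 data.frame(date = "2011-06-01", actor = "A",
                            recipient = "B", group = 1))
  eff <- data.frame(id_a = "A", id_b = "B", life_year = 0L, effort = 1)
  expect_warning(r <- compute_dyadic_rates(groom, eff, inds3), "rejected")
  expect_equal(r$n_events, 2L)
})

test_that("DSI standardization uses the sample sd per stratum", {
  idx <- data.frame(focal = "A", partner = c("B", "C", "D"),
                    life_year = 0L, dyad_type = "FF",
                    n_events = 0L, effort = 1, raw_rate = c(2, 1, 0))
  z <- standardize_dsi(idx)$dsi_z
  expect_equal(z, c(1, 0, -1), tolerance = 1e-12)

  idx2 <- idx[1:2, ]; idx2$raw_rate <- c(5, 1)
  z2 <- standardize_dsi(idx2)$dsi_z
  expect_equal(z2, c(0.7071068, -0.7071068), tolerance = 1e-6)

  idx$raw_rate <- c(3, 3, 3)
  expect_warning(z3 <- standardize_dsi(idx)$dsi_z, "degenerate")
  expect_equal(z3, c(0, 0, 0))
})

test_that("standardized strata have mean 0 and sd 1 within 1e-9", {
  set.seed(5)
  idx <- data.frame(focal = "A",
                    partner = sprintf("P%02d", 1:40),
                    life_year = rep(0:3, each = 10),
                    dyad_type = rep(c("FF", "FM"), 20),
                    n_events = 0L, effort = 1,
                    raw_rate = rexp(40))
  z <- standardize_dsi(idx)
  for (s in split(z$dsi_z, paste(z$dyad_type, z$life_year))) {
    expect_lt(abs(mean(s)), 1e-9)
    expect_lt(abs(sd(s) - 1), 1e-9)
  }
})

test_that("focal bond strength averages the top k partners", {
  sex <- c(A = "F", P1 = "F", P2 = "F", P3 = "F", P4 = "F", M1 = "M")
  idx <- data.frame(focal = "A", partner = c("P1", "P2", "P3", "P4"),
                    dsi_z = c(2, 1, 0.5, -1))
  expect_equal(focal_bond_strength(idx, "A", "F", 3, sex),
               (2 + 1 + 0.5) / 3)
  expect_equal(focal_bond_strength(idx[2, ], "A", "F", 3, sex), 1)   # m < k
  expect_true(is.na(focal_bond_strength(idx, "A", "M", 3, sex)))     # m = 0
})

test_that("grooming direction is pooled: swapping actor/recipient changes nothing", {
  set.seed(9)
  groom <- rbind(groom_events("A", "B", 5), groom_events("C", "A", 3),
                 groom_events("B", "C", 2))
  eff <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                    life_year = 0L, effort = c(1, 2, 1))
  r1 <- standardize_dsi(compute_dyadic_rates(groom, eff, inds3))
  swapped <- groom
  names(swapped)[names(swapped) == "actor"] <- "tmp"
  names(swapped)[names(swapped) == "recipient"] <- "actor"
  names(swapped)[names(swapped) == "tmp"] <- "recipient"
  r2 <- standardize_dsi(compute_dyadic_rates(swapped, eff, inds3))
  expect_equal(r1$dsi_z, r2$dsi_z)
  expect_equal(r1$raw_rate, r2$raw_rate)
})

test_that("ordinal ranks minimize wins below the diagonal", {
  # perfectly transitive triad
  w <- build_rank_matrix(data.frame(
    winner = c(rep("A", 5), rep("A", 3), rep("B", 2)),
    loser = c(rep("B", 5), rep("C", 3), rep("C", 2))))
  r <- ordinal_ranks(w)
  expect_equal(r$order, c("A", "B", "C"))
  expect_equal(r$objective, 0)

  # single individual
  w1 <- matrix(0L, 1, 1, dimnames = list("Z", "Z"))
  expect_equal(ordinal_ranks(w1)$ordinal, c(Z = 1L))

  # cyclic triad: best achievable is 1, equal to the exhaustive minimum
  w <- build_rank_matrix(data.frame(
    winner = c(rep("A", 3), rep("B", 3), "C"),
    loser = c(rep("B", 3), rep("C", 3), "A")))
  r <- ordinal_ranks(w)
  expect_equal(r$objective, 1)
  expect_equal(r$objective, oracle_min_wins(w))
})

test_that("ordinal ranks match the exhaustive oracle and ignore id order", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    w <- matrix(rpois(n * n, 1.2), n, n,
                dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    diag(w) <- 0L
    r <- ordinal_ranks(w)
    expect_equal(r$objective, oracle_min_wins(w))
    perm <- sample(n)
    r2 <- ordinal_ranks(w[perm, perm])
    expect_equal(r2$objective, r$objective)
  }
})

test_that("swap-descent handles large groups and never worsens its start", {
  set.seed(3)
  n <- 12
  w <- matrix(rpois(n * n, 1), n, n,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n)))
  diag(w) <- 0L
  score <- rowSums(w) - colSums(w)
  start <- rownames(w)[order(-score, rownames(w))]
  start_obj <- {
    m <- w[start, start]
    sum(m[lower.tri(m)])
  }
  r <- ordinal_ranks(w)
  expect_lte(r$objective, start_obj)
  # warm start from a previous ordering also never worsens
  prev <- sample(rownames(w))
  m <- w[prev, prev]
  expect_lte(ordinal_ranks(w, previous = prev)$objective,
             sum(m[lower.tri(m)]))
})

test_that("proportional rank maps ordinals onto [0, 1]", {
  expect_equal(proportional_rank(1, 5), 1.0)
  expect_equal(proportional_rank(5, 5), 0.0)
  expect_equal(proportional_rank(3, 5), 0.5)
  expect_true(is.na(proportional_rank(1, 1)))
  expect_error(proportional_rank(6, 5), "corrupted")
  # strictly decreasing in r; mean over a full group is 0.5
  for (n in 2:6) {
    p <- proportional_rank(seq_len(n), n)
    expect_true(all(diff(p) < 0))
    expect_equal(mean(p), 0.5)
  }
})

test_that("annual rank averages available months", {
  expect_equal(annual_rank(c(0.5, 0.7, 0.9)), 0.7)
  expect_equal(annual_rank(1.0), 1.0)
  expect_true(is.na(annual_rank(numeric(0))))
})

test_that("the metrics stage produces a merged covariate table", {
  groom <- rbind(groom_events("A", "B", 4), groom_events("A", "C", 2))
  eff <- data.frame(id_a = c("A", "A", "B", "B", "C", "C"),
                    id_b = c("B", "C", "A", "C", "A", "B"),
                    life_year = 0L, effort = 1)
  agon <- data.frame(date = "2005-06-10",
                     winner = c("A", "A", "B"), loser = c("B", "C", "C"),
                     group = 1, decided = TRUE)
  cov <- interaction_covariates(groom, agon, eff, inds3)
  expect_setequal(names(cov),
                  c("id", "sex", "life_year", "dsi_f", "dsi_m", "prop_rank"))
  expect_equal(cov$prop_rank[cov$id == "A"], 1.0)
  expect_equal(cov$prop_rank[cov$id == "C"], 0.0)
})
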