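# File formats, validation, and orchestration of the full workflow:
# simulate/ingest -> metrics -> prep -> fit -> diagnose -> report.
# All tables are delimited text (CSV, UTF-8, header row, ISO-8601 dates).

#' Load and validate an individual registry
#'
#' Expected columns: `id, sex, birth_min, birth_max, entry_date, last_date,
#' fate, origin`. Violations of the record invariants
#' (`birth_min <= birth_max <= entry_date <= last_date`, known fate levels,
#' `fate = "unknown"` only for sexes with out-migration enabled) are rejected
#' with row-numbered messages; a summary of counts by sex and fate is
#' reported.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param out_migration_sexes sexes for which unknown fates are admissible.
#' @param quiet suppress the summary message.
#' @return validated registry data frame.
#' @export
load_individuals <- function(path, out_migration_sexes = "M", quiet = FALSE) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "birth_min", "birth_max", "entry_date", "last_date",
            "fate", "origin")
  missing_cols <- setdiff(need, names(df))
  check(length(missing_cols) == 0, "missing columns: %s",
        paste(missing_cols, collapse = ", "))
  parse_date <- function(col) {
    d <- as.Date(df[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df[[col]]) & df[[col]] != "")
    check(length(bad) == 0, "unparseable %s at rows: %s", col,
          paste(utils::head(bad, 5), collapse = ", "))
    d
  }
  bmin <- parse_date("birth_min"); bmax <- parse_date("birth_max")
  entry <- parse_date("entry_date"); last <- parse_date("last_date")
  bad <- which(bmin > bmax)
  check(length(bad) == 0, "birth_min > birth_max at rows: %s",
        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(bmax > entry | entry > last)
  check(length(bad) == 0,
        "dates violate birth_max <= entry_date <= last_date at rows: %s",
        paste(utils::head(bad, 5), collapse = ", "))
  check(all(df$fate %in% c("death", "censored", "unknown")),
        "fate must be one of death/censored/unknown")
  check(all(df$sex %in% c("F", "M")), "sex must be F or M")
  check(all(df$origin %in% c("natal", "immigrant")),
        "origin must be natal or immigrant")
  bad <- which(df$fate == "unknown" & !(df$sex %in% out_migration_sexes))
  check(length(bad) == 0,
        "fate 'unknown' for a sex without out-migration at rows: %s",
        paste(utils::head(bad, 5), collapse = ", "))
  check(!anyDuplicated(df$id), "duplicated individual ids")
  if (!quiet) {
    tal <- table(df$sex, df$fate)
    message("loaded ", nrow(df), " individuals; fate tallies:\n",
            paste(utils::capture.output(print(tal)), collapse = "\n"))
  }
  df
}

#' Load interaction records
#'
#' @param path CSV path or data frame.
#' @param kind `"grooming"` (columns `date, actor, recipient, group`) or
#'   `"agonism"` (`date, winner, loser, group, decided`).
#' @return validated data frame.
#' @export
load_interactions <- function(path, kind = c("grooming", "agonism")) {
  kind <- match.arg(kind)
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (kind == "grooming") c("date", "actor", "recipient", "group")
          else c("date", "winner", "loser", "group", "decided")
  missing_cols <- setdiff(need, names(df))
  check(length(missing_cols) == 0, "missing columns: %s",
        paste(missing_cols, collapse = ", "))
  check(!any(is.na(as.Date(df$date, format = "%Y-%m-%d"))),
        "unparseable dates in %s records", kind)
  pair <- if (kind == "grooming") cbind(df$actor, df$recipient)
          else cbind(df$winner, df$loser)
  check(!any(pair[, 1] == pair[, 2]), "self-interaction records present")
  df
}

#' Read and write covariate tables
#'
#' The covariate table has columns `id, sex, life_year, dsi_f, dsi_m,
#' prop_rank` (empty fields for missing) plus an optional `year_mid` calendar
#' anchor emitted by the simulator. Writers and readers round-trip exactly.
#'
#' @param covariates covariate data frame.
#' @param path CSV path.
#' @return `read_covariates()`: the data frame.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (c in intersect(c("dsi_f", "dsi_m", "prop_rank"), names(df))) {
    df[[c]] <- as.numeric(df[[c]])
  }
  df
}

#' Cohort composition tallies
#'
#' Counts and percentages of departures by death, right-censoring and
#' disappearance with unknown fate, per sex, plus the share of subjects with
#' known (point) birth dates.
#'
#' @param individuals registry data frame.
#' @return list with a per-sex data frame `by_sex` (counts and percentages)
#'   and `known_birth` (count, total, percent).
#' @export
cohort_composition <- function(individuals) {
  by_sex <- do.call(rbind, lapply(split(individuals, individuals$sex),
                                  function(d) {
    n <- nrow(d)
    data.frame(sex = d$sex[1], n = n,
               n_death = sum(d$fate == "death"),
               n_censored = sum(d$fate == "censored"),
               n_unknown = sum(d$fate == "unknown"),
               pct_death = 100 * sum(d$fate == "death") / n,
               pct_censored = 100 * sum(d$fate == "censored") / n,
               pct_unknown = 100 * sum(d$fate == "unknown") / n)
  }))
  rownames(by_sex) <- NULL
  known <- sum(individuals$birth_min == individuals$birth_max)
  list(by_sex = by_sex,
       known_birth = list(count = known, total = nrow(individuals),
                          pct = 100 * known / nrow(individuals)))
}

#' Run configuration for the full pipeline
#'
#' @param individuals,covariates registry and covariate tables (paths or data
#'   frames); `covariates` may be `NULL` when raw interaction tables are
#'   given instead.
#' @param grooming,agonism,effort optional raw interaction inputs; when all
#'   three are supplied the metrics stage builds the covariate table.
#' @param chain_cfg [chain_config()].
#' @param prior_spec [default_prior_spec()].
#' @param imputation `"truncated_normal"` (within-sampler, the full model) or
#'   `"linear"` (alternate deterministic interpolation applied before
#'   fitting).
#' @param alpha ages at maturity (female 5, male 7).
#' @param sexes which sexes to fit.
#' @param out_dir output directory for posterior draws, summaries and the
#'   run manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(individuals, covariates = NULL, grooming = NULL,
                       agonism = NULL, effort = NULL,
                       chain_cfg = chain_config(),
                       prior_spec = default_prior_spec(),
                       imputation = c("truncated_normal", "linear"),
                       alpha = default_alpha(), sexes = c("F", "M"),
                       out_dir = tempfile("socmort_run_")) {
  imputation <- match.arg(imputation)
  check(!is.null(covariates) ||
          (!is.null(grooming) && !is.null(agonism) && !is.null(effort)),
        "supply either a covariate table or raw interaction tables")
  structure(list(individuals = individuals, covariates = covariates,
                 grooming = grooming, agonism = agonism, effort = effort,
                 chain_cfg = chain_cfg, prior_spec = prior_spec,
                 imputation = imputation, alpha = alpha, sexes = sexes,
                 out_dir = out_dir), class = "run_config")
}

# deterministic pre-fill of interior covariate gaps by linear interpolation
# (the alternate imputation route); remaining cells stay missing and are
# handled by the within-sampler imputation as usual
apply_linear_imputation <- function(covariates) {
  out <- covariates
  for (cn in c("dsi_f", "dsi_m", "prop_rank")) {
    sp <- split(seq_len(nrow(out)), out$id)
    for (rows in sp) {
      rows <- rows[order(out$life_year[rows])]
      v <- out[[cn]][rows]
      if (all(is.na(v)) || !any(is.na(v))) next
      out[[cn]][rows] <- impute_linear(v)
    }
  }
  out
}

#' Run the full workflow
#'
#' Executes metrics (if raw interactions are supplied), covariate prep,
#' per-sex MCMC fits, convergence diagnosis and reporting. Writes per-sex
#' posterior draws (`posterior_<sex>.csv`, one row per retained draw with
#' chain and iteration columns), summary tables (`summary_<sex>.csv`:
#' median, 68% and 95% credible intervals, R-hat, hazard-effect percent) and
#' a JSON run manifest echoing the seed and configuration. Warns if any
#' R-hat exceeds 1.1.
#'
#' @param cfg [run_config()].
#' @return list with per-sex `posterior_set`s, summary tables, and the
#'   manifest, invisibly; side effect: files under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  individuals <- load_individuals(cfg$individuals, quiet = TRUE)
  if (!is.null(cfg$covariates)) {
    covariates <- if (is.data.frame(cfg$covariates)) cfg$covariates else
      read_covariates(cfg$covariates)
  } else {
    covariates <- interaction_covariates(
      load_interactions(cfg$grooming, "grooming"),
      load_interactions(cfg$agonism, "agonism"),
      if (is.data.frame(cfg$effort)) cfg$effort else
        utils::read.csv(cfg$effort, stringsAsFactors = FALSE),
      individuals, alpha = cfg$alpha)
  }
  if (cfg$imputation == "linear") {
    covariates <- apply_linear_imputation(covariates)
  }

  fits <- list(); summaries <- list()
  for (s in cfg$sexes) {
    data <- assemble_model_data(individuals, covariates, s, cfg$alpha)
    ps <- run_chains(data, cfg$chain_cfg, cfg$prior_spec)
    fits[[s]] <- ps
    summaries[[s]] <- summarize_posterior(ps)
    write_posterior(ps, file.path(cfg$out_dir, paste0("posterior_", s, ".csv")))
    utils::write.csv(summaries[[s]],
                     file.path(cfg$out_dir, paste0("summary_", s, ".csv")),
                     row.names = FALSE)
    bad <- ps$rhat[ps$rhat > 1.1]
    if (length(bad)) {
      warning("sex ", s, ": R-hat > 1.1 for ",
              paste(names(bad), collapse = ", "))
    }
  }

  manifest <- list(
    seed = cfg$chain_cfg$seed,
    chains = cfg$chain_cfg$n_chains, n_iter = cfg$chain_cfg$n_iter,
    burn_in = cfg$chain_cfg$burn_in, thin = cfg$chain_cfg$thin,
    imputation = cfg$imputation, sexes = cfg$sexes,
    alpha = as.list(cfg$alpha),
    n_individuals = nrow(individuals),
    package_version = as.character(utils::packageVersion("socmort")),
    max_rhat = vapply(fits, function(f) max(f$rhat), 0))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, summaries = summaries, manifest = manifest,
                 out_dir = cfg$out_dir))
}

#' Write posterior draws as delimited text
#'
#' One row per retained draw with `chain` and `iter` columns followed by the
#' parameters; deterministic, so identical seeds give byte-identical files.
#'
#' @param ps a `posterior_set`.
#' @param path CSV path.
#' @export
write_posterior <- function(ps, path) {
  rows <- do.call(rbind, lapply(seq_along(ps$draws), function(ch) {
    d <- ps$draws[[ch]]
    cbind(data.frame(chain = ch, iter = seq_len(nrow(d))), as.data.frame(d))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
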