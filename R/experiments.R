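#' Configuration for one simulated condition
#'
#' A scenario bundles the cohort size, replication, seeding and all
#' generative parameters of one experimental condition. Replicate `r` uses
#' the deterministic seed ladder `stage_seed(base_seed, r, stage)` — see
#' [stage_seed()] — so every run is exactly reproducible and stages are
#' independently seeded.
#'
#' @param n cohort size per replicate (default 1,000,000).
#' @param replicates number of replicates (default 10).
#' @param base_seed integer base seed.
#' @param q carrier frequency (default 0.59).
#' @param RR carrier risk ratio.
#' @param F overall case-fatality fraction among incident cases (0 = no
#'   fatal-case exclusion).
#' @param d fatality differential between genotypes.
#' @param s statin-use fraction.
#' @param e fraction of carrier excess risk eliminated by statin.
#' @param adjust_for_statin include statin as a covariate in the default fit.
#' @param fatality_convention `"mean_relative"` or `"relative"`, see
#'   [solve_fatality_rates()].
#' @return a `scenario_config` (also a `risk_config`).
#' @examples
#' scenario_config(RR = 1.25, F = 0.415, d = 0.2, n = 1e5, replicates = 5)
#' @export
scenario_config <- function(n = 1e6, replicates = 10, base_seed = 1,
                            q = 0.59, RR = 1.5, F = 0, d = 0,
                            s = 0, e = 1, adjust_for_statin = FALSE,
                            fatality_convention = c("mean_relative",
                                                    "relative")) {
  fatality_convention <- match.arg(fatality_convention)
  rc <- risk_config(q = q, RR = RR, s = s, e = e)
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) {
    stop("n must be >= 1", call. = FALSE)
  }
  if (!(is.numeric(replicates) && length(replicates) == 1 && replicates >= 1)) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  if (!(F >= 0 && F < 1)) stop("F must be in [0, 1)", call. = FALSE)
  if (!(d >= 0 && d < 1)) stop("d must be in [0, 1)", call. = FALSE)
  solve_fatality_rates(F, d, q, fatality_convention)  # fail fast if infeasible
  structure(
    c(rc, list(n = as.integer(n), replicates = as.integer(replicates),
               base_seed = as.integer(base_seed), F = F, d = d,
               adjust_for_statin = isTRUE(adjust_for_statin),
               fatality_convention = fatality_convention)),
    class = c("scenario_config", "risk_config")
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: n=", x$n, " x ", x$replicates, " replicates, seed ",
      x$base_seed, "\n  q=", x$q, " RR=", x$RR, " F=", x$F, " d=", x$d,
      " s=", x$s, " e=", x$e,
      if (x$adjust_for_statin) " (statin covariate)", "\n", sep = "")
  invisible(x)
}

condition_label <- function(cfg) {
  sprintf("RR=%g F=%g d=%g s=%g e=%g", cfg$RR, cfg$F, cfg$d, cfg$s, cfg$e)
}

#' Run one simulated condition: replicate loop, fits, pooling
#'
#' Executes the full pipeline per replicate — population, genotype, statin,
#' risk, events, fatal-case exclusion, logistic fit — and pools the carrier
#' odds ratios. When `fit_both_statin = TRUE` each replicate is fitted twice
#' on the same data, with and without the statin covariate, to probe whether
#' covariate adjustment recovers the undiluted OR (it does not, because the
#' statin effect is an interaction with genotype, not an additive log-odds
#' term).
#'
#' @param cfg a `scenario_config`.
#' @param demog demography table (packaged default if `NULL`).
#' @param incidence calibrated incidence table (packaged default if `NULL`).
#' @param fit_both_statin also fit with the statin covariate added.
#' @param verbose log per-replicate case counts to stderr.
#' @return a `condition_result`: list with `pooled` (a `pooled_estimate`),
#'   `fits`, `pooled_statin_adj` and `fits_statin_adj` (when requested),
#'   `cfg`, `n_cases_mean`, `clipped` (total clipped risks, expected 0).
#' @examples
#' \donttest{
#' res <- run_condition(scenario_config(n = 2e4, replicates = 3, RR = 1.5))
#' res$pooled
#' }
#' @export
run_condition <- function(cfg, demog = NULL, incidence = NULL,
                          fit_both_statin = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(demog)) demog <- load_demography()
  if (is.null(incidence)) incidence <- default_baseline(demog = demog)
  fits <- vector("list", cfg$replicates)
  fits_adj <- if (fit_both_statin) vector("list", cfg$replicates)
  n_cases <- numeric(cfg$replicates)
  clipped <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(cfg$replicates)) {
    cohort <- simulate_cohort(cfg, demog, incidence, replicate = r)
    clipped <- clipped + attr(cohort, "clipped")
    fits[[r]] <- fit_logistic(
      cohort, covariates = c("age", "sex", "carrier"),
      include_statin_covariate = cfg$adjust_for_statin
    )
    if (fit_both_statin) {
      fits_adj[[r]] <- fit_logistic(
        cohort, covariates = c("age", "sex", "carrier"),
        include_statin_covariate = TRUE
      )
    }
    n_cases[r] <- fits[[r]]$n_cases
    if (verbose) {
      message(sprintf("[%s] replicate %d/%d: %d cases, OR %.4f",
                      condition_label(cfg), r, cfg$replicates,
                      fits[[r]]$n_cases, fit_or(fits[[r]])))
    }
  }
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", condition_label(cfg),
                    proc.time()[["elapsed"]] - t0))
  }
  structure(
    list(pooled = pool_replicates(fits),
         fits = fits,
         pooled_statin_adj = if (fit_both_statin) pool_replicates(fits_adj),
         fits_statin_adj = fits_adj,
         cfg = cfg,
         n_cases_mean = mean(n_cases),
         clipped = clipped),
    class = "condition_result"
  )
}

#' @export
print.condition_result <- function(x, ...) {
  cat(condition_label(x$cfg), "\n")
  print(x$pooled)
  invisible(x)
}

# shared grid executor: one row per cell, per-cell failures recorded
run_grid <- function(grid, cfg_base, demog, incidence, fit_both_statin,
                     oracle = TRUE, verbose = FALSE) {
  pooled_rows <- vector("list", nrow(grid))
  rep_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- utils::modifyList(cfg_base, as.list(grid[i, , drop = FALSE]))
    cell <- try({
      cfg <- do.call(scenario_config, args)
      res <- run_condition(cfg, demog, incidence,
                           fit_both_statin = fit_both_statin,
                           verbose = verbose)
      exp_or <- if (!oracle) {
        NA_real_
      } else if (cfg$s > 0) {
        as.numeric(expected_or_statin(demog, incidence, cfg))
      } else {
        as.numeric(expected_or(demog, incidence, cfg, F = cfg$F, d = cfg$d,
                               convention = cfg$fatality_convention))
      }
      pooled_rows[[i]] <- data.frame(
        grid[i, , drop = FALSE],
        pooled_or = res$pooled$or,
        mc_halfwidth = res$pooled$mc_halfwidth,
        pooled_or_statin_adj = if (fit_both_statin) {
          res$pooled_statin_adj$or
        } else NA_real_,
        oracle_or = exp_or,
        n_cases_mean = res$n_cases_mean,
        failed = FALSE, error = NA_character_,
        row.names = NULL
      )
      rep_rows[[i]] <- data.frame(
        grid[rep(i, cfg$replicates), , drop = FALSE],
        replicate = seq_len(cfg$replicates),
        or = res$pooled$replicate_ors,
        n_cases = vapply(res$fits, `[[`, numeric(1), "n_cases"),
        row.names = NULL
      )
      NULL
    }, silent = TRUE)
    if (inherits(cell, "try-error")) {
      pooled_rows[[i]] <- data.frame(
        grid[i, , drop = FALSE],
        pooled_or = NA_real_, mc_halfwidth = NA_real_,
        pooled_or_statin_adj = NA_real_, oracle_or = NA_real_,
        n_cases_mean = NA_real_,
        failed = TRUE, error = conditionMessage(attr(cell, "condition")),
        row.names = NULL
      )
    }
  }
  structure(
    list(pooled = do.call(rbind, pooled_rows),
         replicates = do.call(rbind, rep_rows)),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment grid: ", nrow(x$pooled), " cells, ",
      sum(x$pooled$failed), " failed\n", sep = "")
  print(format(x$pooled[setdiff(names(x$pooled), "error")], digits = 4), ...)
  invisible(x)
}

write_experiment <- function(result, name, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$replicates, file.path(out_dir,
            paste0("results_", name, ".csv")), row.names = FALSE)
  write.csv(result$pooled[setdiff(names(result$pooled), "error")],
            file.path(out_dir, paste0("pooled_", name, ".csv")),
            row.names = FALSE)
  oc <- result$pooled[!result$pooled$failed,
                      c(intersect(c("RR", "F", "d", "s", "e"),
                                  names(result$pooled)), "oracle_or")]
  write.csv(oc, file.path(out_dir, paste0("oracle_", name, ".csv")),
            row.names = FALSE)
  invisible(out_dir)
}

grid_defaults <- function(overrides, fast) {
  base <- list(n = 1e6, replicates = 10, base_seed = 1)
  if (fast) {
    base$n <- 1e5
    base$replicates <- 5
  }
  utils::modifyList(base, overrides)
}

#' Survival-bias experiment grid (fatality differential)
#'
#' Sweeps the fatality differential `d` from 0 to 0.25 in steps of 0.05 for
#' overall fatality `F` in \{0.33, 0.415, 0.50\} and carrier risk ratio `RR`
#' in \{1.25, 1.50\}, with no statin use. Produces the classic picture of
#' survival bias: curves for different `F` coincide at `d = 0` and fan out
#' as the genotype fatality gap grows.
#'
#' `fast = TRUE` drops to n = 100,000 with 5 replicates — all qualitative
#' structure is preserved at roughly ten times the Monte-Carlo noise.
#'
#' @param overrides named list of `scenario_config` arguments to override
#'   (e.g. `list(n = 1e5, replicates = 5, base_seed = 7)`).
#' @param demog,incidence inputs as in [run_condition()].
#' @param out_dir if non-`NULL`, write `results_figure1.csv`,
#'   `pooled_figure1.csv`, `oracle_figure1.csv` there.
#' @param fast reduced-scale mode.
#' @param verbose log per-condition progress to stderr.
#' @return an `experiment_result` with `pooled` and `replicates` tables.
#' @export
run_figure1_grid <- function(overrides = list(), demog = NULL,
                             incidence = NULL, out_dir = NULL,
                             fast = FALSE, verbose = FALSE) {
  if (is.null(demog)) demog <- load_demography()
  if (is.null(incidence)) incidence <- default_baseline(demog = demog)
  grid <- expand.grid(d = seq(0, 0.25, by = 0.05), RR = c(1.25, 1.5),
                      F = c(0.33, 0.415, 0.50))
  res <- run_grid(grid, grid_defaults(overrides, fast), demog, incidence,
                  fit_both_statin = FALSE, verbose = verbose)
  write_experiment(res, "figure1", out_dir)
  res
}

#' Statin-dilution experiment grid (full excess-risk elimination)
#'
#' Sweeps statin use `s` from 0 to 0.9 in steps of 0.1 for `RR` in
#' \{1.25, 1.50\} with `e = 1` (treated carriers keep none of the excess
#' risk) and no fatal-case exclusion. Every cell is fitted twice — with and
#' without the statin covariate — demonstrating that covariate adjustment
#' does not undo the dilution.
#'
#' @inheritParams run_figure1_grid
#' @return an `experiment_result`; the pooled table carries both
#'   `pooled_or` and `pooled_or_statin_adj`.
#' @export
run_figure2_grid <- function(overrides = list(), demog = NULL,
                             incidence = NULL, out_dir = NULL,
                             fast = FALSE, verbose = FALSE) {
  if (is.null(demog)) demog <- load_demography()
  if (is.null(incidence)) incidence <- default_baseline(demog = demog)
  grid <- expand.grid(s = seq(0, 0.9, by = 0.1), RR = c(1.25, 1.5))
  grid$e <- 1
  res <- run_grid(grid, grid_defaults(overrides, fast), demog, incidence,
                  fit_both_statin = TRUE, verbose = verbose)
  write_experiment(res, "figure2", out_dir)
  res
}

#' Partial statin-benefit experiment grid
#'
#' Sweeps the eliminated fraction of carrier excess risk `e` over
#' \{0.2, 0.4, 0.6, 0.8, 1.0\} crossed with statin use `s` from 0 to 0.9,
#' at `RR = 1.5`. Shows the dilution of the carrier OR scaling with the
#' product `s * e` — the odds reduction is proportional to the share of the
#' excess risk actually eliminated in the population.
#'
#' @inheritParams run_figure1_grid
#' @return an `experiment_result`.
#' @export
run_figure3_grid <- function(overrides = list(), demog = NULL,
                             incidence = NULL, out_dir = NULL,
                             fast = FALSE, verbose = FALSE) {
  if (is.null(demog)) demog <- load_demography()
  if (is.null(incidence)) incidence <- default_baseline(demog = demog)
  grid <- expand.grid(s = seq(0, 0.9, by = 0.1),
                      e = c(0.2, 0.4, 0.6, 0.8, 1.0))
  grid$RR <- 1.5
  res <- run_grid(grid, grid_defaults(overrides, fast), demog, incidence,
                  fit_both_statin = FALSE, verbose = verbose)
  write_experiment(res, "figure3", out_dir)
  res
}
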