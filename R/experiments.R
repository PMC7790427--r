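## Replicate orchestration, treatment sweeps, Latin hypercube sensitivity
## analysis and aggregate outcome metrics.

#' Run independent replicates
#'
#' Runs `n` simulations with distinct, logged seeds, so any reported
#' aggregate can be regenerated exactly from (params, treatment, seeds).
#'
#' @param params A [sim_params()].
#' @param treatment A [treatment_spec()] or `NULL`.
#' @param n Number of replicates (>= 1).
#' @param seeds Integer vector of length `n`; defaults to
#'   `params$seed + 0:(n-1)`.
#' @param surrogate Trained surrogate shared across replicates.
#' @return Data frame of per-run summaries, one row per replicate, with the
#'   seed column first.
#' @export
run_replicates <- function(params, treatment = NULL, n = 10, seeds = NULL,
                           surrogate = NULL) {
  stopifnot(n >= 1)
  if (is.null(seeds)) seeds <- params$seed + seq_len(n) - 1L
  stopifnot(length(seeds) == n, !anyDuplicated(seeds))
  if (is.null(surrogate)) surrogate <- default_surrogate()
  out <- lapply(seeds, function(sd) {
    run <- run_simulation(params, treatment, surrogate, seed = sd)
    s <- run$summary
    data.frame(seed = sd, outcome = s$outcome,
               elimination_time_d = s$elimination_time_d,
               time_from_treatment_d = s$time_from_treatment_d,
               max_m1 = s$max_m1, max_tcell = s$max_tcell,
               max_tcell_active = s$max_tcell_active,
               final_cancer = s$final_cancer)
  })
  do.call(rbind, out)
}

#' Aggregate replicate outcomes
#'
#' Computes the panel metrics: fraction of tumors removed, mean time from
#' treatment start to removal (averaged over eliminated runs only; 0 when
#' none), and mean with standard deviation of the maxima of M1, total T and
#' active T counts. When a reference arm is supplied (the lowest treatment
#' strength), significance against it is assessed with a two-sided
#' two-proportion exact test (Fisher) for the removal fraction and
#' rank-sum (Wilcoxon) tests for the continuous maxima, flagged at p < 0.01.
#'
#' @param summaries Data frame from [run_replicates()].
#' @param reference Optional reference-arm data frame.
#' @return List of metrics (class `"tme_aggregate"`).
#' @export
aggregate_runs <- function(summaries, reference = NULL) {
  stopifnot(nrow(summaries) > 0)
  elim <- summaries$outcome == "eliminated"
  times <- summaries$time_from_treatment_d[elim]
  agg <- list(
    n = nrow(summaries),
    fraction_removed = mean(elim),
    mean_time_to_removal = if (any(elim)) mean(times) else 0,
    max_m1_mean = mean(summaries$max_m1),
    max_m1_sd = stats::sd(summaries$max_m1),
    max_tcell_mean = mean(summaries$max_tcell),
    max_tcell_sd = stats::sd(summaries$max_tcell),
    max_tcell_active_mean = mean(summaries$max_tcell_active),
    max_tcell_active_sd = stats::sd(summaries$max_tcell_active))
  if (!is.null(reference)) {
    ref_elim <- reference$outcome == "eliminated"
    tab <- matrix(c(sum(elim), sum(!elim), sum(ref_elim), sum(!ref_elim)),
                  nrow = 2)
    agg$p_fraction <- fisher.test(tab)$p.value
    agg$p_max_m1 <- suppressWarnings(
      wilcox.test(summaries$max_m1, reference$max_m1)$p.value)
    agg$significant <- agg$p_fraction < 0.01
  }
  structure(agg, class = "tme_aggregate")
}

#' @export
print.tme_aggregate <- function(x, ...) {
  cat(sprintf(paste0("<tme_aggregate> n=%d: removed %.0f%%, mean time to ",
                     "removal %.1f d, max M1 %.1f+-%.1f\n"),
              x$n, 100 * x$fraction_removed, x$mean_time_to_removal,
              x$max_m1_mean, x$max_m1_sd))
  invisible(x)
}

#' Treatment-strength sweep
#'
#' Runs matched-seed replicate sets across treatment strengths for one
#' strategy and schedule, mirroring the continuous-strength panels (the
#' lowest strength is the significance reference).
#'
#' @param params A [sim_params()].
#' @param strategy Treatment strategy.
#' @param strengths Numeric vector of strengths to sweep.
#' @param n Replicates per strength.
#' @param schedule,start_day,cycle_duration,days_on Passed to
#'   [treatment_spec()].
#' @param seeds Optional seed vector shared across arms (matched seeds).
#' @param surrogate Trained surrogate.
#' @return List with `table` (tidy data frame: one row per strength with the
#'   aggregate metrics) and `runs` (per-arm summaries).
#' @export
treatment_sweep <- function(params, strategy, strengths, n = 10,
                            schedule = "continuous", start_day = 100,
                            cycle_duration = NULL, days_on = NULL,
                            seeds = NULL, surrogate = NULL) {
  if (is.null(surrogate)) surrogate <- default_surrogate()
  if (is.null(seeds)) seeds <- params$seed + seq_len(n) - 1L
  runs <- lapply(strengths, function(s) {
    spec <- treatment_spec(strategy, s, schedule, start_day,
                           cycle_duration, days_on)
    run_replicates(params, spec, n, seeds, surrogate)
  })
  names(runs) <- as.character(strengths)
  ref <- runs[[1]]
  rows <- lapply(seq_along(strengths), function(i) {
    agg <- aggregate_runs(runs[[i]], reference = if (i > 1) ref else NULL)
    data.frame(strength = strengths[i],
               fraction_removed = agg$fraction_removed,
               mean_time_to_removal = agg$mean_time_to_removal,
               max_m1_mean = agg$max_m1_mean,
               max_tcell_mean = agg$max_tcell_mean,
               max_tcell_active_mean = agg$max_tcell_active_mean,
               p_fraction = if (i > 1) agg$p_fraction else NA_real_,
               significant = if (i > 1) agg$significant else NA)
  })
  list(table = do.call(rbind, rows), runs = runs)
}

#' Latin hypercube parameter sample
#'
#' Stratified one-sample-per-stratum design over the given ranges: for each
#' parameter the `n_sets` sampled values occupy distinct equal-width
#' strata, and column shuffles are independent (each parameter value
#' appears in exactly one set).
#'
#' @param ranges Named list of `c(lo, hi)` parameter ranges
#'   (non-degenerate).
#' @param n_sets Number of parameter sets.
#' @param seed Optional RNG seed.
#' @return Data frame with `n_sets` rows, one column per parameter.
#' @export
lhs_sample <- function(ranges, n_sets, seed = NULL) {
  stopifnot(n_sets >= 1, length(ranges) >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[2] <= r[1]) stop("degenerate range for ", nm)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n_sets, length(ranges))
  out <- as.data.frame(mapply(function(col, r) r[1] + col * (r[2] - r[1]),
                              as.data.frame(u), ranges, SIMPLIFY = FALSE))
  names(out) <- names(ranges)
  out
}

#' Default LHS ranges for the sensitivity analysis
#'
#' The parameters varied in the sensitivity analysis (macrophage
#' recruitment rate, tumor IL-4 secretion, T-cell IFN-gamma secretion,
#' tumor proliferation rate, M2 IL-4 secretion and macrophage lifespan),
#' each spanning one order of magnitude around its default.
#'
#' @param params A [sim_params()] supplying the centers.
#' @return Named list of ranges for [lhs_sample()].
#' @export
default_lhs_ranges <- function(params = sim_params()) {
  spread <- function(x) c(x / sqrt(10), x * sqrt(10))
  list(mac_recruitment_rate_day = spread(params$mac_recruitment_rate_day),
       ksec_il4_tumor = spread(params$ksec_il4_tumor),
       ksec_ifng_tcell = spread(params$ksec_ifng_tcell),
       proliferation_rate_day = spread(params$proliferation_rate_day),
       ksec_il4_m2 = spread(params$ksec_il4_m2),
       mac_lifespan_h = spread(params$mac_lifespan_h))
}

#' Run an LHS sensitivity experiment
#'
#' Simulates each sampled parameter set in replicate and records the
#' fraction of tumors removed and the mean final tumor cell count.
#'
#' @param params Base [sim_params()].
#' @param design Data frame from [lhs_sample()] (columns are `sim_params`
#'   names).
#' @param n_replicates Replicates per parameter set.
#' @param surrogate Trained surrogate.
#' @return Data frame: one row per set with the sampled values,
#'   `fraction_removed` and `final_tumor_mean`.
#' @export
run_lhs <- function(params, design, n_replicates = 3, surrogate = NULL) {
  if (is.null(surrogate)) surrogate <- default_surrogate()
  rows <- lapply(seq_len(nrow(design)), function(i) {
    over <- as.list(design[i, , drop = FALSE])
    p <- do.call(sim_params, utils::modifyList(unclass(params)[
      setdiff(names(unclass(params)), "ca_period_h")], over))
    reps <- run_replicates(p, NULL, n_replicates,
                           seeds = params$seed * 1000L + i * 10L +
                             seq_len(n_replicates),
                           surrogate = surrogate)
    cbind(design[i, , drop = FALSE],
          data.frame(fraction_removed = mean(reps$outcome == "eliminated"),
                     final_tumor_mean = mean(reps$final_cancer)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity scatter tables and rank correlations
#'
#' Reshapes LHS results into a tidy (parameter, value, metric) table and
#' computes the Spearman rank correlation of each parameter with each
#' outcome metric. A metric that is constant across sets has correlation 0.
#'
#' @param lhs_results Data frame from [run_lhs()].
#' @param metrics Metric column names present in `lhs_results`.
#' @return List with `scatter` (tidy data frame) and `rank_correlation`
#'   (data frame: parameter, metric, rho).
#' @export
sensitivity_report <- function(lhs_results,
                               metrics = c("fraction_removed",
                                           "final_tumor_mean")) {
  pars <- setdiff(names(lhs_results), metrics)
  scatter <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(parameter = p, value = lhs_results[[p]], metric = m,
                 outcome = lhs_results[[m]])
    }))
  }))
  rho <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(metrics, function(m) {
      y <- lhs_results[[m]]
      r <- if (stats::sd(y) == 0) 0 else {
        suppressWarnings(cor(lhs_results[[p]], y, method = "spearman"))
      }
      data.frame(parameter = p, metric = m, rho = r)
    }))
  }))
  list(scatter = scatter, rank_correlation = rho)
}
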