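#' Proportional relative bias of abundance
#'
#' `(mean(estimate) - mean(truth)) / mean(truth)`: the ratio-of-means
#' convention — true and estimated abundance are each averaged over the
#' years first (the years of sampling under the standard design), then
#' compared. This differs from averaging per-year ratios when the series
#' varies; the ratio-of-means convention is used throughout.
#'
#' @param truth,estimate Numeric vectors of per-year totals over the same
#'   years (e.g. from [true_abundance()] and [derived_abundance()]).
#' @return A single proportional bias (0.10 means 10% overestimate).
#' @export
proportional_bias <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must cover the same years.",
          class = "kinmix_parameter_error")
  }
  mt <- mean(truth)
  if (!is.finite(mt) || mt == 0) {
    abort("mean true abundance is zero; bias undefined.",
          class = "kinmix_parameter_error")
  }
  (mean(estimate) - mt) / mt
}

# cumulative survival over ages [from, to): prod_{a=from}^{to-1} S_a
cumulative_survival <- function(S, from = 4, to = 10) {
  prod(S[(from + 1L):to])
}

#' Simulate, tally and fit one CKMR replicate
#'
#' The full per-replicate pipeline: [simulate_study()], kin extraction and
#' [tally_comparisons()], [fit_ckmr()], then bias and derived summaries.
#'
#' @param config A [kin_config()].
#' @param priors Optional [ckmr_priors()] (default: built from the
#'   config's life history).
#' @param compute_hessian Compute SEs (default TRUE).
#' @return A one-row tibble with the replicate's summaries: kin counts,
#'   convergence, proportional abundance bias (ages 2+ over the sampling
#'   years), the ratio of estimated to true cumulative survival ages 4-10,
#'   and the three survival SE/prior-SD ratios.
#' @export
run_ckmr_replicate <- function(config, priors = NULL,
                               compute_hessian = TRUE) {
  if (is.null(priors)) priors <- ckmr_priors(config$lh)
  sim <- simulate_study(config)
  pops <- find_pops(sim$samples, sim$pedigree)
  hsps <- find_hsps(sim$samples, sim$pedigree)
  tallies <- tally_comparisons(sim$samples, pops, hsps)
  fit <- fit_ckmr(tallies, priors, n_years = config$n_years,
                  compute_hessian = compute_hessian)

  tr <- true_abundance(sim)
  est <- derived_abundance(fit, years = config$sample_years, min_age = 2)
  bias <- proportional_bias(tr$abundance, est$abundance)
  surv_ratio <- cumulative_survival(fit$dynamics$S) /
    cumulative_survival(survival_vector(config$lh))
  ratios <- if (all(is.finite(fit$se[2:4]))) {
    fit$se[2:4] / priors$eta_sd
  } else rep(NA_real_, 3)

  tibble(
    dispersal = config$dispersal$mode, sampling = config$sampling$mode,
    seed = if (is.null(config$seed)) NA_integer_ else config$seed,
    n_samples = nrow(sim$samples),
    n_pops = nrow(pops), n_hsps = nrow(hsps),
    n_hsps_cross_cohort = sum(tallies$hsp$m),
    converged = fit$convergence, bias = bias,
    surv_ratio_4_10 = surv_ratio,
    se_ratio_eta1 = ratios[1], se_ratio_eta2 = ratios[2],
    se_ratio_eta3 = ratios[3]
  )
}

scenario_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

#' Crossed dispersal x sampling bias study
#'
#' For each combination of dispersal and sampling regime, simulates `reps`
#' independent data sets, fits the naive CKMR model to each, and records
#' per-replicate proportional abundance bias and derived summaries.
#' Replicates that fail to converge are kept in the table (flagged) but
#' should be excluded from bias means; [summarise_bias_study()] does so and
#' reports exclusion counts.
#'
#' @param dispersal_modes,sampling_modes Character vectors of regime names.
#' @param reps Replicates per scenario cell.
#' @param seed Master seed; per-replicate seeds are drawn from it
#'   reproducibly.
#' @param n_per_year Samples per year (default 100).
#' @param lh Calibrated [life_history()] (default the package standard).
#' @param compute_hessian Compute SEs per fit (default TRUE).
#' @param ... Further arguments to [kin_config()] (e.g. `n0`, `n_years`).
#' @return A tibble with one row per scenario x replicate.
#' @export
run_bias_study <- function(dispersal_modes = c("complete_mixing",
                                               "age_independent",
                                               "juvenile_only", "none"),
                           sampling_modes = c("uniform", "moderate_gradient",
                                              "extreme_gradient",
                                              "restricted_north"),
                           reps = 100, seed = NULL, n_per_year = 100L,
                           lh = calibrated_life_history(),
                           compute_hessian = TRUE, ...) {
  cells <- tidyr::expand_grid(dispersal = dispersal_modes,
                              sampling = sampling_modes)
  seeds <- scenario_seeds(seed, nrow(cells) * reps)
  priors <- ckmr_priors(lh)
  out <- vector("list", nrow(cells) * reps)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      cfg <- kin_config(lh = lh, dispersal = cells$dispersal[i],
                        sampling = cells$sampling[i],
                        n_per_year = n_per_year, seed = seeds[[k]], ...)
      row <- tryCatch(
        run_ckmr_replicate(cfg, priors, compute_hessian = compute_hessian),
        error = function(e) {
          warn(sprintf("replicate failed (%s x %s, rep %d): %s",
                       cells$dispersal[i], cells$sampling[i], r,
                       conditionMessage(e)))
          tibble(dispersal = cells$dispersal[i], sampling = cells$sampling[i],
                 seed = if (is.null(seeds[[k]])) NA_integer_ else seeds[[k]],
                 n_samples = NA_integer_, n_pops = NA_integer_,
                 n_hsps = NA_integer_, n_hsps_cross_cohort = NA_integer_,
                 converged = FALSE, bias = NA_real_,
                 surv_ratio_4_10 = NA_real_, se_ratio_eta1 = NA_real_,
                 se_ratio_eta2 = NA_real_, se_ratio_eta3 = NA_real_)
        })
      out[[k]] <- mutate(row, rep = r)
    }
  }
  bind_rows(out) %>% select("dispersal", "sampling", "rep", dplyr::everything())
}

#' Scenario-level summary of a bias study
#'
#' @param results A [run_bias_study()] table.
#' @return One row per scenario: mean and sd of proportional bias over
#'   converged replicates, mean kin counts, mean cumulative-survival ratio,
#'   and the number of replicates excluded for non-convergence.
#' @export
summarise_bias_study <- function(results) {
  results %>%
    group_by(.data$dispersal, .data$sampling) %>%
    summarise(
      reps = n(),
      excluded = sum(!.data$converged | !is.finite(.data$bias)),
      mean_bias = mean(.data$bias[.data$converged], na.rm = TRUE),
      sd_bias = stats::sd(.data$bias[.data$converged], na.rm = TRUE),
      mean_surv_ratio_4_10 = mean(.data$surv_ratio_4_10[.data$converged],
                                  na.rm = TRUE),
      mean_n_pops = mean(.data$n_pops, na.rm = TRUE),
      mean_n_hsps = mean(.data$n_hsps, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Kolmogorov-Smirnov power study
#'
#' Varies sampling intensity (newly dead animals genotyped per year) and
#' dispersal regime, and records KS mixing-test p-values for POP and HSP
#' distances in each replicate. No estimation is involved.
#'
#' @param intensities Samples per year (default the low/medium/high levels
#'   15, 25, 100).
#' @param dispersal_modes Regimes to contrast (default no dispersal versus
#'   complete mixing).
#' @param sampling Spatial sampling regime (default uniform).
#' @param reps Replicates per condition.
#' @param seed Master seed.
#' @param lh Calibrated life history.
#' @param ... Further arguments to [kin_config()].
#' @return A tibble `dispersal, intensity, rep, kind, n_kin, n_null,
#'   statistic, p_value`; replicates with no kin pairs carry `NA` p-values
#'   (skipped tests).
#' @export
run_ks_power_study <- function(intensities = c(15L, 25L, 100L),
                               dispersal_modes = c("none", "complete_mixing"),
                               sampling = "uniform", reps = 100, seed = NULL,
                               lh = calibrated_life_history(), ...) {
  cells <- tidyr::expand_grid(dispersal = dispersal_modes,
                              intensity = intensities)
  seeds <- scenario_seeds(seed, nrow(cells) * reps)
  out <- vector("list", nrow(cells) * reps)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      cfg <- kin_config(lh = lh, dispersal = cells$dispersal[i],
                        sampling = sampling,
                        n_per_year = cells$intensity[i], seed = seeds[[k]], ...)
      sim <- simulate_study(cfg)
      res <- suppressMessages(mixing_diagnostics(sim))
      out[[k]] <- mutate(res, dispersal = cells$dispersal[i],
                         intensity = cells$intensity[i], rep = r)
    }
  }
  bind_rows(out) %>%
    select("dispersal", "intensity", "rep", "kind", dplyr::everything())
}
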