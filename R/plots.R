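#' Plot estimated against true schedules
#'
#' Survival and fecundity curves at the fitted parameters, overlaid on the
#' data-generating curves when a life history is supplied.
#'
#' @param object A [fit_ckmr()] result.
#' @param truth Optional data-generating [life_history()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ckmr_fit <- function(object, truth = NULL, ...) {
  est <- estimated_schedules(object) %>%
    tidyr::pivot_longer(-"age", names_to = "schedule") %>%
    mutate(source = "estimated")
  df <- est
  if (!is.null(truth)) {
    tr <- tidy(truth) %>%
      tidyr::pivot_longer(-"age", names_to = "schedule") %>%
      mutate(source = "true")
    df <- bind_rows(est, tr)
  }
  ggplot(df, aes(x = .data$age, y = .data$value,
                 linetype = .data$source)) +
    geom_line() +
    facet_wrap(~schedule, scales = "free_y") +
    labs(x = "age (years)", y = NULL,
         title = "Estimated vs true life-history schedules") +
    theme_minimal()
}

#' Boxplots of proportional abundance bias by scenario
#'
#' @param results A [run_bias_study()] table.
#' @return A ggplot of per-replicate bias, faceted by dispersal regime.
#' @export
plot_bias_study <- function(results) {
  df <- filter(results, .data$converged, is.finite(.data$bias))
  ggplot(df, aes(x = .data$sampling, y = .data$bias)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_boxplot() +
    facet_wrap(~.data$dispersal) +
    labs(x = "sampling scenario", y = "proportional bias of ages-2+ abundance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Kin-pair versus null distance histograms
#'
#' @param ds A [build_distance_sets()] result.
#' @param binwidth Histogram bin width in grid units.
#' @return A ggplot comparing the POP, HSP and null distance distributions
#'   (densities).
#' @export
plot_distance_histogram <- function(ds, binwidth = 0.5) {
  df <- bind_rows(
    tibble(set = "null", distance = ds$null),
    tibble(set = "POP", distance = ds$pop),
    tibble(set = "HSP", distance = ds$hsp)
  )
  ggplot(df, aes(x = .data$distance, y = ggplot2::after_stat(density))) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "grey70", colour = "grey30") +
    facet_wrap(~.data$set, ncol = 1) +
    labs(x = "distance between sampling cells", y = "density") +
    theme_minimal()
}

#' Boxplots of KS p-values by sampling intensity
#'
#' @param results A [run_ks_power_study()] table.
#' @return A ggplot of p-value distributions by intensity, kin kind and
#'   dispersal regime.
#' @export
plot_ks_power <- function(results) {
  df <- filter(results, is.finite(.data$p_value))
  ggplot(df, aes(x = factor(.data$intensity), y = .data$p_value)) +
    geom_hline(yintercept = 0.05, linetype = 2, colour = "grey50") +
    geom_boxplot() +
    facet_grid(.data$kind ~ .data$dispersal) +
    labs(x = "samples per year", y = "KS p-value") +
    theme_minimal()
}
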