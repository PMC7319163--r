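#' Kin-pair and null distance sets for mixing diagnostics
#'
#' Builds the Euclidean distances (between sampling-cell centroids) of
#' parent-offspring and half-sibling pairs, together with a null
#' distribution of distances over all eligible sampled pairs. Because
#' dispersal occurs between years, pairs sampled (a) in the same year or
#' (b) in the year of birth of one of the two animals are removed from both
#' the kin and the null sets. Kin pairs are not removed from the null set;
#' they are a negligible fraction of all comparisons.
#'
#' @param samples Sample records with `cell_x`, `cell_y` (e.g.
#'   `sim$samples`).
#' @param pops POP matches from [find_pops()].
#' @param hsps HSP matches from [find_hsps()].
#' @param grid The study [make_grid()] (used for centroid coordinates when a
#'   match table carries cells only).
#' @return An object of class `distance_sets`: list with numeric vectors
#'   `pop`, `hsp`, `null` and the exclusion counts.
#' @export
build_distance_sets <- function(samples, pops, hsps, grid = make_grid()) {
  cx <- grid$centroid[, 1]; cy <- grid$centroid[, 2]
  excl <- function(y1, y2, b1, b2) y1 == y2 | y1 == b2 | y2 == b1

  ns <- nrow(samples)
  if (ns < 2) {
    null_d <- numeric(0)
  } else {
    i <- rep(seq_len(ns - 1L), times = (ns - 1L):1L)
    j <- sequence((ns - 1L):1L) + i
    keep <- !excl(samples$sample_year[i], samples$sample_year[j],
                  samples$birth_year[i], samples$birth_year[j])
    i <- i[keep]; j <- j[keep]
    null_d <- sqrt((samples$cell_x[i] - samples$cell_x[j])^2 +
                     (samples$cell_y[i] - samples$cell_y[j])^2)
  }

  pop_keep <- !excl(pops$y1, pops$y2, pops$b1, pops$b2)
  pop_d <- sqrt((cx[pops$parent_cell] - cx[pops$offspring_cell])^2 +
                  (cy[pops$parent_cell] - cy[pops$offspring_cell])^2)[pop_keep]
  hsp_keep <- !excl(hsps$y1, hsps$y2, hsps$b1, hsps$b2)
  hsp_d <- sqrt((cx[hsps$cell1] - cx[hsps$cell2])^2 +
                  (cy[hsps$cell1] - cy[hsps$cell2])^2)[hsp_keep]

  structure(
    list(pop = pop_d, hsp = hsp_d, null = null_d,
         n_excluded = c(pop = sum(!pop_keep), hsp = sum(!hsp_keep))),
    class = "distance_sets"
  )
}

#' Two-sample Kolmogorov-Smirnov mixing test
#'
#' Compares the distance distribution of kin pairs with the null
#' distribution of all eligible sampled pairs. A kin distribution shifted
#' toward short distances indicates incomplete mixing. Uses the asymptotic
#' two-sample KS distribution; ties (distances take at most 100 x 100 cell
#' values) make the p-value conservative approximations, and null pairs
#' share animals, so p-values are diagnostics rather than exact error rates.
#'
#' @param kin Numeric vector of kin-pair distances.
#' @param null Numeric vector of null distances.
#' @return A tibble `n_kin, n_null, statistic, p_value`; when the kin set is
#'   empty the test is skipped (`NA` statistic and p, with a message).
#' @export
ks_mixing_test <- function(kin, null) {
  if (!length(kin) || !length(null)) {
    inform("empty distance set: KS test skipped.")
    return(tibble(n_kin = length(kin), n_null = length(null),
                  statistic = NA_real_, p_value = NA_real_))
  }
  kt <- suppressWarnings(ks.test(kin, null, exact = FALSE))
  tibble(n_kin = length(kin), n_null = length(null),
         statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Run both KS mixing tests on a simulation
#'
#' Convenience wrapper: extracts kin pairs, builds distance sets and tests
#' POP and HSP distances separately against the null.
#'
#' @param sim A [simulate_study()] result.
#' @return A tibble with one row per kin kind: `kind, n_kin, n_null,
#'   statistic, p_value`.
#' @export
mixing_diagnostics <- function(sim) {
  pops <- find_pops(sim$samples, sim$pedigree)
  hsps <- find_hsps(sim$samples, sim$pedigree)
  ds <- build_distance_sets(sim$samples, pops, hsps, sim$config$grid)
  bind_rows(
    mutate(ks_mixing_test(ds$pop, ds$null), kind = "POP"),
    mutate(ks_mixing_test(ds$hsp, ds$null), kind = "HSP")
  ) %>% select("kind", dplyr::everything())
}

#' Kin-pair distance by offspring age and adult age increment
#'
#' Summarizes how parent-offspring pair distances change with the
#' offspring's age at sampling (`sampling year - offspring birth year`) and
#' with the adult age increment (time between the offspring's birth and the
#' parent's sampling). Diffusive all-ages dispersal makes distance grow in
#' both margins; juvenile-only dispersal makes it grow with early offspring
#' age but stay flat in the adult increment; no dispersal keeps it flat at
#' zero.
#'
#' @param pops POP matches from [find_pops()].
#' @param grid The study [make_grid()].
#' @return A tibble `margin, increment, mean_distance, n_pairs` with margins
#'   `"offspring_age"` and `"adult_increment"`.
#' @export
distance_by_increment <- function(pops, grid = make_grid()) {
  cx <- grid$centroid[, 1]; cy <- grid$centroid[, 2]
  d <- sqrt((cx[pops$parent_cell] - cx[pops$offspring_cell])^2 +
              (cy[pops$parent_cell] - cy[pops$offspring_cell])^2)
  tb <- tibble(
    offspring_age = pops$y2 - pops$b2,
    adult_increment = pops$y1 - pops$b2,
    distance = d
  )
  bind_rows(
    tb %>% group_by(margin = "offspring_age", increment = .data$offspring_age) %>%
      summarise(mean_distance = mean(.data$distance), n_pairs = n(),
                .groups = "drop"),
    tb %>% group_by(margin = "adult_increment", increment = .data$adult_increment) %>%
      summarise(mean_distance = mean(.data$distance), n_pairs = n(),
                .groups = "drop")
  )
}
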