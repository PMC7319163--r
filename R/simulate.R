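#' Simulation configuration
#'
#' Collects the study conditions of a simulated CKMR data set. Defaults are
#' the standard conditions: 10,000 animals on a 10 x 10 grid, 60 years,
#' lethal sampling of 100 newly dead animals per year over the final 20
#' years.
#'
#' @param lh A (calibrated) [life_history()].
#' @param grid A [make_grid()].
#' @param dispersal A [dispersal_spec()] or a mode name.
#' @param sampling A [sampling_spec()] or a mode name.
#' @param n0 Initial population size.
#' @param n_years Number of simulated years.
#' @param sample_years Years in which newly dead animals are sampled.
#' @param n_per_year Number of newly dead animals sampled per year.
#' @param seed Optional integer seed.
#' @return A list of class `kin_config`.
#' @export
kin_config <- function(lh = calibrated_life_history(),
                       grid = make_grid(),
                       dispersal = "complete_mixing",
                       sampling = "uniform",
                       n0 = 10000L,
                       n_years = 60L,
                       sample_years = 41:60,
                       n_per_year = 100L,
                       seed = NULL) {
  if (is.character(dispersal)) dispersal <- dispersal_spec(dispersal)
  if (is.character(sampling)) sampling <- sampling_spec(sampling, grid = grid)
  if (n0 <= 0) abort("`n0` must be positive.", class = "kinmix_parameter_error")
  if (any(sample_years > n_years) || any(sample_years < 1)) {
    abort("`sample_years` must lie within 1..n_years.",
          class = "kinmix_parameter_error")
  }
  structure(
    list(lh = lh, grid = grid, dispersal = dispersal, sampling = sampling,
         n0 = as.integer(n0), n_years = as.integer(n_years),
         sample_years = as.integer(sample_years),
         n_per_year = as.integer(n_per_year),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "kin_config"
  )
}

# weighted sampling without replacement of up to n newly dead animals.
# `dead`: data frame with columns id, cell. Returns the selected ids; if
# fewer animals died in supported cells than requested, all of them.
#' Sample newly dead animals with spatially varying probability
#'
#' Draws up to `n_per_year` distinct animals from one year's deaths, without
#' replacement, with selection probability proportional to the sampling
#' weight of the cell each animal occupied at death. Cells with zero weight
#' contribute no samples.
#'
#' @param dead A data frame of that year's deaths with columns `id`, `cell`.
#' @param n_per_year Target number of samples.
#' @param sampling A [sampling_spec()].
#' @return Integer vector of sampled ids (possibly shorter than
#'   `n_per_year`; a shortfall is signalled as a warning by the caller).
#' @export
sample_dead <- function(dead, n_per_year, sampling) {
  w <- sampling$w[dead$cell]
  eligible <- which(w > 0)
  if (!length(eligible) || n_per_year <= 0) return(integer(0))
  k <- min(n_per_year, length(eligible))
  pick <- eligible[sample.int(length(eligible), k, prob = w[eligible])]
  dead$id[pick]
}

new_pop_store <- function(cap) {
  list(
    sex = integer(cap), birth = integer(cap), death = integer(cap),
    mother = integer(cap), father = integer(cap),
    cell = integer(cap), death_cell = integer(cap),
    sampled = logical(cap), sample_year = integer(cap)
  )
}

grow_store <- function(st, cap_new) {
  for (nm in names(st)) length(st[[nm]]) <- cap_new
  st
}

#' Simulate a spatial pedigree-tracked CKMR study
#'
#' Runs the individual-based model: founders drawn from the stable age
#' distribution and placed uniformly on the grid, then `n_years - 1` annual
#' cycles of mortality, movement and within-cell breeding under a
#' postbreeding census, with lethal sampling of newly dead animals during the
#' sampling window.
#'
#' Within each year, in order: (1) every animal of census age `a` (as of the
#' previous census) dies with probability `1 - S_a`, and animals that reached
#' age 37 die deterministically; newly dead animals are sampled in sampling
#' years with probability proportional to the sampling weight of their death
#' cell; (2) survivors move according to the dispersal regime; (3) each
#' female breeds with probability `f_{a,female}`, her mate drawn from males
#' currently in her cell with probability proportional to `f_{a_male,male}`
#' (a cell without males produces no offspring); each breeding female
#' produces one offspring (sex 50:50) in her current cell. Newborns first
#' face mortality, movement and breeding the following year.
#'
#' @param config A [kin_config()]; or pass the same arguments directly.
#' @param ... Arguments forwarded to [kin_config()] when `config` is missing.
#' @return An object of class `ckmr_simulation`: a list with
#'   * `pedigree`: tibble `id, sex, birth_year, death_year, mother_id,
#'     father_id, death_cell` (NA death = alive at the end; NA parents =
#'     founder),
#'   * `samples`: tibble `id, sex, birth_year, sample_year, cell, cell_x,
#'     cell_y`,
#'   * `true_n`: tibble `year, age, sex, n` of census abundance,
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sim <- simulate_study(kin_config(n0 = 500, n_years = 25,
#'                                  sample_years = 16:25, n_per_year = 20,
#'                                  seed = 1))
#' dplyr::count(sim$samples, sample_year)
simulate_study <- function(config = kin_config(...), ...) {
  cfg <- config
  if (!inherits(cfg, "kin_config")) abort("`config` must be a kin_config.",
                                          class = "kinmix_parameter_error")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  lh <- cfg$lh; grid <- cfg$grid
  max_age <- lh$max_age
  S <- survival_vector(lh)                 # ages 0..37, S[38] = 0
  fF <- fecundity_vector(lh, "female")
  fM <- fecundity_vector(lh, "male")
  sad <- stable_age_distribution(lh)$proportion
  n_cells <- grid$n_cells
  K <- if (cfg$dispersal$mode %in% c("age_independent", "juvenile_only")) {
    dispersal_matrix(cfg$dispersal, grid)
  } else NULL

  cap <- cfg$n0 + as.integer(ceiling(cfg$n_years * cfg$n0 * sad[1] * 1.6)) + 1000L
  st <- new_pop_store(cap)
  n_ind <- cfg$n0

  # founders: census year 1
  ages0 <- sample.int(max_age + 1L, cfg$n0, replace = TRUE, prob = sad) - 1L
  idx0 <- seq_len(cfg$n0)
  st$sex[idx0] <- 1L + (runif(cfg$n0) < 0.5)
  st$birth[idx0] <- 1L - ages0
  st$death[idx0] <- NA_integer_
  st$mother[idx0] <- NA_integer_
  st$father[idx0] <- NA_integer_
  st$cell[idx0] <- sample.int(n_cells, cfg$n0, replace = TRUE)
  st$sample_year[idx0] <- NA_integer_

  alive <- idx0
  Ntrue <- array(0L, dim = c(max_age + 1L, cfg$n_years, 2L))
  census <- function(t, ids) {
    age <- t - st$birth[ids]
    idx <- age * 2L + st$sex[ids]         # 1..(2*(max_age+1))
    tabulate(idx, nbins = 2L * (max_age + 1L))
  }
  cn <- census(1L, alive)
  Ntrue[, 1L, 1L] <- cn[seq(1L, by = 2L, length.out = max_age + 1L)]
  Ntrue[, 1L, 2L] <- cn[seq(2L, by = 2L, length.out = max_age + 1L)]

  shortfalls <- integer(0)

  for (t in 2:cfg$n_years) {
    if (!length(alive)) {
      abort(sprintf("population extinct in year %d.", t),
            class = "kinmix_simulation_error")
    }
    alpha <- t - st$birth[alive] - 1L     # age during year t (pre-birthday)
    p <- S[pmin(alpha, max_age) + 1L]
    dies <- runif(length(alive)) >= p
    dead <- alive[dies]
    if (length(dead)) {
      st$death[dead] <- t
      st$death_cell[dead] <- st$cell[dead]
    }

    if (t %in% cfg$sample_years) {
      sel <- sample_dead(list(id = dead, cell = st$death_cell[dead]),
                         cfg$n_per_year, cfg$sampling)
      if (length(sel) < cfg$n_per_year) shortfalls <- c(shortfalls, t)
      if (length(sel)) {
        st$sampled[sel] <- TRUE
        st$sample_year[sel] <- t
      }
    }

    alive <- alive[!dies]
    alpha <- alpha[!dies]

    # movement
    mode <- cfg$dispersal$mode
    if (mode == "complete_mixing") {
      st$cell[alive] <- sample.int(n_cells, length(alive), replace = TRUE)
    } else if (mode != "none") {
      movers <- if (mode == "juvenile_only") alive[alpha == 0L] else alive
      if (length(movers)) {
        by_cell <- split(movers, st$cell[movers])
        for (cl in names(by_cell)) {
          grp <- by_cell[[cl]]
          st$cell[grp] <- sample.int(n_cells, length(grp), replace = TRUE,
                                     prob = K[as.integer(cl), ])
        }
      }
    }

    # breeding (within current cell)
    fem <- alive[st$sex[alive] == 1L]
    if (length(fem)) {
      af <- t - st$birth[fem] - 1L
      breeders <- fem[runif(length(fem)) < fF[af + 1L]]
    } else breeders <- integer(0)

    if (length(breeders)) {
      males <- alive[st$sex[alive] == 2L]
      wm <- fM[t - st$birth[males] - 1L + 1L]
      males_by_cell <- split(seq_along(males), st$cell[males])
      br_by_cell <- split(breeders, st$cell[breeders])
      mothers <- integer(0); fathers <- integer(0)
      for (cl in names(br_by_cell)) {
        mi <- males_by_cell[[cl]]
        if (is.null(mi)) next                   # no males in cell: no births
        moms <- br_by_cell[[cl]]
        if (length(mi) == 1L) {
          dads <- rep(males[mi], length(moms))
        } else {
          dads <- males[mi[sample.int(length(mi), length(moms),
                                      replace = TRUE, prob = wm[mi])]]
        }
        mothers <- c(mothers, moms)
        fathers <- c(fathers, dads)
      }
      nb <- length(mothers)
      if (nb) {
        if (n_ind + nb > cap) {
          cap <- max(cap * 2L, n_ind + nb)
          st <- grow_store(st, cap)
        }
        new_idx <- n_ind + seq_len(nb)
        n_ind <- n_ind + nb
        st$sex[new_idx] <- 1L + (runif(nb) < 0.5)
        st$birth[new_idx] <- t
        st$death[new_idx] <- NA_integer_
        st$mother[new_idx] <- mothers
        st$father[new_idx] <- fathers
        st$cell[new_idx] <- st$cell[mothers]
        st$sample_year[new_idx] <- NA_integer_
        alive <- c(alive, new_idx)
      }
    }

    cn <- census(t, alive)
    Ntrue[, t, 1L] <- cn[seq(1L, by = 2L, length.out = max_age + 1L)]
    Ntrue[, t, 2L] <- cn[seq(2L, by = 2L, length.out = max_age + 1L)]
  }

  if (length(shortfalls)) {
    warn(sprintf(
      "fewer eligible dead than requested in %d sampling year(s): %s",
      length(shortfalls), paste(shortfalls, collapse = ", ")))
  }

  ids <- seq_len(n_ind)
  sex_chr <- c("female", "male")[st$sex[ids]]
  pedigree <- tibble(
    id = ids, sex = sex_chr, birth_year = st$birth[ids],
    death_year = st$death[ids], mother_id = st$mother[ids],
    father_id = st$father[ids],
    death_cell = ifelse(is.na(st$death[ids]), NA_integer_, st$death_cell[ids])
  )
  sidx <- ids[st$sampled[ids]]
  samples <- tibble(
    id = sidx, sex = sex_chr[sidx], birth_year = st$birth[sidx],
    sample_year = st$sample_year[sidx], cell = st$death_cell[sidx],
    cell_x = grid$centroid[st$death_cell[sidx], 1],
    cell_y = grid$centroid[st$death_cell[sidx], 2]
  )
  true_n <- tibble(
    year = rep(seq_len(cfg$n_years), each = (max_age + 1L) * 2L),
    age = rep(rep(0:max_age, times = 2L), times = cfg$n_years),
    sex = rep(rep(c("female", "male"), each = max_age + 1L), times = cfg$n_years),
    n = as.integer(c(sapply(seq_len(cfg$n_years),
                            function(t) c(Ntrue[, t, 1L], Ntrue[, t, 2L]))))
  )

  structure(
    list(pedigree = pedigree, samples = samples, true_n = true_n,
         config = cfg, sampling_shortfall_years = shortfalls),
    class = "ckmr_simulation"
  )
}

#' @export
print.ckmr_simulation <- function(x, ...) {
  cat("<ckmr_simulation>\n")
  cat(sprintf("  individuals: %d   samples: %d   years: %d\n",
              nrow(x$pedigree), nrow(x$samples), x$config$n_years))
  cat(sprintf("  dispersal: %s   sampling: %s\n",
              x$config$dispersal$mode, x$config$sampling$mode))
  invisible(x)
}

#' True abundance of ages `min_age` and older by year
#'
#' @param sim A `ckmr_simulation`.
#' @param years Years to report (default the sampling window).
#' @param min_age Minimum age included (default 2: subadults and adults).
#' @return A tibble `year, abundance`.
#' @export
true_abundance <- function(sim, years = sim$config$sample_years, min_age = 2) {
  sim$true_n %>%
    filter(.data$year %in% years, .data$age >= min_age) %>%
    group_by(year = .data$year) %>%
    summarise(abundance = sum(.data$n), .groups = "drop")
}
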