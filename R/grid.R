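#' Square study grid
#'
#' A `nx` by `ny` grid of unit cells. Cells are indexed `1..nx*ny` in
#' row-major order from the south-west corner: cell `(row - 1) * nx + col`,
#' with row 1 the southernmost row and row `ny` the northern edge. Centroids
#' sit at `(col - 0.5, row - 0.5)`.
#'
#' @param nx,ny Number of columns and rows (default 10 x 10).
#' @return An object of class `kin_grid` with fields `nx`, `ny`, `n_cells`,
#'   `row`, `col`, `centroid` (matrix) and `dist` (pairwise centroid
#'   distances).
#' @export
make_grid <- function(nx = 10L, ny = 10L) {
  n <- nx * ny
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  centroid <- cbind(x = col - 0.5, y = row - 0.5)
  d <- as.matrix(stats::dist(centroid))
  dimnames(d) <- NULL
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), n_cells = as.integer(n),
         row = row, col = col, centroid = centroid, dist = d),
    class = "kin_grid"
  )
}

#' Dispersal regime
#'
#' Four movement regimes for the simulator:
#' * `"complete_mixing"`: an animal's cell each year is uniform over the grid,
#'   independent of its previous location.
#' * `"age_independent"`: all ages move by a Gaussian kernel on centroid
#'   distance, `psi_{m,n} proportional to N(d_{m,n}; 0, kernel_sd)`,
#'   renormalized over the in-grid cells.
#' * `"juvenile_only"`: the same kernel at age 0; older animals never move.
#' * `"none"`: no movement at any age.
#'
#' @param mode One of the four regime names.
#' @param kernel_sd Standard deviation of the Gaussian kernel (grid-cell
#'   units; default 1).
#' @return An object of class `dispersal_spec`.
#' @export
dispersal_spec <- function(mode = c("complete_mixing", "age_independent",
                                    "juvenile_only", "none"),
                           kernel_sd = 1) {
  mode <- match.arg(mode)
  if (kernel_sd <= 0) abort("`kernel_sd` must be positive.",
                            class = "kinmix_parameter_error")
  structure(list(mode = mode, kernel_sd = kernel_sd), class = "dispersal_spec")
}

# cell-to-cell transition matrix implied by a dispersal spec (rows sum to 1);
# for juvenile_only this is the age-0 matrix, older ages are the identity.
dispersal_matrix <- function(spec, grid) {
  n <- grid$n_cells
  switch(spec$mode,
    none = diag(n),
    complete_mixing = matrix(1 / n, n, n),
    {
      k <- dnorm(grid$dist, mean = 0, sd = spec$kernel_sd)
      k / rowSums(k)
    }
  )
}

#' Movement probabilities from one cell
#'
#' The probability vector over destination cells for an animal of a given age
#' starting in `from_cell`, under a dispersal regime.
#'
#' @param spec A [dispersal_spec()].
#' @param age Age in years (matters only for `"juvenile_only"`).
#' @param from_cell Cell index.
#' @param grid A [make_grid()].
#' @return A nonnegative vector over cells summing to 1.
#' @export
dispersal_row <- function(spec, age, from_cell, grid) {
  if (from_cell < 1 || from_cell > grid$n_cells) {
    abort("`from_cell` out of range.", class = "kinmix_parameter_error")
  }
  stay <- function() { v <- numeric(grid$n_cells); v[from_cell] <- 1; v }
  switch(spec$mode,
    none = stay(),
    complete_mixing = rep(1 / grid$n_cells, grid$n_cells),
    age_independent = dispersal_matrix(spec, grid)[from_cell, ],
    juvenile_only = if (age == 0) dispersal_matrix(spec, grid)[from_cell, ] else stay()
  )
}

#' Spatial sampling regime
#'
#' Per-cell relative sampling weights `w_m` in `[0, 1]` with maximum 1:
#' * `"uniform"`: all cells 1.
#' * `"moderate_gradient"`: linear in row from 0.5 (south) to 1 (north edge),
#'   a 2:1 north-to-south ratio with a smooth transition.
#' * `"extreme_gradient"`: linear from 0.1 to 1, a 10-fold variation.
#' * `"restricted_north"`: weight 1 in the northernmost row, 0 elsewhere.
#'
#' @param mode Regime name, or `"custom"` with explicit `weights`.
#' @param grid A [make_grid()].
#' @param weights Optional explicit per-cell weights (overrides `mode`).
#' @return An object of class `sampling_spec` with field `w`.
#' @export
sampling_spec <- function(mode = c("uniform", "moderate_gradient",
                                   "extreme_gradient", "restricted_north",
                                   "custom"),
                          grid = make_grid(), weights = NULL) {
  mode <- match.arg(mode)
  frac <- (grid$row - 1) / (grid$ny - 1)
  w <- switch(mode,
    uniform = rep(1, grid$n_cells),
    moderate_gradient = 0.5 + 0.5 * frac,
    extreme_gradient = 0.1 + 0.9 * frac,
    restricted_north = as.numeric(grid$row == grid$ny),
    custom = {
      if (is.null(weights)) abort("`weights` required for mode = 'custom'.",
                                  class = "kinmix_parameter_error")
      weights
    }
  )
  if (length(w) != grid$n_cells || any(w < 0) || max(w) <= 0) {
    abort("weights must be nonnegative with a positive maximum.",
          class = "kinmix_parameter_error")
  }
  structure(list(mode = mode, w = w / max(w)), class = "sampling_spec")
}
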