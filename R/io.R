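#' Read and write pipeline tables as delimited text
#'
#' Tab-separated serialization of the pipeline's tabular products: the
#' pedigree, sample records, and kin tallies (long format with a `kind`
#' column, `y1` empty for HSP cells).
#'
#' @param x The object to write.
#' @param path File path.
#' @return The input (writers, invisibly) or a tibble / `kin_tallies`
#'   (readers).
#' @name kinmix-io
NULL

#' @rdname kinmix-io
#' @export
write_pedigree <- function(x, path) {
  readr::write_tsv(select(x, "id", "sex", "birth_year", "death_year",
                          "mother_id", "father_id"), path)
  invisible(x)
}

#' @rdname kinmix-io
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = "i", sex = "c", birth_year = "i", death_year = "i",
    mother_id = "i", father_id = "i"))
}

#' @rdname kinmix-io
#' @export
write_samples <- function(x, path) {
  readr::write_tsv(select(x, "id", "sex", "birth_year", "sample_year",
                          "cell", "cell_x", "cell_y"), path)
  invisible(x)
}

#' @rdname kinmix-io
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = "i", sex = "c", birth_year = "i", sample_year = "i", cell = "i",
    cell_x = "d", cell_y = "d"))
}

#' @rdname kinmix-io
#' @export
write_tallies <- function(x, path) {
  long <- bind_rows(
    mutate(x$pop, kind = "pop"),
    mutate(x$hsp, kind = "hsp", y1 = NA_integer_)
  ) %>% select("kind", "b1", "y1", "b2", "g", "n", "m")
  readr::write_tsv(long, path)
  invisible(x)
}

#' @rdname kinmix-io
#' @export
read_tallies <- function(path) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    kind = "c", b1 = "i", y1 = "i", b2 = "i", g = "c", n = "i", m = "i"))
  pop <- long %>% filter(.data$kind == "pop") %>%
    select("b1", "y1", "b2", "g", "n", "m")
  hsp <- long %>% filter(.data$kind == "hsp") %>%
    select("b1", "b2", "g", "n", "m")
  structure(list(pop = pop, hsp = hsp,
                 n_samples = NA_integer_),
            class = "kin_tallies")
}

#' Read or write a run configuration as structured text
#'
#' Serializes the scalar study conditions (life-history parameters, scenario
#' modes, sizes, seed) to YAML. Grid geometry is reconstructed from `nx`,
#' `ny`.
#'
#' @param config A [kin_config()].
#' @param path File path.
#' @return `write_kin_config()` the config invisibly; `read_kin_config()` a
#'   rebuilt `kin_config`.
#' @export
write_kin_config <- function(config, path) {
  lh <- config$lh
  obj <- list(
    life_history = list(eta = lh$eta, nu_female = lh$nu_female,
                        nu_male = lh$nu_male, max_age = lh$max_age,
                        prior_sd_eta = lh$prior_sd_eta,
                        prior_cv_nu = lh$prior_cv_nu),
    grid = list(nx = config$grid$nx, ny = config$grid$ny),
    dispersal = list(mode = config$dispersal$mode,
                     kernel_sd = config$dispersal$kernel_sd),
    sampling = list(mode = config$sampling$mode),
    n0 = config$n0, n_years = config$n_years,
    sample_years = config$sample_years, n_per_year = config$n_per_year,
    seed = config$seed
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(config)
}

#' @rdname write_kin_config
#' @export
read_kin_config <- function(path) {
  obj <- yaml::read_yaml(path)
  lh <- life_history(eta = unlist(obj$life_history$eta),
                     nu_female = unlist(obj$life_history$nu_female),
                     nu_male = unlist(obj$life_history$nu_male),
                     max_age = obj$life_history$max_age,
                     prior_sd_eta = unlist(obj$life_history$prior_sd_eta),
                     prior_cv_nu = obj$life_history$prior_cv_nu)
  grid <- make_grid(obj$grid$nx, obj$grid$ny)
  kin_config(
    lh = lh, grid = grid,
    dispersal = dispersal_spec(obj$dispersal$mode,
                               kernel_sd = obj$dispersal$kernel_sd),
    sampling = sampling_spec(obj$sampling$mode, grid = grid),
    n0 = obj$n0, n_years = obj$n_years,
    sample_years = unlist(obj$sample_years), n_per_year = obj$n_per_year,
    seed = obj$seed
  )
}
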