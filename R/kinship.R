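#' Parent-offspring pairs among sampled animals
#'
#' Finds every sampled pair in which one animal is the recorded mother or
#' father of the other, using the true pedigree. Founders (sentinel parents)
#' never match as anyone's offspring.
#'
#' @param samples Tibble of sample records (`id`, `sex`, `birth_year`,
#'   `sample_year`, `cell`, ...), e.g. `sim$samples`.
#' @param pedigree Pedigree tibble covering all sampled ids
#'   (`id`, `mother_id`, `father_id`, ...).
#' @return A tibble of matches with one row per pair: `parent_id`,
#'   `offspring_id`, `kind` (`"mother-offspring"` or `"father-offspring"`),
#'   `g` (parent sex), `b1`, `y1` (parent birth and sampling year), `b2`,
#'   `y2`, and the two sampling cells.
#' @export
find_pops <- function(samples, pedigree) {
  check_samples_in_pedigree(samples, pedigree)
  ped <- select(pedigree, id = "id", mother_id = "mother_id",
                father_id = "father_id")
  off <- inner_join(samples, ped, by = "id")
  one_side <- function(parent_col, kind, g) {
    m <- inner_join(
      select(off, offspring_id = "id", b2 = "birth_year", y2 = "sample_year",
             offspring_cell = "cell", parent = dplyr::all_of(parent_col)),
      select(samples, parent = "id", b1 = "birth_year", y1 = "sample_year",
             parent_cell = "cell"),
      by = "parent"
    )
    if (!nrow(m)) return(NULL)
    mutate(m, kind = kind, g = g)
  }
  out <- bind_rows(
    one_side("mother_id", "mother-offspring", "female"),
    one_side("father_id", "father-offspring", "male")
  )
  if (is.null(out) || !nrow(out)) {
    return(tibble(parent_id = integer(0), offspring_id = integer(0),
                  kind = character(0), g = character(0),
                  b1 = integer(0), y1 = integer(0), b2 = integer(0),
                  y2 = integer(0), parent_cell = integer(0),
                  offspring_cell = integer(0)))
  }
  out %>%
    rename(parent_id = "parent") %>%
    select("parent_id", "offspring_id", "kind", "g", "b1", "y1", "b2", "y2",
           "parent_cell", "offspring_cell") %>%
    arrange(.data$parent_id, .data$offspring_id)
}

#' Half-sibling pairs among sampled animals
#'
#' Finds every sampled pair sharing exactly one recorded parent; the shared
#' parent's sex labels the match as maternal or paternal. Pairs sharing both
#' parents (full siblings) are excluded from matches entirely (full-sibling
#' pairs are not modelled), though they still count as comparisons in
#' [tally_comparisons()].
#'
#' @inheritParams find_pops
#' @return A tibble of matches: `id1`, `id2` (id1 < id2), `kind`
#'   (`"maternal-hsp"` or `"paternal-hsp"`), `g` (shared parent sex), `b1`,
#'   `b2` (older then younger sibling birth years), `y1`, `y2` (their
#'   sampling years, same order) and sampling cells `cell1`, `cell2`.
#' @export
find_hsps <- function(samples, pedigree) {
  check_samples_in_pedigree(samples, pedigree)
  ped <- select(pedigree, id = "id", mother_id = "mother_id",
                father_id = "father_id")
  ss <- inner_join(samples, ped, by = "id")
  pairs_sharing <- function(parent_col) {
    s <- ss[!is.na(ss[[parent_col]]), ]
    if (!nrow(s)) return(NULL)
    s <- select(s, id = "id", b = "birth_year", y = "sample_year",
                cell = "cell", parent = dplyr::all_of(parent_col))
    p <- inner_join(s, s, by = "parent", suffix = c(".1", ".2"),
                    relationship = "many-to-many")
    p <- filter(p, .data$id.1 < .data$id.2)
    p
  }
  mat <- pairs_sharing("mother_id")
  pat <- pairs_sharing("father_id")
  key <- function(p) paste(p$id.1, p$id.2)
  full <- intersect(if (is.null(mat)) character(0) else key(mat),
                    if (is.null(pat)) character(0) else key(pat))
  shape <- function(p, kind, g) {
    if (is.null(p) || !nrow(p)) return(NULL)
    p <- p[!(key(p) %in% full), , drop = FALSE]
    if (!nrow(p)) return(NULL)
    older_first <- p$b.1 <= p$b.2
    tibble(
      id1 = p$id.1, id2 = p$id.2, kind = kind, g = g,
      b1 = ifelse(older_first, p$b.1, p$b.2),
      b2 = ifelse(older_first, p$b.2, p$b.1),
      y1 = ifelse(older_first, p$y.1, p$y.2),
      y2 = ifelse(older_first, p$y.2, p$y.1),
      cell1 = ifelse(older_first, p$cell.1, p$cell.2),
      cell2 = ifelse(older_first, p$cell.2, p$cell.1)
    )
  }
  out <- bind_rows(shape(mat, "maternal-hsp", "female"),
                   shape(pat, "paternal-hsp", "male"))
  if (is.null(out) || !nrow(out)) {
    return(tibble(id1 = integer(0), id2 = integer(0), kind = character(0),
                  g = character(0), b1 = integer(0), b2 = integer(0),
                  y1 = integer(0), y2 = integer(0), cell1 = integer(0),
                  cell2 = integer(0)))
  }
  arrange(out, .data$id1, .data$id2, .data$kind)
}

check_samples_in_pedigree <- function(samples, pedigree) {
  missing <- setdiff(samples$id, pedigree$id)
  if (length(missing)) {
    abort(sprintf("%d sampled id(s) missing from the pedigree (e.g. %s).",
                  length(missing), missing[1]),
          class = "kinmix_data_integrity_error")
  }
  invisible(TRUE)
}

#' Sufficient-statistic tallies of kin comparisons and matches
#'
#' Reduces the pairwise comparisons among sampled animals to the sufficient
#' statistics the pseudolikelihood consumes: comparison counts `n` and match
#' counts `m` per covariate combination.
#'
#' POP comparisons are ordered (potential parent, potential offspring) pairs
#' of distinct animals, indexed by the potential parent's birth year `b1`,
#' capture year `y1` and sex `g`, and the potential offspring's birth year
#' `b2`. Comparisons with `y1 == b2` (parent dead in the potential
#' offspring's birth year) are omitted from both `n` and `m`. Every cross
#' pair enters `n` regardless of whether the corresponding kinship
#' probability is structurally zero; zero-probability cells simply contribute
#' nothing to the likelihood (and must have `m = 0`).
#'
#' HSP comparisons are unordered pairs with distinct birth years
#' (`b1 < b2`); same-age comparisons are omitted. Each pair is a comparison
#' for each shared-parent sex `g`, so every unordered pair appears in both
#' the maternal and the paternal stratum; matches land in the stratum of the
#' shared parent's sex (full siblings in neither).
#'
#' @param samples Sample records (see [find_pops()]).
#' @param pops POP matches from [find_pops()] (computed if omitted).
#' @param hsps HSP matches from [find_hsps()] (computed if omitted).
#' @param pedigree Needed only when `pops`/`hsps` are omitted.
#' @return An object of class `kin_tallies`: list with tibbles `pop`
#'   (`b1, y1, b2, g, n, m`) and `hsp` (`b1, b2, g, n, m`), plus
#'   `n_samples`.
#' @export
tally_comparisons <- function(samples, pops = NULL, hsps = NULL,
                              pedigree = NULL) {
  if (is.null(pops)) pops <- find_pops(samples, pedigree)
  if (is.null(hsps)) hsps <- find_hsps(samples, pedigree)

  parent_strata <- count(samples, b1 = .data$birth_year,
                         y1 = .data$sample_year, g = .data$sex, name = "n_par")
  off_strata <- count(samples, b2 = .data$birth_year, name = "n_off")
  pop_n <- cross_join(parent_strata, off_strata) %>%
    mutate(n = .data$n_par * .data$n_off)
  # remove self-comparisons (an animal compared with itself)
  self_n <- count(samples, b1 = .data$birth_year, y1 = .data$sample_year,
                  g = .data$sex, name = "n_self") %>%
    mutate(b2 = .data$b1)
  pop_n <- left_join(pop_n, self_n, by = c("b1", "y1", "g", "b2")) %>%
    mutate(n = .data$n - dplyr::coalesce(.data$n_self, 0L)) %>%
    filter(.data$y1 != .data$b2, .data$n > 0) %>%
    select("b1", "y1", "b2", "g", "n")

  pop_m <- pops %>%
    filter(.data$y1 != .data$b2) %>%
    count(.data$b1, .data$y1, .data$b2, .data$g, name = "m")
  pop <- left_join(pop_n, pop_m, by = c("b1", "y1", "b2", "g")) %>%
    mutate(m = dplyr::coalesce(.data$m, 0L)) %>%
    arrange(.data$g, .data$b1, .data$y1, .data$b2)

  birth_strata <- count(samples, b = .data$birth_year, name = "nb")
  hp <- cross_join(rename(birth_strata, b1 = "b", n1 = "nb"),
                   rename(birth_strata, b2 = "b", n2 = "nb")) %>%
    filter(.data$b1 < .data$b2) %>%
    mutate(n = .data$n1 * .data$n2) %>%
    select("b1", "b2", "n")
  hsp_n <- bind_rows(mutate(hp, g = "female"), mutate(hp, g = "male"))
  hsp_m <- hsps %>%
    filter(.data$b1 < .data$b2) %>%
    count(.data$b1, .data$b2, .data$g, name = "m")
  hsp <- left_join(hsp_n, hsp_m, by = c("b1", "b2", "g")) %>%
    mutate(m = dplyr::coalesce(.data$m, 0L)) %>%
    select("b1", "b2", "g", "n", "m") %>%
    arrange(.data$g, .data$b1, .data$b2)

  if (any(pop$m > pop$n) || any(hsp$m > hsp$n)) {
    abort("internal error: more matches than comparisons in a tally cell.",
          class = "kinmix_internal_error")
  }
  structure(list(pop = pop, hsp = hsp, n_samples = nrow(samples)),
            class = "kin_tallies")
}

#' @export
print.kin_tallies <- function(x, ...) {
  cat("<kin_tallies>\n")
  cat(sprintf("  samples: %d\n", x$n_samples))
  cat(sprintf("  POP cells: %d (comparisons %d, matches %d)\n",
              nrow(x$pop), sum(x$pop$n), sum(x$pop$m)))
  cat(sprintf("  HSP cells: %d (comparisons %d, matches %d)\n",
              nrow(x$hsp), sum(x$hsp$n), sum(x$hsp$m)))
  invisible(x)
}
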