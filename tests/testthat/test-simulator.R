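test_that("identical configuration and seed reproduce the simulation exactly", {
  s1 <- simulate_study(small_config(11))
  s2 <- simulate_study(small_config(11))
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$true_n, s2$true_n)
})

test_that("bookkeeping conservation: births - deaths = change in alive count", {
  sim <- suppressWarnings(simulate_study(small_config(3)))
  ped <- sim$pedigree
  tot <- dplyr::count(sim$true_n, year, wt = n)$n
  for (t in 2:sim$config$n_years) {
    births <- sum(ped$birth_year == t)
    deaths <- sum(!is.na(ped$death_year) & ped$death_year == t)
    expect_identical(tot[t] - tot[t - 1], births - deaths)
  }
  # census totals also equal the pedigree's alive counts
  alive_60 <- sum(ped$birth_year <= sim$config$n_years &
                    (is.na(ped$death_year)))
  expect_identical(tot[sim$config$n_years], alive_60)
})

test_that("every sampled animal is dead and sampled in its death year", {
  sim <- suppressWarnings(simulate_study(small_config(4)))
  ped <- sim$pedigree[match(sim$samples$id, sim$pedigree$id), ]
  expect_true(all(!is.na(ped$death_year)))
  expect_identical(sim$samples$sample_year, ped$death_year)
  expect_identical(sim$samples$cell, ped$death_cell)
  # ages at death within the cap
  expect_true(all(sim$samples$sample_year - sim$samples$birth_year - 1 <= 37))
  # parents born before their offspring
  kids <- ped <- sim$pedigree
  mo <- match(kids$mother_id, ped$id)
  expect_true(all(is.na(mo) | ped$birth_year[mo] < kids$birth_year))
})

test_that("no fecundity means no births, a shrinking population, and eventual extinction", {
  # with zero fecundity the stable age structure collapses onto the oldest
  # class, so the founders age out quickly: no births ever, the population
  # only shrinks, and a long horizon ends in a simulation error
  lh <- life_history(nu_female = c(1, 1e9), nu_male = c(1, 1e9))
  cfg <- kin_config(lh = lh, n0 = 500, n_years = 2, sample_years = 2,
                    n_per_year = 5, seed = 1)
  sim <- suppressWarnings(simulate_study(cfg))
  expect_identical(sum(sim$pedigree$birth_year > 1), 0L)
  tot <- dplyr::count(sim$true_n, year, wt = n)$n
  expect_true(all(diff(tot) <= 0))
  cfg10 <- kin_config(lh = lh, n0 = 500, n_years = 10, sample_years = 10,
                      n_per_year = 5, seed = 1)
  expect_error(suppressWarnings(simulate_study(cfg10)),
               class = "kinmix_simulation_error")
})

test_that("with survival near one, only the age cap kills and nobody leaves their cell", {
  lh <- life_history(eta = c(1e-8, 1, 1e-10))
  cfg <- kin_config(lh = lh, dispersal = "none", n0 = 400, n_years = 6,
                    sample_years = 6, n_per_year = 1, seed = 2)
  sim <- suppressWarnings(simulate_study(cfg))
  ped <- sim$pedigree
  dead <- ped[!is.na(ped$death_year), ]
  # every death is an age-cap death at completed age 37
  expect_true(all(dead$death_year - dead$birth_year - 1 == 37))
  # no dispersal: offspring stay in the mother's cell; dead parents of dead
  # offspring share their death cell
  kids <- ped[ped$birth_year > 1 & !is.na(ped$death_year), ]
  if (nrow(kids)) {
    mo <- match(kids$mother_id, ped$id)
    mo_dead <- !is.na(ped$death_year[mo])
    expect_identical(kids$death_cell[mo_dead], ped$death_cell[mo][mo_dead])
  }
  expect_identical(sum(ped$birth_year <= 1), 400L)
})

test_that("parents are co-located at conception (mate drawn from the mother's cell)", {
  # with no movement an animal occupies one cell for life, so its death cell
  # records that cell; parents of every offspring must then share it
  sim <- suppressWarnings(simulate_study(small_config(5, dispersal = "none",
                                                      n0 = 600)))
  ped <- sim$pedigree
  kids <- ped[ped$birth_year > 1, ]
  mo <- match(kids$mother_id, ped$id)
  fa <- match(kids$father_id, ped$id)
  expect_true(all(ped$sex[mo] == "female"))
  expect_true(all(ped$sex[fa] == "male"))
  both_dead <- !is.na(ped$death_year[mo]) & !is.na(ped$death_year[fa])
  expect_gt(sum(both_dead), 100)
  expect_identical(ped$death_cell[mo][both_dead], ped$death_cell[fa][both_dead])
  kid_dead <- both_dead & !is.na(kids$death_year)
  expect_identical(kids$death_cell[kid_dead], ped$death_cell[mo][kid_dead])
})

test_that("initial ages follow the stable age distribution", {
  lh <- test_lh()
  sad <- stable_age_distribution(lh)$proportion
  counts <- numeric(38)
  for (s in 1:10) {
    sim <- simulate_study(kin_config(lh = lh, n0 = 1000, n_years = 2,
                                     sample_years = 2, n_per_year = 1,
                                     seed = s))
    age1 <- 1 - sim$pedigree$birth_year[sim$pedigree$birth_year <= 1]
    counts <- counts + tabulate(age1 + 1, 38)
  }
  # chi-square goodness of fit against the stable proportions (pooled tail)
  keep <- sad * sum(counts) >= 5
  obs <- c(counts[keep], sum(counts[!keep]))
  expc <- c(sad[keep], sum(sad[!keep])) * sum(counts)
  chi2 <- sum((obs - expc)^2 / expc)
  expect_lt(chi2, qchisq(0.999, df = length(obs) - 1))
})

test_that("standard design yields 20 x 100 samples and a stationary population", {
  lh <- test_lh()
  sim <- simulate_study(kin_config(lh = lh, n0 = 4000, seed = 8))
  expect_identical(nrow(sim$samples), 2000L)
  expect_identical(sort(unique(sim$samples$sample_year)), 41:60)
  expect_identical(as.integer(table(sim$samples$sample_year)), rep(100L, 20))
  tot <- dplyr::count(sim$true_n, year, wt = n)$n
  expect_equal(mean(tot[41:60]), 4000, tolerance = 0.12)
  # founders are all dead before the sampling window begins
  founders <- sim$pedigree$birth_year <= 1
  expect_true(all(sim$pedigree$death_year[founders] < 41, na.rm = TRUE))
  expect_true(all(!is.na(sim$pedigree$death_year[founders])))
})
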