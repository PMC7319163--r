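theta_true_for <- function(n0) {
  lh <- test_lh()
  sad <- stable_age_distribution(lh)$proportion
  kinmix:::theta_from_truth(lh, 0.5 * n0 * sad[1])
}

test_that("projection: certain survival with no recruitment shifts cohorts unchanged", {
  th <- make_theta(log(100), c(1e-9, 1, 1e-12), c(1, 1e9), c(1, 1e9))
  dyn <- project_dynamics(th, n_years = 20)
  # year-1 column is flat at exp(R0) (survivorship ~ 1), pushed along cohorts
  expect_equal(dyn$N[1:37, 1], rep(100, 37), tolerance = 1e-6)
  for (t in 2:20) expect_equal(dyn$N[2:38, t], dyn$N[1:37, t - 1],
                               tolerance = 1e-6)
})

test_that("projection at the data-generating theta is stationary", {
  dyn <- project_dynamics(theta_true_for(10000))
  tot <- colSums(dyn$N)
  expect_lt(max(abs(tot / tot[1] - 1)), 0.001)
  # recruitment column equals the printed recruitment sum recomputed directly
  for (t in c(2, 30, 60)) {
    recruits <- 0.5 * sum(dyn$N[2:38, t] * dyn$fF[1:37])
    expect_equal(dyn$N[1, t], recruits)
  }
})

test_that("POP probability: zero branches and equal-parents reduction to 1/K", {
  dyn <- project_dynamics(theta_true_for(10000))
  expect_identical(pop_probability(30, 34, 35, "female", dyn), 0)  # y1 < b2
  expect_identical(pop_probability(2, 55, 41, "female", dyn), 0)   # b2 > b1 + 37
  expect_identical(pop_probability(30, 40, 30, "male", dyn), 0)    # same cohort
  expect_identical(pop_probability(32, 40, 30, "male", dyn), 0)    # younger "parent"
  # hand-built dynamics: K equally fecund parent ages with one animal each
  K <- 5
  toy <- dyn
  toy$N <- matrix(0, 38, toy$n_years)
  toy$N[11:(10 + K), ] <- 1
  toy$fF <- rep(0.7, 38); toy$fM <- rep(0.7, 38)
  fshift <- c(0, toy$fF[1:37])
  toy$DF <- colSums(toy$N * fshift); toy$DM <- toy$DF
  b2 <- 40
  p <- pop_probability(b2 - 12, 50, b2, "female", toy)  # census age 12 in b2
  expect_equal(p, 1 / K)
})

test_that("denominator consistency: parent-age probabilities sum to one over a cohort", {
  dyn <- project_dynamics(theta_true_for(10000))
  b2 <- 45
  for (g in c("female", "male")) {
    p <- pop_probability(b2 - (1:37), 60, b2, g, dyn)
    expect_equal(sum(dyn$N[2:38, b2] * p), 1, tolerance = 1e-10)
  }
})

test_that("HSP probability matches a direct triple-sum transcription", {
  dyn <- project_dynamics(theta_true_for(10000))
  cases <- expand.grid(b1 = c(10L, 30L, 44L), d = c(1L, 3L, 10L, 25L),
                       g = c("female", "male"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    b1 <- cases$b1[i]; b2 <- b1 + cases$d[i]; g <- cases$g[i]
    expect_equal(hsp_probability(b1, b2, g, dyn),
                 oracle_hsp(b1, b2, g, dyn), tolerance = 1e-12)
  }
  # a gap no parent can survive
  expect_identical(hsp_probability(2, 40, "female", dyn), 0)
  expect_error(hsp_probability(30, 30, "female", dyn),
               class = "kinmix_parameter_error")
})

test_that("HSP single-breeding-age toy reduces to s^gap * f / (sum N f)", {
  dyn <- project_dynamics(theta_true_for(10000), n_years = 30)
  s <- 0.9; phi <- 0.6; A <- 9       # parents all census age A+1 at b1
  toy <- dyn
  toy$S <- rep(s, 38)
  toy$C <- cumprod(c(1, rep(s, 37)))
  toy$fF <- toy$fM <- c(numeric(A), rep(phi, 38 - A))
  toy$N <- matrix(0, 38, 30)
  toy$N[A + 2, 10] <- 50              # breeders of cohort b1 = 10
  toy$N[12:20, 14] <- 3               # arbitrary breeders in year b2 = 14
  fshift <- c(0, toy$fF[1:37])
  toy$DF <- toy$DM <- colSums(toy$N * fshift)
  gap <- 4
  expected <- s^gap * phi / toy$DF[14]
  expect_equal(hsp_probability(10, 14, "female", toy), expected)
})

test_that("pseudolikelihood values: direct substitution and zero-count reduction", {
  # single POP cell with n = 100, P = 0.02, m = 2: data term -(2 log 2 - 2)
  expect_equal(kinmix:::poisson_nll_terms(100, 2, 0.02), -(2 * log(2) - 2))
  expect_equal(kinmix:::poisson_nll_terms(100, 0, 0.02), 2)   # mu only
  expect_identical(kinmix:::poisson_nll_terms(100, 1, 0), Inf)
  expect_identical(kinmix:::poisson_nll_terms(100, 0, 0), 0)

  # all m = 0 reduces the data part to the sum of the mu
  lh <- test_lh()
  priors <- ckmr_priors(lh)
  th <- theta_true_for(10000)
  dyn <- project_dynamics(th)
  tal <- structure(list(
    pop = tibble::tibble(b1 = c(30L, 31L), y1 = c(45L, 46L), b2 = c(40L, 41L),
                         g = "female", n = c(50L, 80L), m = c(0L, 0L)),
    hsp = tibble::tibble(b1 = 35L, b2 = 38L, g = "male", n = 200L, m = 0L),
    n_samples = 0L), class = "kin_tallies")
  mu <- 50 * pop_probability(30, 45, 40, "female", dyn) +
    80 * pop_probability(31, 46, 41, "female", dyn) +
    200 * hsp_probability(35, 38, "male", dyn)
  expect_equal(neg_log_pseudolikelihood(th, tal, priors), mu)  # priors at mean
  expect_identical(neg_log_pseudolikelihood(rep(NA_real_, 8), tal, priors), Inf)
})

test_that("merging tally cells with identical covariates only shifts the objective by a constant", {
  # sufficiency: the theta-dependent part of the objective depends on the
  # tallies only through the per-covariate sums; splitting a cell changes the
  # value by the theta-free m log n term alone
  sim <- simulate_study(small_config(31))
  tal <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
  priors <- ckmr_priors(test_lh())
  thA <- theta_true_for(800)
  thB <- thA + 0.05
  split_tal <- tal
  r <- which(split_tal$pop$m >= 1 & split_tal$pop$n >= 2)[1]
  row <- split_tal$pop[r, ]
  row1 <- row; row1$n <- 1L; row1$m <- 0L
  row2 <- row; row2$n <- row$n - 1L
  split_tal$pop <- dplyr::bind_rows(split_tal$pop[-r, ], row1, row2)
  dA <- neg_log_pseudolikelihood(thA, tal, priors, n_years = 45) -
    neg_log_pseudolikelihood(thA, split_tal, priors, n_years = 45)
  dB <- neg_log_pseudolikelihood(thB, tal, priors, n_years = 45) -
    neg_log_pseudolikelihood(thB, split_tal, priors, n_years = 45)
  expect_equal(dA, dB, tolerance = 1e-8)
})

test_that("score is centred at truth for model-generated binomial tallies", {
  # tallies drawn from the model's own Bernoulli assumption: the estimating
  # equation must be unbiased, so the mean finite-difference gradient at the
  # generating theta is zero within Monte-Carlo error
  set.seed(99)
  sim <- simulate_study(kin_config(lh = test_lh(), n0 = 4000, seed = 12))
  skeleton <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
  priors <- ckmr_priors(test_lh())
  th <- theta_true_for(4000)
  dyn <- project_dynamics(th)
  Pp <- pop_probability(skeleton$pop$b1, skeleton$pop$y1, skeleton$pop$b2,
                        skeleton$pop$g, dyn)
  okh <- skeleton$hsp$b2 - skeleton$hsp$b1 <= 37
  Ph <- numeric(nrow(skeleton$hsp))
  Ph[okh] <- hsp_probability(skeleton$hsp$b1[okh], skeleton$hsp$b2[okh],
                             skeleton$hsp$g[okh], dyn)
  grads <- matrix(NA_real_, 40, 8)
  h <- 1e-4 * pmax(abs(th), 0.5)
  for (r in 1:40) {
    tal <- skeleton
    tal$pop$m <- rbinom(nrow(tal$pop), tal$pop$n, Pp)
    tal$hsp$m <- rbinom(nrow(tal$hsp), tal$hsp$n, Ph)
    ld <- kinmix:::prepare_likelihood_data(tal)
    f <- function(x) kinmix:::nll_from_data(x, ld, priors)
    for (i in 1:8) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
      grads[r, i] <- (f(tp) - f(tm)) / (2 * h[i])
    }
  }
  z <- colMeans(grads) / (apply(grads, 2, sd) / sqrt(nrow(grads)))
  expect_true(all(abs(z) < 4))
})

test_that("simulated kin frequencies match model probabilities at the study scale", {
  # the bridge between simulator and estimator: stratum-aggregated observed
  # matches against sum(n * P) at the data-generating parameters
  obs <- exp <- c(pop = 0, hsp = 0)
  th <- theta_true_for(4000)
  dyn <- project_dynamics(th)
  for (s in 1:6) {
    sim <- simulate_study(kin_config(lh = test_lh(), n0 = 4000, seed = 100 + s))
    tal <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
    Pp <- pop_probability(tal$pop$b1, tal$pop$y1, tal$pop$b2, tal$pop$g, dyn)
    okh <- tal$hsp$b2 - tal$hsp$b1 <= 37
    Ph <- hsp_probability(tal$hsp$b1[okh], tal$hsp$b2[okh], tal$hsp$g[okh], dyn)
    obs <- obs + c(sum(tal$pop$m), sum(tal$hsp$m))
    exp <- exp + c(sum(tal$pop$n * Pp), sum(tal$hsp$n[okh] * Ph))
  }
  # tolerance covers Monte-Carlo error plus the small known finite-population
  # effects (within-cell mate competition, realized-trajectory noise)
  expect_equal(unname(obs[1] / exp[1]), 1, tolerance = 0.12)
  expect_equal(unname(obs[2] / exp[2]), 1, tolerance = 0.12)
})

test_that("fitting works: fixed point at the optimum and sane derived output", {
  sim <- simulate_study(small_config(41, n0 = 1500))
  tal <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
  priors <- ckmr_priors(test_lh())
  fit <- fit_ckmr(tal, priors, n_years = 45, compute_hessian = FALSE)
  expect_true(fit$convergence)
  refit <- fit_ckmr(tal, priors, init = fit$theta, n_years = 45,
                    compute_hessian = FALSE)
  expect_equal(refit$objective, fit$objective, tolerance = 1e-6)
  expect_equal(unname(refit$theta), unname(fit$theta), tolerance = 1e-2)
  ab <- derived_abundance(fit, years = 39:45, min_age = 2)
  expect_identical(ab$year, 39:45)
  expect_true(all(ab$abundance > 0))
  # derived totals equal direct summation over the projected table
  expect_equal(ab$abundance[1], 2 * sum(fit$dynamics$N[3:38, 39]))
  expect_identical(derived_abundance(fit, 40, min_age = 38)$abundance, 0)
  full <- derived_abundance(fit, 40, min_age = 0)$abundance
  expect_gt(full, ab$abundance[2])
  td <- tidy(fit)
  expect_identical(td$term[1], "R0")
  expect_true(all(is.na(td$std.error)))
})

test_that("dropping HSP strata loses survival information (larger SEs)", {
  sim <- simulate_study(small_config(42, n0 = 1500))
  tal <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
  priors <- ckmr_priors(test_lh())
  fit_full <- fit_ckmr(tal, priors, n_years = 45)
  tal_pop <- tal
  tal_pop$hsp <- tal$hsp[0, ]
  fit_pop <- fit_ckmr(tal_pop, priors, n_years = 45)
  r_full <- se_prior_ratios(fit_full)
  r_pop <- se_prior_ratios(fit_pop)
  eta_rows <- 1:3
  expect_gt(mean(r_pop$ratio[eta_rows]), mean(r_full$ratio[eta_rows]))
})

test_that("with a prior-only objective the SE/prior-SD ratios are one", {
  # no informative data cells: the curvature in the penalized parameters is
  # exactly the prior precision, so each ratio is 1 up to FD error
  priors <- ckmr_priors(test_lh())
  th <- theta_true_for(10000)
  ld <- list(pop_female = data.frame(), pop_male = data.frame(),
             hsp_female = data.frame(), hsp_male = data.frame(),
             n_years = 60L, max_age = 37L)
  f <- function(x) kinmix:::nll_from_data(x, ld, priors)
  H <- kinmix:::fd_hessian(f, th)[2:8, 2:8]
  se <- sqrt(diag(solve(H)))
  ratios <- se / c(priors$eta_sd, priors$nu_sd)
  expect_equal(ratios, rep(1, 7), tolerance = 1e-4, ignore_attr = TRUE)
})
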