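#' Prior specification for the CKMR pseudolikelihood
#'
#' Gaussian priors enter the objective as quadratic penalties: on the three
#' log-scale RAW survival parameters (means at the data-generating values,
#' sds `sigma_i`) and on the four natural-scale logistic fecundity parameters
#' (means at the data-generating values, sds `tau_{g,i} = cv * nu_{g,i}`).
#'
#' @param lh The data-generating [life_history()] (its parameter values are
#'   the prior means, and its `prior_sd_eta` / `prior_cv_nu` the sds).
#' @return An object of class `ckmr_priors`.
#' @export
ckmr_priors <- function(lh) {
  nu <- c(lh$nu_female, lh$nu_male)
  structure(
    list(eta_mean = log(lh$eta), eta_sd = lh$prior_sd_eta,
         nu_mean = nu, nu_sd = lh$prior_cv_nu * nu,
         max_age = lh$max_age),
    class = "ckmr_priors"
  )
}

theta_names <- c("R0", "leta1", "leta2", "leta3",
                 "nuF1", "nuF2", "nuM1", "nuM2")

#' Assemble a parameter vector theta
#'
#' `theta = (R0, log eta_1..3, nu_{f,1}, nu_{f,2}, nu_{m,1}, nu_{m,2})`:
#' log initial recruitment per sex plus the survival and fecundity curve
#' parameters the estimator fits.
#'
#' @param R0 Log of the expected number of age-0 animals per sex in year 1.
#' @param eta RAW survival parameters (natural scale; stored as logs).
#' @param nu_female,nu_male Logistic fecundity parameters per sex.
#' @return A named numeric vector of length 8.
#' @export
make_theta <- function(R0, eta, nu_female, nu_male) {
  setNames(c(R0, log(eta), nu_female, nu_male), theta_names)
}

# theta implied by a life history plus a known initial recruitment level
theta_from_truth <- function(lh, recruits_per_sex) {
  make_theta(log(recruits_per_sex), lh$eta, lh$nu_female, lh$nu_male)
}

#' Deterministic age-structured dynamics implied by theta
#'
#' Projects expected per-sex abundance `N_{a,t}` for ages 0..37 and years
#' `1..n_years` under a postbreeding census. Year 1 assumes a stable age
#' structure seeded by `N_{0,1} = exp(R0)` and the survivorship recursion
#' `N_{a+1,1} = N_{a,1} S_a`; later years follow `N_{a+1,t} = N_{a,t-1} S_a`
#' with recruitment `N_{0,t} = 0.5 * sum_a N_{a,t,female} f_{a-1,female}`
#' (animals counted at census age `a` bred at age `a - 1`). Survival is
#' sex-independent, so one matrix serves both sexes; recruits split equally.
#'
#' @param theta Parameter vector from [make_theta()].
#' @param n_years Number of projected years (default 60).
#' @param max_age Maximum age (37).
#' @return An object of class `ckmr_dynamics`: list with `N` (38 x n_years
#'   per-sex matrix), `S`, `fF`, `fM` (schedules over ages 0..37), `C`
#'   (cumulative survivorship `l_a`), `DF`, `DM` (total expected
#'   reproductive output `sum_a N_{a,t,g} f_{a-1,g}` per year and sex), and
#'   `ok` (FALSE if the projection overflowed).
#' @export
project_dynamics <- function(theta, n_years = 60L, max_age = 37L) {
  eta <- exp(theta[2:4])
  S <- c(raw_survival(0:(max_age - 1L), eta), 0)
  fF <- logistic_fecundity(0:max_age, theta[5:6])
  fM <- logistic_fecundity(0:max_age, theta[7:8])
  k <- max_age + 1L

  N <- matrix(0, k, n_years)
  N[1, 1] <- exp(theta[1])
  for (a in 1:(k - 1L)) N[a + 1L, 1] <- N[a, 1] * S[a]
  # f_{a-1} aligned with census age a: index a+1 in N pairs with fF[a]
  fshift_F <- c(0, fF[1:(k - 1L)])   # f_{a-1} for a = 0..max_age (f_{-1} = 0)
  fshift_M <- c(0, fM[1:(k - 1L)])
  for (t in 2:n_years) {
    N[2:k, t] <- N[1:(k - 1L), t - 1L] * S[1:(k - 1L)]
    N[1, t] <- 0.5 * sum(N[, t] * fshift_F)
  }
  ok <- all(is.finite(N))
  C <- cumprod(c(1, S[1:(k - 1L)]))   # l_a = prod_{x < a} S_x, a = 0..max_age
  DF <- colSums(N * fshift_F)
  DM <- colSums(N * fshift_M)
  structure(
    list(N = N, S = S, fF = fF, fM = fM, C = C, DF = DF, DM = DM,
         n_years = n_years, max_age = max_age, theta = theta, ok = ok),
    class = "ckmr_dynamics"
  )
}

#' Parent-offspring pair probability
#'
#' The expected-relative-reproductive-output ratio for a comparison with
#' parent birth year `b1`, parent capture year `y1`, offspring birth year
#' `b2` and parent sex `g`:
#' `P = f_{b2-b1-1,g} / sum_a N_{a,b2,g} f_{a-1,g}` when the parent was
#' captured at or after the offspring's birth (`y1 >= b2`) and the implied
#' breeding age `b2 - b1 - 1` lies in 0..36; 0 otherwise.
#'
#' @param b1,y1,b2 Integer years (vectorized).
#' @param g Parent sex, `"female"` or `"male"` (vectorized).
#' @param dyn A [project_dynamics()] result.
#' @return Probabilities in `[0, 1)`.
#' @export
pop_probability <- function(b1, y1, b2, g, dyn) {
  n <- max(length(b1), length(y1), length(b2), length(g))
  b1 <- rep_len(b1, n); y1 <- rep_len(y1, n)
  b2 <- rep_len(b2, n); g <- rep_len(g, n)
  age_breed <- b2 - b1 - 1L
  valid <- y1 >= b2 & age_breed >= 0L & age_breed < dyn$max_age &
    b2 >= 1L & b2 <= dyn$n_years
  p <- numeric(n)
  if (any(valid)) {
    i <- which(valid)
    f <- ifelse(g[i] == "female", dyn$fF[age_breed[i] + 1L],
                dyn$fM[age_breed[i] + 1L])
    d <- ifelse(g[i] == "female", dyn$DF[b2[i]], dyn$DM[b2[i]])
    bad_d <- !is.finite(d) | d <= 0
    if (any(bad_d)) {
      warn("zero total reproductive output in a comparison year; returning 0.")
      f[bad_d] <- 0
      d[bad_d] <- 1
    }
    p[i] <- f / d
  }
  p
}

#' Half-sibling pair probability
#'
#' Sums over the possible ages of the shared parent: the probability the
#' parent (of sex `g`) had census age `a` in the older sibling's birth year
#' `b1` given it bred then, times survival from `b1` to `b2`, times its
#' relative reproductive output in `b2`:
#' \deqn{P' = \sum_a \frac{N_{a,b1,g} f_{a-1,g}}{\sum_{a'} N_{a',b1,g}
#'   f_{a'-1,g}} \left(\prod_{y=b1}^{b2-1} S_{a+y-b1}\right)
#'   \frac{f_{a+b2-b1-1,g}}{\sum_{a'} N_{a',b2,g} f_{a'-1,g}}.}
#' Terms requiring survival or breeding past age 37 vanish.
#'
#' @param b1,b2 Older and younger sibling birth years (`b1 < b2`),
#'   vectorized.
#' @param g Shared parent sex (vectorized).
#' @param dyn A [project_dynamics()] result.
#' @return Probabilities in `[0, 1)`.
#' @export
hsp_probability <- function(b1, b2, g, dyn) {
  n <- max(length(b1), length(b2), length(g))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n); g <- rep_len(g, n)
  if (any(b1 >= b2)) {
    abort("hsp_probability requires b1 < b2 (same-age comparisons are excluded).",
          class = "kinmix_parameter_error")
  }
  Pmat <- hsp_probability_matrix(dyn)
  out <- numeric(n)
  for (i in seq_len(n)) {
    delta <- b2[i] - b1[i]
    if (delta > dyn$max_age) next
    out[i] <- Pmat[[g[i]]][b1[i], delta]
  }
  out
}

# P'(b1, delta, g) for all b1 in 1..n_years, delta in 1..max_age, as two
# matrices (one per parent sex). Survival products collapse to survivorship
# ratios C_{a+delta} / C_a with C_a = 0 past the age cap.
hsp_probability_matrix <- function(dyn) {
  k <- dyn$max_age + 1L
  Cx <- c(dyn$C, numeric(dyn$max_age + 1L))       # l_a, zero past max_age
  build <- function(f, D) {
    fshift <- c(0, f[1:(k - 1L)])
    Q <- dyn$N * fshift
    Q <- sweep(Q, 2L, ifelse(D > 0, D, Inf), "/")
    Q <- Q / dyn$C
    fx <- c(f, numeric(dyn$max_age + 1L))
    M <- matrix(0, k, dyn$max_age)
    a <- 0:(k - 1L)
    for (delta in 1:dyn$max_age) {
      M[, delta] <- Cx[a + delta + 1L] * fx[a + delta]
    }
    P <- crossprod(Q, M)                           # [b1, delta] numerators
    for (delta in 1:dyn$max_age) {
      b2 <- seq_len(dyn$n_years) + delta
      ok <- b2 <= dyn$n_years
      P[ok, delta] <- P[ok, delta] / ifelse(D[b2[ok]] > 0, D[b2[ok]], Inf)
      P[!ok, delta] <- 0
    }
    P
  }
  list(female = build(dyn$fF, dyn$DF), male = build(dyn$fM, dyn$DM))
}

# Precompute index structures so the objective is cheap to evaluate many
# times. Cells whose kinship probability is structurally zero (support
# conditions independent of theta) contribute exactly zero for every theta
# and are dropped; a match in such a cell is an impossible event.
prepare_likelihood_data <- function(tallies, n_years = 60L, max_age = 37L) {
  pop <- tallies$pop
  age_breed <- pop$b2 - pop$b1 - 1L
  pop_valid <- pop$y1 >= pop$b2 & age_breed >= 0L & age_breed < max_age &
    pop$b2 >= 1L & pop$b2 <= n_years
  if (any(pop$m[!pop_valid] > 0)) {
    abort("POP match found in a structurally impossible comparison cell.",
          class = "kinmix_internal_error")
  }
  pop <- pop[pop_valid, ]
  hsp <- tallies$hsp
  hsp_valid <- (hsp$b2 - hsp$b1) <= max_age & hsp$b1 >= 1L &
    hsp$b2 <= n_years
  if (any(hsp$m[!hsp_valid] > 0)) {
    abort("HSP match found in a structurally impossible comparison cell.",
          class = "kinmix_internal_error")
  }
  hsp <- hsp[hsp_valid, ]
  list(
    pop_female = pop[pop$g == "female", ],
    pop_male = pop[pop$g == "male", ],
    hsp_female = hsp[hsp$g == "female", ],
    hsp_male = hsp[hsp$g == "male", ],
    n_years = n_years, max_age = max_age
  )
}

# Poisson negative log-likelihood terms per cell: mu - m log(mu), with the
# conventions mu = n P, cells with P = 0 and m = 0 contributing 0, and
# P = 0 with m > 0 contributing +Inf.
poisson_nll_terms <- function(n, m, P) {
  mu <- n * P
  out <- mu
  pos <- m > 0
  if (any(pos)) {
    out[pos] <- ifelse(mu[pos] > 0, mu[pos] - m[pos] * log(mu[pos]), Inf)
  }
  out
}

#' Penalized negative log pseudolikelihood
#'
#' The naive CKMR objective: Poisson-approximated pairwise likelihood over
#' POP and HSP tally cells plus Gaussian prior penalties,
#' \deqn{\Lambda(\theta) = \sum_{cells} \{n P(\theta) - m \log(n P(\theta))\}
#'   + \tfrac12 \sum_i \left(\frac{\tilde\eta_i - \eta_i}{\sigma_i}\right)^2
#'   + \tfrac12 \sum_{g,i} \left(\frac{\tilde\nu_{g,i} -
#'   \nu_{g,i}}{\tau_{g,i}}\right)^2,}
#' dropping constants in theta. Cells with `n = 0`, or with structurally
#' zero probability and `m = 0`, contribute exactly zero; a match in a
#' zero-probability cell yields `+Inf`, as does any non-finite projection.
#'
#' @param theta Parameter vector ([make_theta()]).
#' @param tallies A [tally_comparisons()] result.
#' @param priors A [ckmr_priors()].
#' @param n_years Projection span (default 60).
#' @return A scalar objective value (possibly `Inf`).
#' @export
neg_log_pseudolikelihood <- function(theta, tallies, priors, n_years = 60L) {
  ld <- prepare_likelihood_data(tallies, n_years = n_years,
                                max_age = priors$max_age)
  nll_from_data(theta, ld, priors)
}

nll_from_data <- function(theta, ld, priors) {
  if (any(!is.finite(theta))) return(Inf)
  dyn <- project_dynamics(theta, n_years = ld$n_years, max_age = ld$max_age)
  if (!dyn$ok) return(Inf)

  total <- 0
  pop_part <- function(cells, f, D) {
    if (!nrow(cells)) return(0)
    age_breed <- cells$b2 - cells$b1
    P <- f[age_breed] / D[cells$b2]       # f_{b2-b1-1}: index (b2-b1-1)+1
    sum(poisson_nll_terms(cells$n, cells$m, P))
  }
  total <- total +
    pop_part(ld$pop_female, dyn$fF, dyn$DF) +
    pop_part(ld$pop_male, dyn$fM, dyn$DM)

  Pmat <- hsp_probability_matrix(dyn)
  hsp_part <- function(cells, Pm) {
    if (!nrow(cells)) return(0)
    P <- Pm[cbind(cells$b1, cells$b2 - cells$b1)]
    sum(poisson_nll_terms(cells$n, cells$m, P))
  }
  total <- total +
    hsp_part(ld$hsp_female, Pmat$female) +
    hsp_part(ld$hsp_male, Pmat$male)

  pen <- 0.5 * sum(((theta[2:4] - priors$eta_mean) / priors$eta_sd)^2) +
    0.5 * sum(((theta[5:8] - priors$nu_mean) / priors$nu_sd)^2)
  total + pen
}

# central finite-difference Hessian
fd_hessian <- function(fn, x, rel_step = 1e-3) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 0.1)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in 1:p) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

#' Fit the naive CKMR model
#'
#' Minimizes the penalized negative log pseudolikelihood over
#' `theta = (R0, log eta, nu)` with `nlminb` (bounded quasi-Newton),
#' starting from the prior means with `R0` initialized by a coarse
#' one-dimensional profile of the objective. On non-convergence the fit is
#' retried from jittered starts (up to 3 attempts). The Hessian is computed
#' by central finite differences at the optimum; standard errors are the
#' square roots of the inverse-Hessian diagonal and are withheld (NA) when
#' the Hessian is not positive definite.
#'
#' @param tallies A [tally_comparisons()] result.
#' @param priors A [ckmr_priors()].
#' @param init Optional starting `theta` (default: prior means + profiled
#'   `R0`).
#' @param n_years Projection span (default 60).
#' @param compute_hessian Set `FALSE` to skip uncertainty (faster).
#' @return An object of class `ckmr_fit`: `theta` (estimates), `se`,
#'   `objective`, `convergence` (TRUE/FALSE), `hessian`, `dynamics` (the
#'   projection at the optimum), `priors`, and bookkeeping fields.
#' @export
fit_ckmr <- function(tallies, priors, init = NULL, n_years = 60L,
                     compute_hessian = TRUE) {
  if (!nrow(tallies$pop) && !nrow(tallies$hsp)) {
    abort("empty tallies.", class = "kinmix_parameter_error")
  }
  ld <- prepare_likelihood_data(tallies, n_years = n_years,
                                max_age = priors$max_age)
  obj <- function(th) nll_from_data(th, ld, priors)

  if (is.null(init)) {
    base <- setNames(c(0, priors$eta_mean, priors$nu_mean), theta_names)
    prof <- vapply(seq(2, 12, by = 0.5),
                   function(r0) { th <- base; th[1] <- r0; obj(th) },
                   numeric(1))
    base[1] <- seq(2, 12, by = 0.5)[which.min(prof)]
    init <- base
  }
  lower <- c(0, priors$eta_mean - 10 * priors$eta_sd,
             pmax(priors$nu_mean - 10 * priors$nu_sd, c(1e-3, 0, 1e-3, 0)))
  upper <- c(20, priors$eta_mean + 10 * priors$eta_sd,
             priors$nu_mean + 10 * priors$nu_sd)

  fit <- NULL
  for (attempt in 1:3) {
    start <- if (attempt == 1) init else {
      pmin(pmax(init + stats::rnorm(length(init), 0, 0.1 * attempt), lower),
           upper)
    }
    fit <- nlminb(start, obj, lower = lower, upper = upper,
                  control = list(eval.max = 1000, iter.max = 500))
    if (fit$convergence == 0) break
  }
  theta_hat <- setNames(fit$par, theta_names)
  converged <- fit$convergence == 0

  hessian <- NULL; se <- rep(NA_real_, length(theta_hat))
  names(se) <- theta_names
  if (compute_hessian && converged) {
    hessian <- fd_hessian(obj, theta_hat)
    ch <- tryCatch(chol(hessian), error = function(e) NULL)
    if (!is.null(ch)) {
      se <- sqrt(diag(chol2inv(ch)))
      names(se) <- theta_names
    } else {
      warn("Hessian not positive definite at the optimum; SEs withheld.")
    }
  }

  structure(
    list(theta = theta_hat, se = se, objective = fit$objective,
         convergence = converged, message = fit$message, hessian = hessian,
         dynamics = project_dynamics(theta_hat, n_years = n_years,
                                     max_age = priors$max_age),
         priors = priors, n_years = n_years,
         n_pop_matches = sum(tallies$pop$m), n_hsp_matches = sum(tallies$hsp$m),
         n_samples = tallies$n_samples),
    class = "ckmr_fit"
  )
}

#' @export
print.ckmr_fit <- function(x, ...) {
  cat("<ckmr_fit>\n")
  cat(sprintf("  converged: %s   objective: %.3f\n", x$convergence, x$objective))
  cat(sprintf("  matches: %d POP, %d HSP from %d samples\n",
              x$n_pop_matches, x$n_hsp_matches, x$n_samples))
  est <- derived_abundance(x)
  cat(sprintf("  mean ages-2+ abundance over years %d-%d: %.0f\n",
              min(est$year), max(est$year), mean(est$abundance)))
  invisible(x)
}

#' @rdname fit_ckmr
#' @param x A `ckmr_fit`.
#' @param ... Unused.
#' @export
tidy.ckmr_fit <- function(x, ...) {
  tibble(term = theta_names, estimate = unname(x$theta),
         std.error = unname(x$se))
}

#' @rdname fit_ckmr
#' @export
glance.ckmr_fit <- function(x, ...) {
  tibble(objective = x$objective, converged = x$convergence,
         n_samples = x$n_samples, n_pop_matches = x$n_pop_matches,
         n_hsp_matches = x$n_hsp_matches)
}

#' Estimated abundance by year
#'
#' Sums projected abundance over ages `min_age`+ and both sexes at the
#' fitted parameters.
#'
#' @param fit A [fit_ckmr()] result (or a `ckmr_dynamics`).
#' @param years Years to report (default the final 20 projected years, the
#'   sampling window under the standard design).
#' @param min_age Minimum age (default 2: subadults and adults).
#' @return A tibble `year, abundance`.
#' @export
derived_abundance <- function(fit, years = NULL, min_age = 2) {
  dyn <- if (inherits(fit, "ckmr_dynamics")) fit else fit$dynamics
  if (is.null(years)) years <- (dyn$n_years - 19L):dyn$n_years
  rows <- if (min_age > dyn$max_age) integer(0) else
    (min_age + 1L):(dyn$max_age + 1L)
  ab <- if (length(rows)) 2 * colSums(dyn$N[rows, years, drop = FALSE]) else
    numeric(length(years))
  tibble(year = years, abundance = ab)
}

#' Posterior-SE to prior-SD ratios
#'
#' For each of the three survival parameters `SE(log eta_i) / sigma_i` and
#' each of the four fecundity parameters `SE(nu_{g,i}) / tau_{g,i}`. Ratios
#' well below 1 indicate the kinship data add information beyond the prior.
#'
#' @param fit A converged [fit_ckmr()] with finite SEs.
#' @return A tibble `term, se, prior_sd, ratio` with seven rows.
#' @export
se_prior_ratios <- function(fit) {
  if (any(!is.finite(fit$se[2:8]))) {
    abort("standard errors unavailable (fit not converged or Hessian not PD).",
          class = "kinmix_fit_error")
  }
  prior_sd <- c(fit$priors$eta_sd, fit$priors$nu_sd)
  tibble(
    term = theta_names[2:8],
    se = unname(fit$se[2:8]),
    prior_sd = prior_sd,
    ratio = unname(fit$se[2:8]) / prior_sd
  )
}

#' Estimated survival and fecundity schedules from a fit
#'
#' @param fit A [fit_ckmr()] result.
#' @return A tibble `age, S_a, f_a_female, f_a_male` at the fitted
#'   parameters.
#' @export
estimated_schedules <- function(fit) {
  dyn <- fit$dynamics
  tibble(age = 0:dyn$max_age, S_a = dyn$S,
         f_a_female = dyn$fF, f_a_male = dyn$fM)
}
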