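#' Parametric life history for a long-lived mammal
#'
#' Bundles the age-specific survival and fecundity schedules used both to
#' generate data (individual-based simulator) and to parameterize the CKMR
#' estimator, together with the hyperparameters of the Gaussian priors placed
#' on those parameters at estimation time.
#'
#' Annual survival follows a 3-parameter reduced additive Weibull (RAW) curve
#' \deqn{S_a = \exp\{-(\eta_1 a)^{\eta_2} - (\eta_1 a)^{1/\eta_2} - \eta_3 a\},}
#' and fecundity-at-age for each sex is logistic,
#' \deqn{f_{a,g} = 1 / (1 + \exp\{-\nu_{g,1}(a - \nu_{g,2})\}).}
#' Survival past age `max_age` (37) is treated as zero: an animal reaching
#' census age 37 dies deterministically the following year.
#'
#' The default parameter values emulate a bearded-seal-like life history:
#' high annual survival at prime ages declining with senescence, female
#' fecundity rising to near 1 with a midpoint near age 5, and a later male
#' midpoint near age 7. `eta[3]` is the senescence/background hazard term that
#' [calibrate_stationarity()] tunes so the population growth rate is 1.
#'
#' @param eta Positive reals `c(eta1, eta2, eta3)` of the RAW survival curve.
#' @param nu_female,nu_male Logistic fecundity parameters `c(slope, midpoint)`
#'   per sex; slope > 0, midpoint >= 0 (years).
#' @param max_age Maximum modelled age (integer, 37).
#' @param prior_sd_eta Prior standard deviations `sigma_i` for the log-scale
#'   RAW parameters.
#' @param prior_cv_nu Prior coefficient of variation for fecundity parameters;
#'   prior sds are `tau_{g,i} = prior_cv_nu * nu_{g,i}`.
#'
#' @return An object of class `life_history`.
#' @seealso [raw_survival()], [logistic_fecundity()], [calibrate_stationarity()]
#' @export
#' @examples
#' lh <- life_history()
#' tidy(calibrate_stationarity(lh))
life_history <- function(eta = c(0.012, 1.25, 0.002),
                         nu_female = c(1.3, 5),
                         nu_male = c(1.1, 7),
                         max_age = 37L,
                         prior_sd_eta = c(0.2, 0.15, 0.3),
                         prior_cv_nu = 0.4) {
  if (length(eta) != 3 || any(!is.finite(eta)) || any(eta <= 0)) {
    abort("`eta` must be three positive finite reals.", class = "kinmix_parameter_error")
  }
  for (nu in list(nu_female, nu_male)) {
    if (length(nu) != 2 || any(!is.finite(nu)) || nu[1] <= 0 || nu[2] < 0) {
      abort("fecundity parameters must be c(slope > 0, midpoint >= 0).",
            class = "kinmix_parameter_error")
    }
  }
  if (max_age != 37L) {
    abort("`max_age` must be 37: the schedules are defined on ages 0..37.",
          class = "kinmix_parameter_error")
  }
  if (length(prior_sd_eta) != 3 || any(prior_sd_eta <= 0) || prior_cv_nu <= 0) {
    abort("prior sds must be positive.", class = "kinmix_parameter_error")
  }
  structure(
    list(eta = unname(eta),
         nu_female = unname(nu_female),
         nu_male = unname(nu_male),
         max_age = as.integer(max_age),
         prior_sd_eta = unname(prior_sd_eta),
         prior_cv_nu = prior_cv_nu),
    class = "life_history"
  )
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history>\n")
  cat(sprintf("  RAW survival eta:    %.5f, %.4f, %.5f\n", x$eta[1], x$eta[2], x$eta[3]))
  cat(sprintf("  fecundity female:    slope %.3f, midpoint %.2f\n",
              x$nu_female[1], x$nu_female[2]))
  cat(sprintf("  fecundity male:      slope %.3f, midpoint %.2f\n",
              x$nu_male[1], x$nu_male[2]))
  cat(sprintf("  max age: %d   lambda: %.5f\n", x$max_age,
              growth_rate(build_leslie(x))))
  invisible(x)
}

#' Reduced additive Weibull annual survival
#'
#' Annual probability of surviving from age `a` to `a + 1`,
#' `S_a = exp(-(eta1*a)^eta2 - (eta1*a)^(1/eta2) - eta3*a)`. At `a = 0` all
#' three hazard terms vanish and the value is exactly 1.
#'
#' @param age Integer age(s) in years, >= 0.
#' @param eta Three positive RAW parameters.
#' @return Survival probabilities in (0, 1], vectorized over `age`.
#' @export
raw_survival <- function(age, eta) {
  if (any(age < 0)) abort("`age` must be >= 0.", class = "kinmix_parameter_error")
  if (length(eta) != 3 || any(eta <= 0)) {
    abort("`eta` must be three positive reals.", class = "kinmix_parameter_error")
  }
  x <- eta[1] * age
  exp(-(x^eta[2]) - (x^(1 / eta[2])) - eta[3] * age)
}

#' Logistic fecundity-at-age
#'
#' `f_{a,g} = 1 / (1 + exp(-nu1 * (a - nu2)))`: the probability that a female
#' of age `a` breeds in a year (or, for males, the relative weight with which
#' a male of age `a` is selected as a mate).
#'
#' @param age Integer age(s) in years, >= 0.
#' @param nu `c(slope, midpoint)` of the logistic curve.
#' @return Probabilities in (0, 1), vectorized over `age`; nondecreasing in age.
#' @export
logistic_fecundity <- function(age, nu) {
  if (any(age < 0)) abort("`age` must be >= 0.", class = "kinmix_parameter_error")
  1 / (1 + exp(-nu[1] * (age - nu[2])))
}

# Survival vector over ages 0..max_age with the age cap applied:
# S_a from the RAW curve for a < max_age, and S_{max_age} = 0 (an animal at
# census age 37 dies deterministically in the following year).
survival_vector <- function(lh) {
  s <- raw_survival(0:(lh$max_age - 1L), lh$eta)
  c(s, 0)
}

fecundity_vector <- function(lh, sex = c("female", "male")) {
  sex <- match.arg(sex)
  nu <- if (sex == "female") lh$nu_female else lh$nu_male
  logistic_fecundity(0:lh$max_age, nu)
}

#' Tabulate the life-history schedules
#'
#' @param x A `life_history`.
#' @param ... Unused.
#' @return A tibble with columns `age`, `S_a` (annual survival, with the
#'   age-37 cap applied), `f_a_female`, `f_a_male`.
#' @export
tidy.life_history <- function(x, ...) {
  tibble(
    age = 0:x$max_age,
    S_a = survival_vector(x),
    f_a_female = fecundity_vector(x, "female"),
    f_a_male = fecundity_vector(x, "male")
  )
}

#' Female-only Leslie matrix under a postbreeding census
#'
#' State vector is census abundance at ages `0..max_age`. Survivors of census
#' age `a` breed with fecundity `f_a` before being counted at age `a + 1`, so
#' first-row (recruitment) entries are `0.5 * S_a * f_{a,female}` (half of
#' offspring are female) and subdiagonal entries are `S_a`. The age cap makes
#' the final class non-surviving.
#'
#' @param lh A `life_history`.
#' @return A `(max_age + 1)` square nonnegative matrix.
#' @export
build_leslie <- function(lh) {
  s <- survival_vector(lh)
  f <- fecundity_vector(lh, "female")
  k <- lh$max_age + 1L
  m <- matrix(0, k, k)
  m[1, ] <- 0.5 * s * f
  m[cbind(2:k, 1:(k - 1))] <- s[1:(k - 1)]
  m
}

#' Dominant eigenvalue (finite population growth rate)
#'
#' @param leslie A nonnegative square projection matrix.
#' @return The modulus of the dominant eigenvalue, lambda.
#' @export
growth_rate <- function(leslie) {
  ev <- eigen(leslie, only.values = TRUE)$values
  if (!length(ev) || any(!is.finite(Mod(ev)))) {
    abort("eigen decomposition failed.", class = "kinmix_numerical_error")
  }
  max(Mod(ev))
}

#' Calibrate the survival curve to a stationary population
#'
#' Adjusts the linear-hazard term `eta3` by bisection until the dominant
#' eigenvalue of the Leslie matrix equals `target` (1 for a stationary
#' population). Increasing `eta3` increases mortality at every age and so
#' strictly decreases lambda, which guarantees the bisection is well posed
#' whenever the bracket straddles the target.
#'
#' @param lh A `life_history`; only `eta[3]` is modified.
#' @param target Target growth rate (default 1).
#' @param tol Absolute tolerance on lambda (default 1e-6, comfortably inside
#'   the 1e-4 the rest of the package assumes).
#' @param bracket Search interval for `eta3`.
#' @return The calibrated `life_history`.
#' @export
calibrate_stationarity <- function(lh, target = 1, tol = 1e-6,
                                   bracket = c(1e-8, 2)) {
  lam <- function(e3) {
    lh2 <- lh
    lh2$eta[3] <- e3
    growth_rate(build_leslie(lh2))
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- lam(lo) - target
  f_hi <- lam(hi) - target
  if (f_lo < 0 && abs(f_lo) < tol) { lh$eta[3] <- lo; return(lh) }
  if (f_lo * f_hi > 0) {
    abort(sprintf(
      "calibration bracket [%g, %g] does not straddle lambda = %g (lambda range [%g, %g]).",
      lo, hi, target, target + f_hi, target + f_lo),
      class = "kinmix_calibration_error")
  }
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    f_mid <- lam(mid) - target
    if (abs(f_mid) < tol) break
    if (f_mid * f_lo > 0) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  lh$eta[3] <- mid
  lh
}

#' Default calibrated life history
#'
#' The package's standard study conditions: the default [life_history()]
#' with `eta3` calibrated so lambda = 1.
#'
#' @param ... Passed to [life_history()].
#' @return A calibrated `life_history`.
#' @export
calibrated_life_history <- function(...) {
  calibrate_stationarity(life_history(...))
}

#' Stable age distribution
#'
#' Normalized dominant right eigenvector of the female Leslie matrix; since
#' survival is sex-independent the same proportions apply to each sex. At
#' lambda = 1 this is proportional to cumulative survivorship
#' `l_a = prod_{x < a} S_x`.
#'
#' @param lh A `life_history` (usually calibrated so lambda is about 1).
#' @return A tibble with columns `age` and `proportion` (sums to 1).
#' @export
stable_age_distribution <- function(lh) {
  m <- build_leslie(lh)
  es <- eigen(m)
  v <- Re(es$vectors[, which.max(Mod(es$values))])
  v <- abs(v)
  tibble(age = 0:lh$max_age, proportion = v / sum(v))
}
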