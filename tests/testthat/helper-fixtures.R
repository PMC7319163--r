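# Shared fixtures and independent oracle implementations.

# calibrated default life history, computed once per test run
test_lh <- local({
  lh <- NULL
  function() {
    if (is.null(lh)) lh <<- calibrated_life_history()
    lh
  }
})

# a small-but-founder-safe study: sampling starts late enough that every
# sampled animal (age at death <= 37) was born in model year >= 1
small_config <- function(seed, dispersal = "complete_mixing",
                         sampling = "uniform", n0 = 800L, n_years = 45L,
                         sample_years = 39:45, n_per_year = 60L) {
  kin_config(lh = test_lh(), dispersal = dispersal, sampling = sampling,
             n0 = n0, n_years = n_years, sample_years = sample_years,
             n_per_year = n_per_year, seed = seed)
}

# O(n^2) brute-force kin finders over all sampled pairs (oracle)
brute_force_pops <- function(samples, pedigree) {
  ped <- pedigree[match(samples$id, pedigree$id), ]
  n <- nrow(samples)
  hits <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!is.na(ped$mother_id[j]) && ped$mother_id[j] == samples$id[i]) hits <- hits + 1L
    if (!is.na(ped$father_id[j]) && ped$father_id[j] == samples$id[i]) hits <- hits + 1L
  }
  hits
}

brute_force_hsps <- function(samples, pedigree) {
  ped <- pedigree[match(samples$id, pedigree$id), ]
  n <- nrow(samples)
  mat <- pat <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sm <- !is.na(ped$mother_id[i]) && !is.na(ped$mother_id[j]) &&
      ped$mother_id[i] == ped$mother_id[j]
    sf <- !is.na(ped$father_id[i]) && !is.na(ped$father_id[j]) &&
      ped$father_id[i] == ped$father_id[j]
    if (sm && !sf) mat <- mat + 1L
    if (sf && !sm) pat <- pat + 1L
  }
  c(maternal = mat, paternal = pat)
}

# independent two-sample KS implementation: D over the pooled support and
# the asymptotic p-value 2 * sum (-1)^(k-1) exp(-2 k^2 t^2)
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  D <- max(abs(Fx - Fy))
  neff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(neff) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(D = D, p = max(0, min(1, p)))
}

# direct triple-sum transcription of the half-sibling probability (oracle)
oracle_hsp <- function(b1, b2, g, dyn) {
  if (b2 > dyn$n_years) return(0)
  f <- if (g == "female") dyn$fF else dyn$fM
  D <- if (g == "female") dyn$DF else dyn$DM
  fidx <- function(a) if (a >= 0 && a <= dyn$max_age) f[a + 1] else 0
  total <- 0
  for (a in 0:dyn$max_age) {
    num1 <- dyn$N[a + 1, b1] * fidx(a - 1)
    if (num1 == 0) next
    surv <- 1
    for (y in b1:(b2 - 1)) {
      ai <- a + y - b1
      surv <- surv * (if (ai <= dyn$max_age) dyn$S[ai + 1] else 0)
    }
    total <- total + (num1 / D[b1]) * surv * fidx(a + b2 - b1 - 1) / D[b2]
  }
  total
}

# a six-animal worked sample set with hand-checkable kin structure:
# two adult females (1, 2), one adult male (3), three juveniles (4, 5, 6).
# 4 and 5 share mother 1 and father 3 (full siblings, different cohorts);
# 6 has mother 2 and father 3. All six sampled.
hand_fixture <- function() {
  pedigree <- tibble::tibble(
    id = 1:6,
    sex = c("female", "female", "male", "female", "male", "female"),
    birth_year = c(30L, 31L, 30L, 45L, 47L, 47L),
    death_year = c(52L, 53L, 51L, 54L, 52L, 53L),
    mother_id = c(NA, NA, NA, 1L, 1L, 2L),
    father_id = c(NA, NA, NA, 3L, 3L, 3L),
    death_cell = c(1L, 2L, 3L, 4L, 5L, 6L)
  )
  samples <- tibble::tibble(
    id = 1:6,
    sex = pedigree$sex,
    birth_year = pedigree$birth_year,
    sample_year = pedigree$death_year,
    cell = pedigree$death_cell,
    cell_x = make_grid()$centroid[pedigree$death_cell, 1],
    cell_y = make_grid()$centroid[pedigree$death_cell, 2]
  )
  list(pedigree = pedigree, samples = samples)
}
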