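# Shared fixtures and independent oracles used across test files.

# bivariate normal pairs with a given population correlation
rbvn <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

# sample correlations of B bivariate-normal samples of size n, vectorized
mc_sample_r <- function(B, n, rho, chunk = 2e4) {
  r <- numeric(0)
  left <- B
  while (left > 0) {
    m <- min(chunk, left)
    z1 <- matrix(rnorm(n * m), n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(rnorm(n * m), n)
    s1 <- colSums(z1); s2 <- colSums(z2)
    r <- c(r, (colSums(z1 * z2) - s1 * s2 / n) /
             sqrt((colSums(z1^2) - s1^2 / n) * (colSums(z2^2) - s2^2 / n)))
    left <- left - m
  }
  r
}

# closed-form OLS on points (x, y): independent oracle for fitted lines
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# hand implementation of the Holm step-down rule
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# analytic solution of the one-tissue model dC/dt = K1*Cp - k*C with
# gamma-variate input Cp = A t exp(-t/tau); oracle for the ODE solver
one_tissue_analytic <- function(t, K1, k, A, tau) {
  a <- k - 1 / tau
  if (abs(a) < 1e-12) stop("degenerate case k == 1/tau not used in tests")
  K1 * A * ((t / a - 1 / a^2) * exp(-t / tau) + exp(-k * t) / a^2)
}

# default ground truth used throughout the kinetics tests
study_truth <- function(...) kinetic_ground_truth(...)

# a null cohort at the study size with no missingness, plain marginals
gaussian_cohort_spec <- function(n, rho_bas_acc = 0, seed = 1) {
  cohort_spec(
    n_participants = n,
    rho_true = list("bas:accumbens" = rho_bas_acc),
    trait_marginals = list(
      digit_span = list(family = "gaussian", mean = 16, sd = 4),
      listening_span = list(family = "gaussian", mean = 4.5, sd = 1.25),
      bis11 = list(family = "gaussian", mean = 62, sd = 8),
      sebr = list(family = "gaussian", mean = 17, sd = 5),
      bas = list(family = "gaussian", mean = 40, sd = 5)),
    ki_marginals = list(
      caudate = list(family = "gaussian", mean = 0.015, sd = 0.00222),
      putamen = list(family = "gaussian", mean = 0.015, sd = 0.00222),
      accumbens = list(family = "gaussian", mean = 0.015, sd = 0.00222)),
    missing = NULL, seed = seed)
}

# Table of published trait x ROI correlation summaries (r, n) used by the
# summary-mode reproduction tests, with the printed inference columns.
published_correlation_summaries <- function() {
  data.frame(
    trait = rep(c("digit_span", "listening_span", "bis11", "sebr", "bas"),
                each = 3),
    roi = rep(c("caudate", "putamen", "accumbens"), 5),
    r = c(-0.035, -0.069, -0.071, 0.04, 0.002, 0.034,
          -0.048, -0.011, -0.04, 0.031, 0.017, 0.123,
          0.16, 0.174, 0.179),
    n = c(rep(94, 6), rep(66, 3), rep(92, 3), rep(94, 3)),
    p = c(0.632, 0.746, 0.751, 0.355, 0.491, 0.375,
          0.648, 0.536, 0.625, 0.386, 0.434, 0.122,
          0.062, 0.046, 0.042),
    p_adj = c(1, 1, 1, 1, 1, 1, 1, 1, 1,
              0.773, 0.773, 0.365, 0.127, 0.127, 0.127),
    bf01_dir = c(9.93, 12.19, 12.31, 5.52, 7.45, 5.78,
                 8.56, 6.98, 4.97, 6.01, 6.7, 2.24,
                 1.3, 1.02, 0.94),
    bf01_two = c(7.33, 6.25, 6.19, 7.09, 7.59, 7.22,
                 6.06, 6.48, 6.19, 7.36, 7.57, 3.92,
                 2.42, 1.93, 1.8))
}
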