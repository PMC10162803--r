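test_that("pearson_r matches the covariance formula and handles deletion", {
  expect_equal(as.numeric(pearson_r(1:10, 1:10)), 1)
  expect_equal(as.numeric(pearson_r(1:10, -(1:10))), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(as.numeric(pearson_r(x, y)), brute)
  r <- pearson_r(c(1, 2, NA, 4, 5), c(2, NA, 3, 5, 7))
  expect_equal(attr(r, "n"), 3)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("one-sided p-values agree with cor.test and are 0.5 at r = 0", {
  expect_equal(p_from_summary(0, 30), 0.5)
  set.seed(8)
  for (i in 1:5) {
    d <- rbvn(20, 0.3)
    ct <- cor.test(d[, 1], d[, 2], alternative = "greater")
    expect_equal(p_from_summary(as.numeric(pearson_r(d[, 1], d[, 2])), 20),
                 unname(ct$p.value), tolerance = 1e-10)
  }
  expect_warning(p1 <- p_from_summary(1, 10), "degenerate")
  expect_equal(p1, 0)
})

test_that("one-sided t p-value matches exhaustive permutation inference", {
  # n = 6: all 720 permutations enumerable; agreement up to the
  # discreteness of the permutation distribution
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  set.seed(12)
  for (i in 1:3) {
    d <- rbvn(6, 0.4)
    robs <- cor(d[, 1], d[, 2])
    rperm <- vapply(perms(d[, 2]), function(p) cor(d[, 1], p), numeric(1))
    p_perm <- mean(rperm >= robs - 1e-12)
    expect_equal(p_from_summary(robs, 6), p_perm, tolerance = 0.1)
  }
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p)))
  }
})

test_that("null correlation density is normalized, symmetric, flat at n = 4", {
  for (n in c(4, 10, 94))
    expect_equal(integrate(function(r) null_r_density(r, n), -1, 1,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  r <- seq(0.05, 0.95, by = 0.1)
  expect_equal(null_r_density(r, 20), null_r_density(-r, 20))
  expect_equal(null_r_density(seq(-0.9, 0.9, 0.3), 4), rep(0.5, 7))
})

test_that("exact correlation density reduces to the null and is normalized", {
  r <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(exact_r_density(r, 0, 20), null_r_density(r, 20),
               tolerance = 1e-10)
  for (case in list(c(0.3, 20), c(0.8, 10), c(-0.5, 50)))
    expect_equal(integrate(function(x) exact_r_density(x, case[1], case[2]),
                           -1, 1, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  # log-space path agrees with the direct path
  expect_equal(exact_r_density(0.4, 0.5, 200, log = TRUE),
               log(exact_r_density(0.4, 0.5, 200)))
})

test_that("exact density tracks the Monte-Carlo distribution of r", {
  set.seed(77)
  r <- mc_sample_r(4e4, 50, 0.5)
  breaks <- seq(-1, 1, by = 0.05)
  counts <- hist(r, breaks = breaks, plot = FALSE)$counts / length(r)
  probs <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(function(x) exact_r_density(x, 0.5, 50),
              breaks[i], breaks[i + 1])$value, numeric(1))
  # modal bin agrees and bin masses match within Monte-Carlo error
  expect_equal(which.max(counts), which.max(probs))
  expect_lt(max(abs(counts - probs)), 4 * sqrt(max(probs) / 4e4) + 0.002)
})

test_that("BF01 at r = 0 is identical for directional and two-sided priors", {
  for (n in c(10, 94)) for (w in c(0.5, 1, 2))
    expect_equal(bf01_correlation(0, n, c(0, 1), w),
                 bf01_correlation(0, n, c(-1, 1), w), tolerance = 1e-7)
})

test_that("directional Bayes factors are asymmetric in the direction of r", {
  # positive r: evidence against positive-H1 weaker than against negative-H1
  expect_lt(bf01_correlation(0.179, 94, c(0, 1)),
            bf01_correlation(0.179, 94, c(-1, 0)))
  expect_gt(bf01_correlation(-0.035, 94, c(0, 1)),
            bf01_correlation(-0.035, 94, c(-1, 0)))
})

test_that("Bayes factors accumulate evidence with n in the right direction", {
  # fixed true-looking r: evidence for H1 grows, BF01 -> 0
  bfs <- vapply(c(10, 50, 200, 1000), function(n)
    bf01_correlation(0.3, n, c(-1, 1)), numeric(1))
  expect_true(all(diff(bfs) < 0))
  # r = 0: evidence of absence grows with n
  bf0 <- vapply(c(10, 50, 200, 1000), function(n)
    bf01_correlation(0, n, c(-1, 1)), numeric(1))
  expect_true(all(diff(bf0) > 0))
})

test_that("robustness curves are consistent, continuous, and tend to 1", {
  rc <- bf_robustness_curve(-0.035, 94, c(0, 1),
                            widths = c(1e-4, 0.1, 0.5, 1, 1.5, 2))
  expect_equal(rc$bf01[rc$width == 1], bf01_correlation(-0.035, 94, c(0, 1)))
  # prior collapsing on the null: BF01 -> 1 (at sqrt(width) speed)
  expect_equal(rc$bf01[rc$width == 1e-4], 1, tolerance = 0.03)
  expect_warning(z <- bf_robustness_curve(0.1, 50, c(0, 1), widths = c(0, 1)),
                 "width = 0")
  expect_equal(nrow(z), 1)
  # independent coarse Gauss-Legendre quadrature oracle
  gauss_bf <- function(r, n, w, lo, hi, nodes = 64) {
    gl <- pracma::gaussLegendre(nodes, lo, hi)
    marg <- sum(gl$w * vapply(gl$x, function(p) exact_r_density(r, p, n),
                              numeric(1)) *
                  stretched_beta_density(gl$x, w, c(lo, hi)))
    null_r_density(r, n) / marg
  }
  for (w in c(0.1, 0.5, 1, 1.5, 2))
    expect_equal(bf01_correlation(0.123, 92, c(0, 1), w),
                 gauss_bf(0.123, 92, w, 0, 1), tolerance = 1e-4)
})

test_that("corr_test produces calibrated one-sided p-values under the null", {
  set.seed(2024)
  pvals <- vapply(1:300, function(s) {
    co <- simulate_cohort(gaussian_cohort_spec(94, 0, seed = 5000 + s))
    p_from_summary(as.numeric(pearson_r(co$bas, co$ki_accumbens)), 94)
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("corr_test assembles per-ROI inference and flags degeneracy", {
  co <- simulate_cohort(gaussian_cohort_spec(60, 0.3, seed = 9))
  tab <- corr_test(co, "bas")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adjusted >= tab$p_one_sided))
  expect_equal(tab$p_adjusted, holm_oracle(tab$p_one_sided))
  # a trait identical to the ki column is degenerate
  co$bas <- co$ki_accumbens
  tab2 <- corr_test(co, "bas")
  expect_true(tab2$degenerate[tab2$roi == "accumbens"])
  expect_error(corr_test(co, "nope"), "not found")
})
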