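# Gauss hypergeometric 2F1(a, b; c; z) on the log scale, by direct series.
# Used with a = b = 1/2, c = n - 1/2 and 0 < z < 1, where all terms are
# positive, the ratio test guarantees convergence, and large c makes the
# series short; log accumulation avoids overflow at large n.
log_hyp2f1 <- function(a, b, cc, z, tol = 1e-15, maxit = 100000L) {
  if (z < 0 || z >= 1) stop("series form requires 0 <= z < 1")
  s <- 1
  lt <- 0
  for (k in seq_len(maxit)) {
    lt <- lt + log(a + k - 1) + log(b + k - 1) - log(cc + k - 1) +
      log(z) - log(k)
    term <- exp(lt)
    s <- s + term
    if (term < tol * s) return(log(s))
  }
  stop("hypergeometric series failed to converge")
}

#' Null sampling density of the Pearson correlation
#'
#' Density of the sample correlation r of n bivariate-normal observations
#' when the population correlation is zero:
#' `f(r | rho = 0, n) = (1 - r^2)^((n-4)/2) / B(1/2, (n-2)/2)` on (-1, 1).
#'
#' @param r numeric, |r| < 1 (vectorized).
#' @param n sample size, >= 4.
#' @return density values.
#' @export
null_r_density <- function(r, n) {
  if (n < 4) stop("n must be >= 4")
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  exp(((n - 4) / 2) * log1p(-r^2) - lbeta(0.5, (n - 2) / 2))
}

#' Exact sampling density of the Pearson correlation
#'
#' Density of the sample correlation r of n observations from a bivariate
#' normal with population correlation rho (Hotelling's hypergeometric
#' form), evaluated in log space throughout:
#' \deqn{f(r) = \frac{(n-2)\,\Gamma(n-1)\,(1-\rho^2)^{(n-1)/2}
#'   (1-r^2)^{(n-4)/2}}{\sqrt{2\pi}\,\Gamma(n-\tfrac12)\,(1-\rho r)^{n-3/2}}
#'   \; {}_2F_1\!\left(\tfrac12,\tfrac12; n-\tfrac12;
#'   \tfrac{1+\rho r}{2}\right).}
#' Reduces to [null_r_density()] at rho = 0 and integrates to 1 over
#' (-1, 1).
#'
#' @param r sample correlation(s), |r| < 1 (vectorized).
#' @param rho population correlation, |rho| < 1.
#' @param n sample size, >= 4.
#' @param log return the log density.
#' @return (log) density values.
#' @export
exact_r_density <- function(r, rho, n, log = FALSE) {
  if (n < 4) stop("n must be >= 4")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  ld <- vapply(r, function(ri) {
    log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
      ((n - 4) / 2) * log1p(-ri^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) +
      ((3 - 2 * n) / 2) * log1p(-rho * ri) +
      log_hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * ri) / 2)
  }, numeric(1))
  if (log) ld else exp(ld)
}

#' Stretched-beta prior density on a correlation
#'
#' The Beta(1/w, 1/w) distribution linearly mapped to (-1, 1); `width = 1`
#' is the uniform ("flat") prior, small widths concentrate mass at zero.
#' Optionally truncated and renormalized to a directional interval.
#'
#' @param rho evaluation points in (-1, 1).
#' @param width prior width w in (0, 2].
#' @param interval length-2 interval, one of (-1,1), (0,1), (-1,0).
#' @return prior density values (zero outside `interval`).
#' @export
stretched_beta_density <- function(rho, width = 1, interval = c(-1, 1)) {
  if (width <= 0) stop("prior width must be > 0")
  a <- 1 / width
  dens <- stats::dbeta((rho + 1) / 2, a, a) / 2
  mass <- stats::pbeta((interval[2] + 1) / 2, a, a) -
    stats::pbeta((interval[1] + 1) / 2, a, a)
  ifelse(rho > interval[1] & rho < interval[2], dens / mass, 0)
}

check_interval <- function(interval) {
  ok <- list(c(0, 1), c(-1, 0), c(-1, 1))
  if (!any(vapply(ok, function(iv) isTRUE(all.equal(iv, as.numeric(interval))),
                  logical(1))))
    stop("interval must be one of (0,1), (-1,0), (-1,1)")
  as.numeric(interval)
}

#' Bayes factor for a correlation from summary statistics
#'
#' Evidence for the null hypothesis rho = 0 against an alternative that
#' places a stretched-beta prior on rho over a (possibly directional)
#' interval:
#' `BF01 = f(r | 0, n) / Int f(r | rho, n) pi(rho) d rho`,
#' with f the exact sampling density of r ([exact_r_density()]) and pi the
#' Beta(1/w, 1/w) prior on (-1, 1) renormalized to `interval`. `width = 1`
#' with interval (0, 1) is the flat directional prior for a positive
#' correlation; interval (-1, 1) gives the non-directional test.
#'
#' @param r observed Pearson correlation, |r| < 1.
#' @param n sample size, >= 4.
#' @param interval prior support: (0,1), (-1,0) or (-1,1).
#' @param width prior width w in (0, 2]; 1 = flat.
#' @param rel.tol quadrature relative tolerance.
#' @return BF01 (> 1 favours the null).
#' @export
bf01_correlation <- function(r, n, interval = c(0, 1), width = 1,
                             rel.tol = 1e-8) {
  interval <- check_interval(interval)
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 4) stop("n must be >= 4")
  if (width <= 0) stop("prior width must be > 0")
  integrand <- function(rho)
    vapply(rho, function(p) exact_r_density(r, p, n), numeric(1)) *
      stretched_beta_density(rho, width, interval)
  marg <- tryCatch(
    stats::integrate(integrand, interval[1], interval[2],
                     rel.tol = rel.tol, subdivisions = 400L),
    error = function(e) stop("marginal-likelihood quadrature failed: ",
                             conditionMessage(e)))
  null_r_density(r, n) / marg$value
}

#' Bayes-factor robustness over prior widths
#'
#' Recomputes BF01 across a grid of stretched-beta prior widths. As the
#' width shrinks to zero the prior collapses onto the null point and BF01
#' tends to 1; width 0 itself is excluded with a warning and reported as
#' the analytic limit 1.
#'
#' @inheritParams bf01_correlation
#' @param widths positive grid of prior widths (default 0.05..2).
#' @return data frame with columns `width`, `bf01`.
#' @export
bf_robustness_curve <- function(r, n, interval = c(0, 1),
                                widths = seq(0.05, 2, by = 0.05)) {
  if (any(widths < 0)) stop("widths must be positive")
  if (any(widths == 0)) {
    warning("width = 0 excluded; its limiting BF01 is 1 (prior collapses onto the null)")
    widths <- widths[widths > 0]
  }
  data.frame(width = widths,
             bf01 = vapply(widths, function(w)
               bf01_correlation(r, n, interval, w), numeric(1)))
}

#' Pearson correlation with pairwise deletion
#'
#' @param x,y numeric vectors of equal length; rows with a missing value
#'   in either are dropped, and the effective n is attached as an
#'   attribute.
#' @return the product-moment correlation, with attribute `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("x is constant; correlation undefined")
  if (stats::var(y) == 0) stop("y is constant; correlation undefined")
  structure(stats::cor(x, y), n = length(x))
}

#' One-sided p-value for a correlation from summary statistics
#'
#' Student-t test on `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with n - 2
#' degrees of freedom; the default alternative is a positive association.
#'
#' @param r sample correlation.
#' @param n sample size >= 4.
#' @param alternative "greater" (positive association), "less", or
#'   "two.sided".
#' @return the p-value. |r| = 1 is flagged degenerate and returns 0 or 1
#'   by sign.
#' @export
p_from_summary <- function(r, n, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 4) stop("n must be >= 4")
  if (abs(r) >= 1) {
    warning("|r| = 1 is degenerate; returning a boundary p-value")
    p_greater <- if (r > 0) 0 else 1
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p_greater <- stats::pt(t, n - 2, lower.tail = FALSE)
  }
  switch(alternative,
         greater = p_greater,
         less = 1 - p_greater,
         two.sided = 2 * min(p_greater, 1 - p_greater))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sort ascending, multiply the i-th smallest p by (m - i + 1), enforce
#' monotonicity, cap at 1; values return in input order. Wraps
#' `stats::p.adjust(method = "holm")`.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Correlation inference for one trait across striatal ROIs
#'
#' For one trait column of a cohort, computes per ROI the Pearson
#' correlation with the ROI influx rate (pairwise deletion), the one-sided
#' p-value for a positive association, the Holm adjustment across the ROI
#' family, and Bayes factors BF01 under the flat directional prior (0, 1)
#' and the flat non-directional prior (-1, 1).
#'
#' @param cohort a cohort data frame (see [simulate_cohort()] /
#'   [load_cohort()]).
#' @param trait trait column name.
#' @param rois ROI names; `ki_<roi>` columns must exist.
#' @param width prior width for the Bayes factors.
#' @return data frame, one row per ROI: `trait`, `roi`, `n`, `r`,
#'   `p_one_sided`, `p_adjusted`, `bf01_directional`, `bf01_two_sided`,
#'   `degenerate`.
#' @export
corr_test <- function(cohort, trait, rois = roi_names(), width = 1) {
  if (!trait %in% names(cohort))
    stop("trait column '", trait, "' not found in cohort")
  ki_cols <- paste0("ki_", rois)
  if (!all(ki_cols %in% names(cohort)))
    stop("missing ROI columns: ",
         paste(setdiff(ki_cols, names(cohort)), collapse = ", "))
  rows <- lapply(seq_along(rois), function(j) {
    x <- cohort[[trait]]; y <- cohort[[ki_cols[j]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) stop("fewer than 4 complete pairs for ", trait,
                          " x ", rois[j])
    r <- pearson_r(x, y)
    n <- attr(r, "n")
    r <- as.numeric(r)
    degen <- abs(r) >= 1 - 1e-12
    if (degen) r <- sign(r) * (1 - 1e-12)
    data.frame(trait = trait, roi = rois[j], n = n, r = r,
               p_one_sided = p_from_summary(r, n),
               bf01_directional = bf01_correlation(r, n, c(0, 1), width),
               bf01_two_sided = bf01_correlation(r, n, c(-1, 1), width),
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_one_sided)
  out[, c("trait", "roi", "n", "r", "p_one_sided", "p_adjusted",
          "bf01_directional", "bf01_two_sided", "degenerate")]
}

#' Correlation inference from printed summary statistics
#'
#' "Summary mode": reproduces a published correlation table from (r, n)
#' pairs alone, without raw data. Holm adjustment is applied within each
#' trait across its ROI rows.
#'
#' @param summary_df data frame with columns `trait`, `roi`, `r`, `n`.
#' @param width prior width for the Bayes factors.
#' @return data frame shaped like the output of [corr_test()].
#' @export
corr_test_summary <- function(summary_df, width = 1) {
  need <- c("trait", "roi", "r", "n")
  if (!all(need %in% names(summary_df)))
    stop("summary_df needs columns ", paste(need, collapse = ", "))
  out <- summary_df
  out$p_one_sided <- mapply(p_from_summary, out$r, out$n)
  out$p_adjusted <- stats::ave(out$p_one_sided, out$trait, FUN = holm_adjust)
  out$bf01_directional <- mapply(function(r, n)
    bf01_correlation(r, n, c(0, 1), width), out$r, out$n)
  out$bf01_two_sided <- mapply(function(r, n)
    bf01_correlation(r, n, c(-1, 1), width), out$r, out$n)
  out[, c("trait", "roi", "n", "r", "p_one_sided", "p_adjusted",
          "bf01_directional", "bf01_two_sided")]
}
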