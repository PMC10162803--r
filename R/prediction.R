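#' Out-of-sample coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. 1 means perfect
#' prediction, 0 matches an intercept-only model, and out-of-sample R2 can
#' be arbitrarily negative when the model predicts worse than the mean.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return R-squared (may be negative).
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths must match")
  if (length(y_true) < 2) stop("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true is constant; R2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return RMSE in the units of y; 0 iff the vectors are identical.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths must match")
  sqrt(mean((y_true - y_pred)^2))
}

#' Random k-fold partition
#'
#' Seeded Fisher-Yates shuffle followed by contiguous chunking into k
#' validation sets whose sizes differ by at most one.
#'
#' @param n number of observations.
#' @param k number of folds, 2 <= k <= n (k = n gives leave-one-out).
#' @param seed RNG seed or NULL (use the current RNG state).
#' @return list of k disjoint integer index vectors partitioning 1..n.
#' @export
kfold_indices <- function(n, k, seed = NULL) {
  if (k > n) stop("k must not exceed n")
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lapply(seq_len(k), function(f) perm[starts[f]:ends[f]])
}

#' Cross-validation configuration
#'
#' @param k folds (default 10).
#' @param repeats number of whole-CV repetitions (default 100).
#' @param n_permutations permutations for the null distribution
#'   (default 5000).
#' @param seed RNG seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 10, repeats = 100, n_permutations = 5000,
                      seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  if (n_permutations < 0) stop("n_permutations must be >= 0")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "cv_config")
}

# One CV repeat: simple OLS y ~ 1 + x per training set, out-of-fold
# predictions pooled. Closed-form slope/intercept via running sums keeps the
# permutation loop cheap; a zero-variance training x falls back to the
# intercept-only fit (counted in the "n_fallback" attribute).
cv_one_repeat <- function(x, y, k) {
  n <- length(x)
  folds <- kfold_indices(n, k)
  pred <- numeric(n)
  Sx <- sum(x); Sy <- sum(y); Sxx <- sum(x * x); Sxy <- sum(x * y)
  fallback <- 0L
  for (idx in folds) {
    xs <- x[idx]; ys <- y[idx]
    m <- n - length(idx)
    sx <- Sx - sum(xs); sy <- Sy - sum(ys)
    vx <- (Sxx - sum(xs * xs)) - sx * sx / m
    if (vx <= 1e-12 * max(1, Sxx)) {
      b <- 0; a <- sy / m
      fallback <- fallback + 1L
    } else {
      b <- ((Sxy - sum(xs * ys)) - sx * sy / m) / vx
      a <- sy / m - b * sx / m
    }
    pred[idx] <- a + b * xs
  }
  structure(pred, n_fallback = fallback)
}

# repeats x {r2, rmse} on pooled out-of-fold predictions; no seeding here
cv_metrics <- function(x, y, k, repeats, keep_errors = FALSE) {
  n <- length(x)
  r2 <- numeric(repeats); rm <- numeric(repeats)
  errs <- if (keep_errors) matrix(NA_real_, n, repeats) else NULL
  fallback <- 0L
  for (b in seq_len(repeats)) {
    pred <- cv_one_repeat(x, y, k)
    fallback <- fallback + attr(pred, "n_fallback")
    r2[b] <- r2_score(y, pred)
    rm[b] <- rmse(y, pred)
    if (keep_errors) errs[, b] <- pred - y
  }
  list(r2 = r2, rmse = rm, errors = errs, n_fallback = fallback)
}

#' Repeated k-fold cross-validation of a simple linear regression
#'
#' Per repeat: a fresh random partition; per fold: OLS fit of
#' `y ~ 1 + x` on the training folds and prediction of the held-out fold;
#' out-of-fold predictions are pooled within the repeat and scored with
#' [r2_score()] and [rmse()]. Means and standard errors
#' (SD across repeats / sqrt(repeats)) summarize the repeats, and the
#' per-participant prediction errors (yhat - y) of every repeat are
#' retained.
#'
#' @param x predictor values (a trait measure).
#' @param y outcome values (ROI influx rates); incomplete pairs are
#'   dropped.
#' @param cfg a [cv_config()].
#' @return object of class `cv_result`: `r2_mean`, `r2_stderr`,
#'   `rmse_mean`, `rmse_stderr`, `r2_per_repeat`, `rmse_per_repeat`,
#'   `per_repeat_errors` (n x repeats), `n`, `n_fallback`, `cfg`.
#' @export
cross_validate <- function(x, y, cfg = cv_config()) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < cfg$k) stop("need at least k complete pairs")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cv_metrics(x, y, cfg$k, cfg$repeats, keep_errors = TRUE)
  structure(list(r2_mean = mean(m$r2),
                 r2_stderr = stats::sd(m$r2) / sqrt(cfg$repeats),
                 rmse_mean = mean(m$rmse),
                 rmse_stderr = stats::sd(m$rmse) / sqrt(cfg$repeats),
                 r2_per_repeat = m$r2, rmse_per_repeat = m$rmse,
                 per_repeat_errors = m$errors,
                 n = length(x), n_fallback = m$n_fallback, cfg = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV (k = %d, %d repeats, n = %d): R2 = %.4f (SE %.4f), RMSE = %.5g (SE %.3g)\n",
              x$cfg$k, x$cfg$repeats, x$n, x$r2_mean, x$r2_stderr,
              x$rmse_mean, x$rmse_stderr))
  invisible(x)
}

#' Permutation test of cross-validated predictive accuracy
#'
#' Builds a null distribution by shuffling the outcome, leaving the
#' predictor intact, and re-running the cross-validation (one repeat per
#' permutation; the null needs only one draw per permutation). The
#' permutation p-value is the proportion of permutations whose accuracy is
#' as good or better than the observed accuracy (>= for R2, <= for RMSE),
#' taken literally with no smoothing; `smoothed = TRUE` switches to the
#' (b + 1) / (B + 1) estimator.
#'
#' @inheritParams cross_validate
#' @param smoothed use the add-one permutation-p estimator.
#' @return list with `perm_p_r2`, `perm_p_rmse`, `observed` (the
#'   [cross_validate()] result), and the null distributions `null_r2`,
#'   `null_rmse`.
#' @export
permutation_test <- function(x, y, cfg = cv_config(), smoothed = FALSE) {
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < cfg$k) stop("need at least k complete pairs")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  obs <- cv_metrics(x, y, cfg$k, cfg$repeats, keep_errors = TRUE)
  B <- cfg$n_permutations
  null_r2 <- numeric(B); null_rmse <- numeric(B)
  for (b in seq_len(B)) {
    yp <- y[sample.int(length(y))]
    pred <- cv_one_repeat(x, yp, cfg$k)
    null_r2[b] <- r2_score(yp, pred)
    null_rmse[b] <- rmse(yp, pred)
  }
  obs_r2 <- mean(obs$r2); obs_rmse <- mean(obs$rmse)
  num_r2 <- sum(null_r2 >= obs_r2)
  num_rmse <- sum(null_rmse <= obs_rmse)
  p <- if (smoothed) function(b) (b + 1) / (B + 1) else function(b) b / B
  observed <- structure(list(r2_mean = obs_r2,
                             r2_stderr = stats::sd(obs$r2) / sqrt(cfg$repeats),
                             rmse_mean = obs_rmse,
                             rmse_stderr = stats::sd(obs$rmse) / sqrt(cfg$repeats),
                             r2_per_repeat = obs$r2,
                             rmse_per_repeat = obs$rmse,
                             per_repeat_errors = obs$errors,
                             n = length(x), n_fallback = obs$n_fallback,
                             cfg = cfg),
                        class = "cv_result")
  list(perm_p_r2 = p(num_r2), perm_p_rmse = p(num_rmse),
       observed = observed, null_r2 = null_r2, null_rmse = null_rmse)
}
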