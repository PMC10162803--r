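#' Default trait and ki marginal descriptions
#'
#' Marginals are deliberately plausible rather than estimated: a normal
#' Digit Span on a 0.5 grid (the two-session average), a Listening Span on
#' the half-point grid 2..7, clipped normal BIS-11 and BAS totals, a
#' log-normal blink rate with median 17 blinks/min, and near-normal striatal
#' influx rates with SD 0.00222 min^-1 so the interquartile range is about
#' 0.003 min^-1 (IQR = 1.349 * SD for a normal).
#'
#' A marginal is a list with `family` ("gaussian" or "lognormal"), location
#' and scale (`mean`/`sd` or `meanlog`/`sdlog`), optional `lower`/`upper`
#' clipping bounds and an optional discretization `step`.
#'
#' @return named list of marginal descriptions for the five traits and
#'   three ROI influx rates.
#' @export
default_marginals <- function() {
  g <- function(mean, sd, lower = -Inf, upper = Inf, step = NA)
    list(family = "gaussian", mean = mean, sd = sd, lower = lower,
         upper = upper, step = step)
  list(
    digit_span     = g(16, 4, lower = 0, step = 0.5),
    listening_span = g(4.5, 1.25, lower = 2, upper = 7, step = 0.5),
    bis11          = g(62, 8, lower = 30, upper = 120, step = 1),
    sebr           = list(family = "lognormal", meanlog = log(17),
                          sdlog = 0.5, lower = 0, upper = Inf, step = NA),
    bas            = g(40, 5, lower = 17, upper = 68, step = 1),
    ki_caudate     = g(0.015, 0.00222, lower = 0),
    ki_putamen     = g(0.015, 0.00222, lower = 0),
    ki_accumbens   = g(0.015, 0.00222, lower = 0)
  )
}

trait_names <- function() c("digit_span", "listening_span", "bis11", "sebr", "bas")
roi_names <- function() c("caudate", "putamen", "accumbens")

#' Specification of a synthetic cohort
#'
#' Describes a cohort generated by a Gaussian copula: latent multivariate
#' normal with unit variances, correlation `rho_true` between each
#' (trait, ROI) pair, `inter_roi_rho` among the three ROI influx rates, and
#' independent traits; each latent coordinate is then pushed through a
#' monotone transform to its marginal. Defaults encode the study design:
#' n = 94 PET participants, per-measure completeness 66/94 for BIS-11 and
#' 92/94 for sEBR, and the observed inter-ROI correlation structure
#' (0.751 caudate-putamen, 0.649 caudate-accumbens, 0.787 putamen-accumbens).
#'
#' @param n_participants cohort size (>= 4).
#' @param rho_true 5 x 3 matrix (traits x ROIs, dimnames as in
#'   [default_marginals()]) of latent trait-ROI correlations in (-1, 1);
#'   default all zero (the null cohort). A named list like
#'   `list("bas:accumbens" = 0.6)` is also accepted.
#' @param trait_marginals,ki_marginals marginal descriptions overriding
#'   entries of [default_marginals()].
#' @param inter_roi_rho length-3 numeric: caudate-putamen,
#'   caudate-accumbens, putamen-accumbens latent correlations.
#' @param missing named vector of per-trait completeness proportions in
#'   (0, 1]; `round(p * n)` rows keep the measure, the rest are set NA.
#'   NULL disables missingness.
#' @param seed RNG seed (integer) or NULL.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 94,
                        rho_true = NULL,
                        trait_marginals = NULL,
                        ki_marginals = NULL,
                        inter_roi_rho = c(0.751, 0.649, 0.787),
                        missing = c(bis11 = 66 / 94, sebr = 92 / 94),
                        seed = NULL) {
  if (n_participants < 4) stop("n_participants must be >= 4")
  traits <- trait_names(); rois <- roi_names()
  rho <- matrix(0, 5, 3, dimnames = list(traits, rois))
  if (!is.null(rho_true)) {
    if (is.matrix(rho_true)) {
      rho[rownames(rho_true), colnames(rho_true)] <- rho_true
    } else if (is.list(rho_true)) {
      for (key in names(rho_true)) {
        pair <- strsplit(key, ":", fixed = TRUE)[[1]]
        rho[pair[1], pair[2]] <- rho_true[[key]]
      }
    } else stop("rho_true must be a traits x ROIs matrix or a named list")
  }
  if (any(abs(rho) >= 1)) stop("every rho_true must lie strictly inside (-1, 1)")
  if (length(inter_roi_rho) != 3 || any(abs(inter_roi_rho) >= 1))
    stop("inter_roi_rho must be three correlations in (-1, 1)")
  marg <- default_marginals()
  for (nm in names(trait_marginals)) marg[[nm]] <- trait_marginals[[nm]]
  for (nm in names(ki_marginals)) marg[[paste0("ki_", sub("^ki_", "", nm))]] <- ki_marginals[[nm]]
  sds <- vapply(marg, function(m)
    if (m$family == "gaussian") m$sd else m$sdlog, numeric(1))
  if (any(sds <= 0)) stop("marginal SDs must be > 0")
  if (!is.null(missing)) {
    if (any(missing <= 0 | missing > 1))
      stop("missing must hold completeness proportions in (0, 1]")
    if (!all(names(missing) %in% traits))
      stop("missing names must be trait names")
  }
  structure(list(n_participants = as.integer(n_participants), rho_true = rho,
                 marginals = marg, inter_roi_rho = inter_roi_rho,
                 missing = missing, seed = seed),
            class = "cohort_spec")
}

# 8 x 8 latent correlation matrix: traits 1..5, ROIs 6..8
latent_correlation <- function(spec) {
  S <- diag(8)
  vars <- c(trait_names(), paste0("ki_", roi_names()))
  dimnames(S) <- list(vars, vars)
  S[1:5, 6:8] <- spec$rho_true
  S[6:8, 1:5] <- t(spec$rho_true)
  S[6, 7] <- S[7, 6] <- spec$inter_roi_rho[1]
  S[6, 8] <- S[8, 6] <- spec$inter_roi_rho[2]
  S[7, 8] <- S[8, 7] <- spec$inter_roi_rho[3]
  S
}

apply_marginal <- function(z, m) {
  u <- stats::pnorm(z)
  x <- switch(m$family,
              gaussian = stats::qnorm(u, m$mean, m$sd),
              lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
              stop("unknown marginal family: ", m$family))
  if (!is.null(m$step) && !is.na(m$step)) x <- round(x / m$step) * m$step
  lo <- if (is.null(m$lower)) -Inf else m$lower
  hi <- if (is.null(m$upper)) Inf else m$upper
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic participant cohort
#'
#' Draws latent multivariate-normal scores with the correlation matrix
#' implied by the spec, transforms each coordinate monotonically to its
#' marginal, and applies per-trait missingness masks. With Gaussian
#' marginals the latent (copula) correlation equals the Pearson correlation
#' of the output; with discretized or clipped marginals rank correlations
#' still converge to the copula values.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` data frame: `participant_id`, the five trait columns,
#'   and `ki_caudate`, `ki_putamen`, `ki_accumbens` (min^-1).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  S <- latent_correlation(spec)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    worst <- which(abs(spec$rho_true) == max(abs(spec$rho_true)), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("implied latent correlation matrix is not positive ",
                        "definite (min eigenvalue %.3g); check rho_true, ",
                        "e.g. pair (%s, %s)"),
                 min(ev), trait_names()[worst[1]], roi_names()[worst[2]]))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_participants
  Z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = S)
  vars <- colnames(S)
  out <- data.frame(participant_id = sprintf("sub-%03d", seq_len(n)))
  for (j in seq_along(vars))
    out[[vars[j]]] <- apply_marginal(Z[, j], spec$marginals[[vars[j]]])
  for (nm in names(spec$missing)) {
    n_obs <- round(spec$missing[[nm]] * n)
    if (n_obs < n) out[[nm]][sample.int(n, n - n_obs)] <- NA
  }
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
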