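test_that("gamma-variate input function has the right shape and area", {
  p <- list(input_A = 50, input_tau = 1)
  t <- seq(0, 60, by = 0.001)
  cp <- simulate_input_function(p, t)
  expect_equal(cp[1], 0)
  expect_true(all(cp >= 0))
  # peak at t = tau
  expect_equal(t[which.max(cp)], 1, tolerance = 1e-2)
  # area A * tau^2 (numeric integral on a fine grid, 0.1%)
  area <- sum(diff(t) * (cp[-1] + cp[-length(cp)]) / 2)
  expect_equal(area, 50 * 1^2, tolerance = 1e-3)
  # zero amplitude gives the zero curve
  expect_true(all(simulate_input_function(list(input_A = 0, input_tau = 1), t) == 0))
  expect_error(simulate_input_function(list(input_A = -1, input_tau = 1), t),
               "positive")
})

test_that("tissue ODE solutions match analytic and stiff-solver oracles", {
  truth <- study_truth()
  t <- seq(0, 89, by = 0.25)
  # reference region is a one-tissue model with a closed-form solution
  ref <- simulate_tissue_tac(truth, t, "reference")
  ana <- one_tissue_analytic(t, truth$K1r, truth$k2r, truth$input_A,
                             truth$input_tau)
  expect_lt(max(abs(ref$activity[-1] - ana[-1]) / pmax(ana[-1], 1e-8)), 1e-3)
  # target C1 obeys the same form; full target checked against radau
  tgt <- simulate_tissue_tac(truth, t, "target")
  cp <- function(tt) truth$input_A * tt * exp(-tt / truth$input_tau)
  radau <- deSolve::ode(c(C1 = 0, C2 = 0), t, function(tt, y, p)
    list(c(p$K1 * cp(tt) - (p$k2 + p$k3) * y[1], p$k3 * y[1])),
    truth, method = "radau", rtol = 1e-10, atol = 1e-12)
  stiff <- radau[, "C1"] + radau[, "C2"]
  expect_lt(max(abs(tgt$activity[-1] - stiff[-1]) / pmax(stiff[-1], 1e-8)),
            1e-3)
  # zero input -> zero tissue everywhere
  t0 <- kinetic_ground_truth(input_A = 0)
  expect_true(all(simulate_tissue_tac(t0, t, "target")$activity == 0))
  expect_true(all(simulate_tissue_tac(t0, t, "reference")$activity == 0))
})

test_that("analytic reference-Patlak asymptote matches a fine-grid fit", {
  for (truth in list(study_truth(),
                     kinetic_ground_truth(K1 = 0.05, k2 = 0.08, k3 = 0.02,
                                          K1r = 0.04, k2r = 0.12))) {
    sched <- frame_schedule(seq(0, 88.5, by = 0.5), seq(0.5, 89, by = 0.5))
    st <- simulate_pet_study(truth, sched, noise_scale = 0, dt = 0.05)
    fit <- patlak_fit(st$target, st$reference, t_star = 60)
    expect_equal(fit$ki_cer, patlak_asymptote(truth), tolerance = 0.02)
  }
})

test_that("k3 = 0 removes trapping and the late Patlak slope collapses", {
  truth <- kinetic_ground_truth(k3 = 1e-10)
  st <- simulate_pet_study(truth)
  fit <- patlak_fit(st$target, st$reference, t_star = 24)
  expect_lt(abs(fit$ki_cer), 0.1 * patlak_asymptote(study_truth()))
})

test_that("frame averaging is exact for constant and linear curves", {
  sched <- build_frame_schedule(list(c(4, 1), c(3, 2), c(3, 3), c(14, 5)))
  expect_equal(nrow(sched), 24)
  const <- frame_average(function(t) rep(3.7, length(t)), sched)
  expect_equal(const$activity, rep(3.7, 24), tolerance = 1e-9)
  lin <- frame_average(function(t) 2 * t, sched)
  expect_equal(lin$activity, 2 * sched$mid, tolerance = 1e-9)
})

test_that("frame averages stay within the curvature bound of mid-time values", {
  # quadratic curve: |frame mean - value at mid| = f'' * dur^2 / 24 exactly
  a <- 0.3
  sched <- default_pet_schedule()
  fr <- frame_average(function(t) a * t^2, sched)
  bound <- 2 * a * (sched$end - sched$start)^2 / 24
  expect_true(all(abs(fr$activity - a * sched$mid^2) <= bound * (1 + 1e-6)))
})

test_that("frame noise is reproducible and scaled by sqrt(activity/duration)", {
  sched <- default_pet_schedule()
  f <- function(t) rep(100, length(t))
  set.seed(99); a1 <- frame_average(f, sched, noise_scale = 1)$activity
  set.seed(99); a2 <- frame_average(f, sched, noise_scale = 1)$activity
  expect_identical(a1, a2)
  # 1-min frames should be noisier than 5-min frames (pooled over draws)
  set.seed(7)
  reps <- replicate(200, frame_average(f, sched, noise_scale = 1)$activity)
  sds <- apply(reps, 1, sd)
  expect_gt(mean(sds[1:4]), 1.5 * mean(sds[11:24]))
})

test_that("null cohorts are uncorrelated and anchored marginals hold", {
  co <- simulate_cohort(gaussian_cohort_spec(10000, 0, seed = 42))
  for (tr in c("digit_span", "listening_span", "bis11", "sebr", "bas"))
    for (roi in c("ki_caudate", "ki_putamen", "ki_accumbens"))
      expect_lt(abs(cor(co[[tr]], co[[roi]])), 0.03)
  # normal ki with SD 0.00222 -> IQR near 1.349 * SD ~ 0.003 (10%)
  expect_equal(unname(IQR(co$ki_caudate)), 0.003, tolerance = 0.1)
  # inter-ROI correlation structure is preserved
  expect_equal(cor(co$ki_caudate, co$ki_putamen), 0.751, tolerance = 0.03)
  expect_equal(cor(co$ki_putamen, co$ki_accumbens), 0.787, tolerance = 0.03)
})

test_that("copula correlation equals Pearson correlation for Gaussian marginals", {
  co <- simulate_cohort(gaussian_cohort_spec(10000, 0.6, seed = 43))
  expect_true(cor(co$bas, co$ki_accumbens) > 0.57 &&
              cor(co$bas, co$ki_accumbens) < 0.63)
  # convergence of the mean sample r across 200 small replicates
  rs <- vapply(1:200, function(s) {
    c2 <- simulate_cohort(gaussian_cohort_spec(250, 0.4, seed = s))
    cor(c2$bas, c2$ki_accumbens)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.4), 2 / sqrt(250))
})

test_that("cohort generation is seed-deterministic and validates its spec", {
  s <- cohort_spec(seed = 5)
  expect_identical(simulate_cohort(s), simulate_cohort(s))
  expect_error(cohort_spec(n_participants = 3), ">= 4")
  expect_error(cohort_spec(rho_true = list("bas:accumbens" = 1)), "inside")
  # strong trait-ROI links conflicting with the inter-ROI structure
  bad <- cohort_spec(rho_true = matrix(c(rep(0, 12), 0.9, -0.9, 0.9), 5, 3,
                                       byrow = TRUE,
                                       dimnames = list(
                                         c("digit_span", "listening_span",
                                           "bis11", "sebr", "bas"),
                                         c("caudate", "putamen", "accumbens"))))
  expect_error(simulate_cohort(bad), "positive definite.*bas",
               ignore.case = TRUE)
})

test_that("per-measure missingness reproduces the study Ns at n = 94", {
  co <- simulate_cohort(cohort_spec(seed = 10))
  expect_equal(nrow(co), 94)
  expect_equal(sum(!is.na(co$bis11)), 66)
  expect_equal(sum(!is.na(co$sebr)), 92)
  expect_equal(sum(!is.na(co$digit_span)), 94)
})

test_that("vEOG simulation embeds the requested blinks", {
  # silent spec: flat zero trace
  flat <- simulate_veog(veog_spec(duration_s = 10, blink_times_s = numeric(),
                                  noise_sd_uV = 0, seed = 1))
  expect_true(all(flat$veog_uV == 0))
  # ground-truth sEBR is count / minutes
  sp <- veog_spec(duration_s = 60,
                  blink_times_s = random_blink_times(17, 60, 1, seed = 2),
                  seed = 2)
  tr <- simulate_veog(sp)
  expect_equal(tr$n_blinks_true, 17)
  expect_equal(sebr_from_blinks(tr$n_blinks_true, tr$duration_s), 17)
  # pulse amplitude is realized
  expect_equal(max(simulate_veog(veog_spec(duration_s = 10,
                                           blink_times_s = 5,
                                           blink_amp_uV = 150,
                                           noise_sd_uV = 0))$veog_uV),
               150, tolerance = 1e-3)
  # determinism
  expect_identical(simulate_veog(sp), simulate_veog(sp))
  # invariant violations
  expect_error(veog_spec(duration_s = 10, blink_times_s = c(1, 1.1),
                         blink_width_ms = 300), "separated")
  expect_error(veog_spec(duration_s = 10, blink_times_s = 11), "within")
})
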