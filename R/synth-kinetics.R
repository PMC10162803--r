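#' Ground-truth kinetic parameters for the PET simulator
#'
#' Parameterizes an irreversible two-tissue-compartment target region
#' (striatum: uptake `K1`, washout `k2`, irreversible trapping `k3`) and a
#' one-tissue reference region (cerebellar grey matter: `K1r`, `k2r`, no
#' trapping), driven by a gamma-variate plasma input
#' `Cp(t) = A * t * exp(-t / tau)`. Blood volume is taken as zero so the
#' late-time reference-Patlak slope has the closed form
#' `K1 * k3 * k2r / ((k2 + k3) * K1r)` (see [patlak_asymptote()]).
#'
#' The defaults put that slope at ~0.015 min^-1, the scale of striatal
#' FDOPA influx rates.
#'
#' @param K1,k2,k3 target-tissue rate constants (min^-1; `K1` in
#'   mL cm^-3 min^-1 convention). All > 0.
#' @param K1r,k2r reference-tissue rate constants (> 0).
#' @param input_A gamma-variate input amplitude (kBq/mL/min).
#' @param input_tau gamma-variate time constant (min).
#' @param noise_scale dimensionless multiplier for frame noise
#'   (see [frame_average()]).
#' @return object of class `kinetic_ground_truth`.
#' @export
kinetic_ground_truth <- function(K1 = 0.03, k2 = 0.057, k3 = 0.01,
                                 K1r = 0.03, k2r = 0.1,
                                 input_A = 80, input_tau = 1.5,
                                 noise_scale = 0) {
  rates <- c(K1 = K1, k2 = k2, k3 = k3, K1r = K1r, k2r = k2r)
  if (any(rates <= 0))
    stop("rate constants must all be > 0 (k3 > 0: irreversible trapping); got ",
         paste(names(rates)[rates <= 0], collapse = ", "), " <= 0")
  if (input_A < 0 || input_tau <= 0) stop("input parameters must be positive")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(K1 = K1, k2 = k2, k3 = k3, K1r = K1r, k2r = k2r,
                 input_A = input_A, input_tau = input_tau,
                 noise_scale = noise_scale),
            class = "kinetic_ground_truth")
}

#' Gamma-variate plasma input function
#'
#' `Cp(t) = A * t * exp(-t / tau)`: zero at t = 0, a single peak at
#' `t = tau`, then decay; total area `A * tau^2`.
#'
#' @param params list with `input_A` (kBq/mL/min) and `input_tau` (min),
#'   e.g. a [kinetic_ground_truth()].
#' @param t_grid increasing time grid in minutes, starting at 0.
#' @return numeric activity (kBq/mL) on `t_grid`.
#' @export
simulate_input_function <- function(params, t_grid) {
  A <- params$input_A; tau <- params$input_tau
  if (is.null(A) || is.null(tau)) stop("params must carry input_A and input_tau")
  if (A < 0 || tau <= 0) stop("input parameters must be positive (amplitude may be zero)")
  if (length(t_grid) < 1 || t_grid[1] < 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be increasing and start at t >= 0")
  A * t_grid * exp(-t_grid / tau)
}

#' Simulate a noise-free tissue time-activity curve
#'
#' Solves the compartment ODEs with `deSolve::ode()` (lsoda, tight
#' tolerances):
#' target `dC1/dt = K1*Cp - (k2 + k3)*C1`, `dC2/dt = k3*C1`,
#' `C_T = C1 + C2`; reference `dCr/dt = K1r*Cp - k2r*Cr`.
#'
#' @param truth a [kinetic_ground_truth()].
#' @param t_grid increasing time grid (min), first element >= 0.
#' @param region `"target"` or `"reference"`.
#' @return data frame with columns `t` (min) and `activity` (kBq/mL).
#' @export
simulate_tissue_tac <- function(truth, t_grid,
                                region = c("target", "reference")) {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  region <- match.arg(region)
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] < 0)
    stop("t_grid must be strictly increasing, starting at t >= 0")
  if (truth$input_A == 0)  # no tracer delivered: all tissue curves are zero
    return(data.frame(t = t_grid, activity = numeric(length(t_grid))))
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  cp <- function(t) truth$input_A * t * exp(-t / truth$input_tau)
  rhs <- if (region == "target") {
    function(t, y, p) list(c(p$K1 * cp(t) - (p$k2 + p$k3) * y[1],
                             p$k3 * y[1]))
  } else {
    function(t, y, p) list(p$K1r * cp(t) - p$k2r * y[1])
  }
  y0 <- if (region == "target") c(C1 = 0, C2 = 0) else c(Cr = 0)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = truth,
                      rtol = 1e-10, atol = 1e-12)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge")
  act <- if (region == "target") sol[, "C1"] + sol[, "C2"] else sol[, "Cr"]
  keep <- match(t_grid, times)
  data.frame(t = t_grid, activity = as.numeric(act[keep]))
}

#' Analytic late-time reference-Patlak slope
#'
#' For the irreversible two-tissue target and one-tissue reference model the
#' Patlak plot against the reference curve becomes linear at late times with
#' slope `K1 * k3 * k2r / ((k2 + k3) * K1r)` (min^-1).
#'
#' @param truth a [kinetic_ground_truth()].
#' @return the asymptotic influx rate (min^-1).
#' @export
patlak_asymptote <- function(truth) {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  truth$K1 * truth$k3 * truth$k2r / ((truth$k2 + truth$k3) * truth$K1r)
}

#' Average a continuous curve into PET frames
#'
#' Each frame value is the time-average of the continuous curve over the
#' frame interval. Optional zero-mean Gaussian noise is added with
#' `sd = noise_scale * sqrt(mean_activity / frame_duration)`, the standard
#' count-statistics approximation in which short, hot frames are noisiest.
#'
#' @param curve a function of time (min), or a data frame with columns
#'   `t` and `activity` (interpolated with a natural spline).
#' @param schedule a [frame_schedule()]; must lie within the simulated span.
#' @param noise_scale dimensionless noise multiplier (0 = noise-free).
#' @param region_label label for the returned [tac()].
#' @return a [tac()].
#' @export
frame_average <- function(curve, schedule, noise_scale = 0,
                          region_label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (is.data.frame(curve)) {
    if (max(schedule$end) > max(curve$t) + 1e-9 || min(schedule$start) < min(curve$t) - 1e-9)
      stop("schedule extends beyond the simulated time span")
    f <- stats::splinefun(curve$t, curve$activity, method = "natural")
  } else if (is.function(curve)) {
    f <- curve
  } else stop("curve must be a function or a data frame with columns t, activity")
  vals <- mapply(function(a, b) {
    stats::integrate(f, a, b, rel.tol = 1e-9,
                     subdivisions = 500L)$value / (b - a)
  }, schedule$start, schedule$end)
  if (noise_scale > 0) {
    sd <- noise_scale * sqrt(pmax(vals, 0) / (schedule$end - schedule$start))
    vals <- vals + stats::rnorm(length(vals), 0, sd)
  }
  tac(schedule, vals, region_label)
}

#' Simulate a full frame-averaged PET study (target + reference TACs)
#'
#' @param truth a [kinetic_ground_truth()].
#' @param schedule a [frame_schedule()]; default the 24-frame protocol.
#' @param noise_scale overrides `truth$noise_scale` if non-NULL.
#' @param dt internal ODE output resolution (min).
#' @return list with [tac()] elements `target` and `reference`.
#' @export
simulate_pet_study <- function(truth, schedule = default_pet_schedule(),
                               noise_scale = NULL, dt = 0.05) {
  ns <- if (is.null(noise_scale)) truth$noise_scale else noise_scale
  t_grid <- seq(0, max(schedule$end), by = dt)
  tgt <- simulate_tissue_tac(truth, t_grid, "target")
  ref <- simulate_tissue_tac(truth, t_grid, "reference")
  list(target = frame_average(tgt, schedule, ns, "target"),
       reference = frame_average(ref, schedule, ns, "reference"))
}
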