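#' Running integral of a frame-wise TAC at frame mid-times
#'
#' Returns per-frame values of the cumulative integral of the activity
#' curve evaluated at the frame mid-times, in kBq min/mL. The default rule
#' treats activity as constant within each frame (matching how frame
#' averages are generated): every completed frame contributes
#' `activity * duration`, and the current frame contributes
#' `activity * (mid - start)`. Activity is assumed zero before the first
#' frame start. A trapezoid rule on the mid-time samples is available as an
#' alternative.
#'
#' @param x a [tac()].
#' @param method `"frame-constant"` (default) or `"trapezoid"`.
#' @return numeric vector, one value per frame.
#' @export
cumulative_integral <- function(x, method = c("frame-constant", "trapezoid")) {
  stopifnot(inherits(x, "tac"))
  method <- match.arg(method)
  s <- x$schedule
  if (method == "frame-constant") {
    full <- x$activity * (s$end - s$start)
    c(0, cumsum(full)[-length(full)]) + x$activity * (s$mid - s$start)
  } else {
    # trapezoid between mid-time samples, triangle from first frame start
    mids <- s$mid
    first <- x$activity[1] * (mids[1] - s$start[1]) / 2
    if (length(mids) == 1) return(first)
    steps <- diff(mids) * (x$activity[-1] + x$activity[-length(mids)]) / 2
    first + c(0, cumsum(steps))
  }
}

#' Patlak transform against a reference-region curve
#'
#' Maps a target/reference TAC pair to Patlak coordinates: per frame,
#' `x = Int_0^t C_ref(tau) dtau / C_ref(t)` (the "normalized time", min) and
#' `y = C_T(t) / C_ref(t)` (dimensionless). For an irreversibly trapped
#' tracer the late-time points fall on a line whose slope is the influx
#' rate. Frames whose reference activity does not exceed `eps` are dropped
#' and reported in the `dropped` attribute.
#'
#' @param target,reference [tac()] objects on the identical schedule.
#' @param eps positive floor for usable reference activity (kBq/mL).
#' @return data frame with columns `mid` (frame mid-time), `x`, `y`;
#'   attribute `dropped` holds indices of discarded frames.
#' @export
patlak_transform <- function(target, reference, eps = 1e-9) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!isTRUE(all.equal(target$schedule$start, reference$schedule$start)) ||
      !isTRUE(all.equal(target$schedule$end, reference$schedule$end)))
    stop("target and reference schedules must be identical")
  usable <- reference$activity > eps
  if (sum(usable) < 3)
    stop("fewer than 3 frames with usable reference activity")
  xi <- cumulative_integral(reference) / reference$activity
  yi <- target$activity / reference$activity
  out <- data.frame(mid = target$schedule$mid, x = xi, y = yi)[usable, ]
  attr(out, "dropped") <- which(!usable)
  out
}

#' Reference-region Patlak fit of the influx rate ki_cer
#'
#' Ordinary least-squares line through the Patlak-transformed points of all
#' frames with mid-time at or after `t_star` (the start of the linear
#' regime; 24 min for the FDOPA protocol). The slope is the influx rate
#' ki_cer (min^-1) relative to the reference region.
#'
#' @param target,reference [tac()] objects on the same schedule.
#' @param t_star minutes; frames with `mid >= t_star` enter the fit.
#' @param eps passed to [patlak_transform()].
#' @return object of class `patlak_fit`: list with `ki_cer`, `intercept`,
#'   `t_star`, `n_frames_used`, `r_squared_fit`.
#' @export
patlak_fit <- function(target, reference, t_star = 24, eps = 1e-9) {
  pts <- patlak_transform(target, reference, eps)
  use <- pts$mid >= t_star
  if (sum(use) < 3) stop("at least 3 frames with mid-time >= t_star required")
  if (t_star > max(target$schedule$end))
    stop("t_star lies beyond the scan span")
  d <- pts[use, ]
  if (stats::var(d$x) < .Machine$double.eps)
    stop("degenerate Patlak abscissa (zero variance)")
  fit <- stats::lm(y ~ x, data = d)
  ss_tot <- sum((d$y - mean(d$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(ki_cer = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 t_star = t_star, n_frames_used = nrow(d),
                 r_squared_fit = r2),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak fit: ki_cer = %.5f min^-1, intercept = %.3f (%d frames, t* = %g min, R2 = %.4f)\n",
              x$ki_cer, x$intercept, x$n_frames_used, x$t_star,
              x$r_squared_fit))
  invisible(x)
}

#' ROI mean of a voxel-wise ki map
#'
#' Arithmetic mean of map voxels under a binary mask; non-finite voxels are
#' excluded with a warning stating how many were dropped.
#'
#' @param ki_map numeric array of voxel-wise influx rates (min^-1).
#' @param mask array of the same shape with values in \{0, 1\}.
#' @return mean influx rate (min^-1).
#' @export
roi_mean_ki <- function(ki_map, mask) {
  if (!identical(dim(ki_map), dim(mask)) &&
      !(is.null(dim(ki_map)) && is.null(dim(mask)) &&
        length(ki_map) == length(mask)))
    stop("ki_map and mask shapes must match")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  vox <- ki_map[mask == 1]
  if (length(vox) == 0) stop("empty mask")
  bad <- !is.finite(vox)
  if (any(bad))
    warning(sprintf("ignoring %d non-finite voxel(s) in ROI mean", sum(bad)))
  mean(vox[!bad])
}

#' Read a NIfTI ki map or ROI mask as a plain array
#'
#' Thin adapters over `RNifti`; masks are binarized by thresholding at 0.5.
#' Voxel-wise correspondence between map and mask is assumed (no
#' resampling is performed).
#'
#' @param path NIfTI-1 file.
#' @return numeric array.
#' @export
read_ki_map <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI files requires the RNifti package")
  as.array(RNifti::readNifti(path))
}

#' @rdname read_ki_map
#' @param threshold binarization threshold for masks.
#' @export
read_roi_mask <- function(path, threshold = 0.5) {
  m <- read_ki_map(path)
  (m > threshold) * 1
}
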