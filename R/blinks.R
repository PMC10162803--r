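#' Band-pass filter and rectify a vertical-EOG trace
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass between
#' 0.5 and 20 Hz, followed by rectification (absolute value). DC offsets
#' and slow drifts fall below the high-pass edge; mains and muscle activity
#' above the low-pass edge are suppressed. The sampling rate must exceed
#' 40 Hz so the 20 Hz edge is below Nyquist.
#'
#' @param trace an `eog_trace` (see [simulate_veog()] / [read_eog_csv()])
#'   or a numeric vector of vEOG samples (then `fs` is required).
#' @param fs sampling rate in Hz (taken from the trace if available).
#' @param band filter edges in Hz.
#' @return numeric vector of filtered, rectified samples, same length as
#'   the input.
#' @export
preprocess_veog <- function(trace, fs = NULL, band = c(0.5, 20)) {
  if (inherits(trace, "eog_trace")) {
    x <- trace$veog_uV
    if (is.null(fs)) fs <- trace$fs
  } else x <- as.numeric(trace)
  if (is.null(fs)) stop("fs must be given when trace is a bare vector")
  if (fs <= 2 * band[2]) stop("fs must exceed twice the upper band edge (40 Hz)")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  abs(signal::filtfilt(bf, x))
}

#' Detect blinks by a sliding-window voltage-rise threshold
#'
#' A blink is an excursion whose voltage rise (sliding-window max minus
#' min) exceeds `threshold_uV` within any `window_ms` span. Threshold
#' crossings are taken with hysteresis (the rise must fall back below
#' `release_frac * threshold_uV` before a new crossing counts) and
#' crossings closer than `window_ms` are merged into one event, replacing
#' the manual curation step of visual EOG scoring.
#'
#' @param filtered numeric vector from [preprocess_veog()].
#' @param fs sampling rate, Hz.
#' @param threshold_uV voltage-rise threshold (microvolt); the default
#'   100 uV suits typical blink amplitudes, and a per-participant override
#'   is supported.
#' @param window_ms span of the sliding rise window (ms).
#' @param release_frac hysteresis release level as a fraction of the
#'   threshold.
#' @return object of class `blink_result`: list with `blink_onsets_s`,
#'   `n_blinks`, `sebr` (blinks/min), `threshold_uV`, `duration_s`.
#' @export
detect_blinks <- function(filtered, fs, threshold_uV = 100, window_ms = 400,
                          release_frac = 0.5) {
  if (threshold_uV <= 0) stop("threshold must be > 0")
  x <- as.numeric(filtered)
  n <- length(x)
  duration_s <- n / fs
  w <- max(2L, round(fs * window_ms / 1000))
  if (n < w) {
    rise <- rep(max(x) - min(x), n)
  } else {
    rmax <- zoo::rollmax(x, w, align = "right", fill = NA)
    rmin <- -zoo::rollmax(-x, w, align = "right", fill = NA)
    rise <- rmax - rmin
    rise[seq_len(w - 1)] <- cummax(x[seq_len(w - 1)]) - cummin(x[seq_len(w - 1)])
  }
  # hysteresis state machine over the rise signal
  onsets <- integer()
  armed <- TRUE
  release <- release_frac * threshold_uV
  above <- rise >= threshold_uV
  below <- rise < release
  for (i in seq_len(n)) {
    if (armed && above[i]) {
      onsets <- c(onsets, i)
      armed <- FALSE
    } else if (!armed && below[i]) {
      armed <- TRUE
    }
  }
  # merge crossings closer than one window
  if (length(onsets) > 1)
    onsets <- onsets[c(TRUE, diff(onsets) >= w)]
  # onset = start of the rise window that triggered
  onset_s <- pmax(onsets - w + 1, 1) / fs
  structure(list(blink_onsets_s = onset_s, n_blinks = length(onsets),
                 sebr = sebr_from_blinks(length(onsets), duration_s),
                 threshold_uV = threshold_uV, duration_s = duration_s),
            class = "blink_result")
}

#' @export
print.blink_result <- function(x, ...) {
  cat(sprintf("%d blinks in %.1f s -> sEBR = %.2f blinks/min (threshold %g uV)\n",
              x$n_blinks, x$duration_s, x$sebr, x$threshold_uV))
  invisible(x)
}

#' Blinks-per-minute normalization
#'
#' @param count number of blinks.
#' @param duration_s recording length (s), > 0.
#' @return blinks per minute.
#' @export
sebr_from_blinks <- function(count, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  count * 60 / duration_s
}

#' Full blink pipeline: filter, rectify, threshold
#'
#' @param trace an `eog_trace`.
#' @inheritParams detect_blinks
#' @return a `blink_result`.
#' @export
sebr_from_trace <- function(trace, threshold_uV = 100, window_ms = 400) {
  filt <- preprocess_veog(trace)
  detect_blinks(filt, trace$fs, threshold_uV, window_ms)
}

#' Flag windows with horizontal-EOG activity (saccade artefacts)
#'
#' Hook for excluding saccade/muscle artefacts: returns a logical vector
#' marking samples where the band-passed hEOG magnitude exceeds a
#' threshold. Full manual review is out of scope.
#'
#' @param heog numeric hEOG samples (microvolt).
#' @param fs sampling rate, Hz.
#' @param threshold_uV artefact threshold.
#' @return logical vector, TRUE where flagged.
#' @export
flag_heog_artifacts <- function(heog, fs, threshold_uV = 100) {
  filt <- preprocess_veog(heog, fs)
  filt > threshold_uV
}
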