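#' Specification of a synthetic vertical-EOG recording
#'
#' Emulates a resting EOG recording at 200 Hz: Gaussian baseline noise with
#' one smooth raised-cosine pulse per blink. Blink onsets must fit in the
#' recording and be separated by more than one pulse width.
#'
#' @param duration_s recording length in seconds (6 or 10 min typical).
#' @param fs sampling rate, Hz.
#' @param blink_times_s numeric vector of blink onsets (s).
#' @param blink_amp_uV pulse amplitude (microvolt).
#' @param blink_width_ms pulse width (ms).
#' @param noise_sd_uV baseline noise SD (microvolt).
#' @param seed RNG seed or NULL.
#' @return object of class `veog_spec`.
#' @export
veog_spec <- function(duration_s = 600, fs = 200, blink_times_s = numeric(),
                      blink_amp_uV = 150, blink_width_ms = 300,
                      noise_sd_uV = 5, seed = NULL) {
  if (fs <= 0) stop("fs must be > 0")
  if (duration_s <= 0) stop("duration must be > 0")
  if (blink_width_ms <= 0) stop("blink width must be > 0")
  if (blink_amp_uV < 0 || noise_sd_uV < 0) stop("amplitudes must be >= 0")
  w_s <- blink_width_ms / 1000
  bt <- sort(blink_times_s)
  if (length(bt) && (min(bt) < 0 || max(bt) + w_s > duration_s))
    stop("blink onsets (plus pulse width) must lie within [0, duration]")
  if (length(bt) > 1 && min(diff(bt)) <= w_s)
    stop("blinks must be separated by more than one pulse width")
  structure(list(duration_s = duration_s, fs = fs, blink_times_s = bt,
                 blink_amp_uV = blink_amp_uV, blink_width_ms = blink_width_ms,
                 noise_sd_uV = noise_sd_uV, seed = seed),
            class = "veog_spec")
}

#' Draw random, non-overlapping blink onset times
#'
#' @param n_blinks number of blinks.
#' @param duration_s recording length (s).
#' @param min_gap_s minimum onset-to-onset separation (s).
#' @param seed RNG seed or NULL.
#' @return sorted onset times (s).
#' @export
random_blink_times <- function(n_blinks, duration_s, min_gap_s = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_blinks == 0) return(numeric())
  span <- duration_s - min_gap_s - n_blinks * min_gap_s
  if (span < 0) stop("too many blinks for the requested duration and gap")
  # uniform spacings plus guaranteed gaps
  u <- sort(stats::runif(n_blinks, 0, span))
  u + min_gap_s * seq_len(n_blinks)
}

#' Simulate a vertical-EOG trace with embedded blinks
#'
#' Baseline Gaussian noise plus one positive raised-cosine pulse of the
#' stated amplitude and width per blink onset. The horizontal channel
#' carries noise only. The ground-truth blink count travels with the trace.
#'
#' @param spec a [veog_spec()].
#' @return object of class `eog_trace`: list with `time_s`, `veog_uV`,
#'   `heog_uV`, `fs`, `duration_s`, `n_blinks_true`, `blink_times_s`.
#' @export
simulate_veog <- function(spec) {
  stopifnot(inherits(spec, "veog_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$fs * spec$duration_s)
  t <- (seq_len(n) - 1) / spec$fs
  v <- stats::rnorm(n, 0, spec$noise_sd_uV)
  h <- stats::rnorm(n, 0, spec$noise_sd_uV)
  w <- spec$blink_width_ms / 1000
  for (t0 in spec$blink_times_s) {
    idx <- which(t >= t0 & t <= t0 + w)
    v[idx] <- v[idx] +
      spec$blink_amp_uV / 2 * (1 - cos(2 * pi * (t[idx] - t0) / w))
  }
  structure(list(time_s = t, veog_uV = v, heog_uV = h, fs = spec$fs,
                 duration_s = spec$duration_s,
                 n_blinks_true = length(spec$blink_times_s),
                 blink_times_s = spec$blink_times_s),
            class = "eog_trace")
}

#' Write / read an EOG trace as CSV (`time_s`, `veog_uV`, `heog_uV`)
#' @param trace an `eog_trace`.
#' @param path file path.
#' @export
write_eog_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              veog_uV = trace$veog_uV,
                              heog_uV = trace$heog_uV),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eog_csv
#' @export
read_eog_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "veog_uV")
  if (!all(need %in% names(d)))
    stop("EOG CSV must have columns ", paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(time_s = d$time_s, veog_uV = d$veog_uV,
                 heog_uV = if ("heog_uV" %in% names(d)) d$heog_uV else NULL,
                 fs = fs, duration_s = length(d$time_s) / fs,
                 n_blinks_true = NA_integer_, blink_times_s = NULL),
            class = "eog_trace")
}
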