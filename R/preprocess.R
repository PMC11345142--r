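#' Continuous EMG recording
#'
#' @param samples numeric vector, mV.
#' @param fs sampling rate, Hz.
#' @param start_time time of the first sample, seconds.
#' @param channel channel label.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs = 10000, start_time = 0,
                          channel = "orbicularis_oculi") {
  stopifnot(is.numeric(samples), fs > 0)
  if (any(!is.finite(samples)))
    stop("non-finite samples at indices: ",
         paste(utils::head(which(!is.finite(samples)), 5), collapse = ", "))
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time, channel = channel),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording '%s': %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Signal-conditioning configuration
#'
#' Parameters of the EMG conditioning chain: zero-phase Butterworth band-pass
#' (mirroring the amplifier's 100--500 Hz analog band), an optional comb of
#' notches at scanner-gradient harmonics, rectification, and a smoothing stage
#' (zero-phase Butterworth low-pass, or a centred moving average).
#'
#' @param fs sampling rate the chain will run at, Hz.
#' @param bp_low,bp_high band-pass edges, Hz.
#' @param bp_order Butterworth order per pass.
#' @param comb_fundamental comb-notch fundamental, Hz; 0 disables the comb.
#' @param comb_harmonics number of harmonics notched.
#' @param comb_q notch quality factor (bandwidth = frequency / Q).
#' @param smooth_cutoff smoothing low-pass cutoff, Hz (used when
#'   `smooth_mode = "lowpass"`).
#' @param smooth_window_ms moving-average window, ms (used when
#'   `smooth_mode = "movavg"`).
#' @param smooth_mode "lowpass" or "movavg".
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(fs = 10000, bp_low = 100, bp_high = 500, bp_order = 4,
                          comb_fundamental = 0, comb_harmonics = 3L,
                          comb_q = 10, smooth_cutoff = 40,
                          smooth_window_ms = 20,
                          smooth_mode = c("lowpass", "movavg")) {
  smooth_mode <- match.arg(smooth_mode)
  if (!(bp_low > 0 && bp_low < bp_high && bp_high < fs / 2))
    stop("invalid band edges: need 0 < bp_low < bp_high < fs/2")
  if (comb_fundamental > 0 && comb_fundamental * comb_harmonics >= fs / 2)
    stop("comb harmonic above Nyquist")
  structure(list(fs = fs, bp_low = bp_low, bp_high = bp_high,
                 bp_order = bp_order, comb_fundamental = comb_fundamental,
                 comb_harmonics = as.integer(comb_harmonics), comb_q = comb_q,
                 smooth_cutoff = smooth_cutoff,
                 smooth_window_ms = smooth_window_ms,
                 smooth_mode = smooth_mode),
            class = "filter_config")
}

# zero-phase (forward-backward) IIR pass; doubles the stopband attenuation
# and cancels phase so scored latencies are unbiased
zero_phase <- function(b, a, x) {
  as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))
}

#' Zero-phase band-pass filter
#'
#' @param x an [emg_recording()].
#' @param cfg a [filter_config()].
#' @return filtered [emg_recording()].
#' @export
bandpass <- function(x, cfg = filter_config(fs = x$fs)) {
  stopifnot(inherits(x, "emg_recording"))
  if (!(cfg$bp_high < x$fs / 2)) stop("bp_high must be below Nyquist")
  bt <- signal::butter(cfg$bp_order, c(cfg$bp_low, cfg$bp_high) / (x$fs / 2),
                       type = "pass")
  x$samples <- zero_phase(bt$b, bt$a, x$samples)
  x
}

# Biquad notch (Orfanidis design): unity gain at DC and Nyquist, null at f0.
notch_coef <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  b0 <- 1 / (1 + tan(pi * bw / fs))
  list(b = b0 * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * b0 * cos(w0), 2 * b0 - 1))
}

#' Comb of notch filters at gradient harmonics
#'
#' Applies a zero-phase biquad notch at each harmonic `k * comb_fundamental`,
#' k = 1..`comb_harmonics`, with bandwidth `f_k / comb_q`. Identity when
#' `comb_fundamental` is 0.
#'
#' @param x an [emg_recording()].
#' @param cfg a [filter_config()].
#' @return filtered [emg_recording()].
#' @export
comb_notch <- function(x, cfg) {
  stopifnot(inherits(x, "emg_recording"))
  if (cfg$comb_fundamental <= 0 || cfg$comb_harmonics < 1) return(x)
  for (k in seq_len(cfg$comb_harmonics)) {
    fk <- k * cfg$comb_fundamental
    if (fk >= x$fs / 2) stop("comb harmonic ", fk, " Hz at/above Nyquist")
    nc <- notch_coef(fk, fk / cfg$comb_q, x$fs)
    x$samples <- zero_phase(nc$b, nc$a, x$samples)
  }
  x
}

#' Full-wave rectification
#'
#' @param x an [emg_recording()] or numeric vector.
#' @return same type, pointwise absolute value.
#' @export
rectify <- function(x) {
  if (inherits(x, "emg_recording")) { x$samples <- abs(x$samples); x }
  else abs(x)
}

#' Smooth a rectified signal into an amplitude envelope
#'
#' Zero-phase Butterworth low-pass (default 40 Hz) or a centred moving
#' average; the result is clamped at 0.
#'
#' @param x an [emg_recording()] holding a rectified signal.
#' @param cfg a [filter_config()].
#' @return a `processed_emg`: list with `envelope` (mV, >= 0), `fs`, and
#'   `provenance` (stages applied, in order).
#' @export
smooth_envelope <- function(x, cfg = filter_config(fs = x$fs)) {
  stopifnot(inherits(x, "emg_recording"))
  if (cfg$smooth_mode == "lowpass") {
    bt <- signal::butter(2, cfg$smooth_cutoff / (x$fs / 2), type = "low")
    env <- zero_phase(bt$b, bt$a, x$samples)
  } else {
    w <- max(1L, round(cfg$smooth_window_ms / 1000 * x$fs))
    if (w %% 2 == 0) w <- w + 1L
    env <- as.numeric(stats::filter(x$samples, rep(1 / w, w), sides = 2))
    half <- (w - 1L) %/% 2L
    # shrink the window at the edges instead of emitting NA
    n <- length(env)
    for (i in which(is.na(env))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      env[i] <- mean(x$samples[lo:hi])
    }
  }
  structure(list(envelope = pmax(0, env), fs = x$fs,
                 provenance = c(attr(x, "provenance"), "smooth")),
            class = "processed_emg")
}

#' @export
print.processed_emg <- function(x, ...) {
  cat(sprintf("Processed EMG envelope: %d samples @ %g Hz; stages: %s\n",
              length(x$envelope), x$fs, paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Run the full conditioning chain
#'
#' band-pass -> comb notch (if configured) -> rectify -> smooth. Every stage
#' is zero-phase and length-preserving; the chain is positively homogeneous
#' (scaling the input scales the envelope).
#'
#' @param x an [emg_recording()].
#' @param cfg a [filter_config()]; its `fs` must match the recording.
#' @return a `processed_emg` (see [smooth_envelope()]) with full provenance.
#' @export
preprocess_emg <- function(x, cfg = filter_config(fs = x$fs)) {
  stopifnot(inherits(x, "emg_recording"))
  if (abs(cfg$fs - x$fs) > 1e-9)
    stop("filter_config fs (", cfg$fs, ") != recording fs (", x$fs, ")")
  stages <- c("bandpass")
  x <- bandpass(x, cfg)
  if (cfg$comb_fundamental > 0 && cfg$comb_harmonics > 0) {
    x <- comb_notch(x, cfg)
    stages <- c(stages, "comb_notch")
  }
  x <- rectify(x)
  stages <- c(stages, "rectify")
  attr(x, "provenance") <- stages
  smooth_envelope(x, cfg)
}
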