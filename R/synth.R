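#' Subject profile for synthetic startle EMG
#'
#' Ground-truth parameters of one simulated participant. Pulse-trial blink
#' amplitude follows the additive log-trial habituation model
#' `A0 + beta_true * log10(ordinal)` (clamped at 0), where the ordinal counts
#' startle-eliciting trials (pulse and PPI) across the whole session. PPI
#' trials are attenuated by the SOA-specific fraction `ppi_true`.
#'
#' Defaults emulate the healthy-adult in-scanner startle literature: initial
#' amplitudes of a few mV on the orbicularis-oculi channel, moderate
#' habituation, 13%/10% inhibition at 60/120 ms SOA and none at 30 ms,
#' blink onset latency near 60 ms.
#'
#' @param A0 initial (trial-1) pulse amplitude, mV.
#' @param beta_true habituation slope, mV per log10(trial); <= 0 habituates.
#' @param ppi_true named numeric: fractional attenuation in \[0,1\] per SOA
#'   (names "30", "60", "120").
#' @param prepulse_response_amp amplitude of the small response to the
#'   prepulse alone, mV.
#' @param response_prob probability that a startle-eliciting trial produces a
#'   scorable blink.
#' @param latency_mean,latency_sd blink onset latency distribution, ms
#'   (truncated to \[35, 95\] so the response stays inside the default scoring
#'   windows).
#' @param spontaneous_blink_rate spontaneous blink rate, events per minute.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(A0 = 5, beta_true = -1.36,
                            ppi_true = c(`30` = 0, `60` = 0.13, `120` = 0.10),
                            prepulse_response_amp = 0.2,
                            response_prob = 1,
                            latency_mean = 60, latency_sd = 10,
                            spontaneous_blink_rate = 5) {
  stopifnot(A0 > 0, all(ppi_true >= 0), all(ppi_true <= 1),
            response_prob >= 0, response_prob <= 1,
            latency_sd >= 0, spontaneous_blink_rate >= 0,
            prepulse_response_amp >= 0)
  structure(list(A0 = A0, beta_true = beta_true, ppi_true = ppi_true,
                 prepulse_response_amp = prepulse_response_amp,
                 response_prob = response_prob,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 spontaneous_blink_rate = spontaneous_blink_rate),
            class = "subject_profile")
}

#' Additive noise model for synthetic in-scanner EMG
#'
#' White measurement noise, scanner-gradient harmonics (pure sinusoids at
#' multiples of a fundamental, standing in for the residual gradient spectrum
#' of a near-silent zero-TE sequence), and slow baseline drift.
#'
#' @param white_noise_sd white noise SD, mV.
#' @param gradient_fundamental gradient harmonic fundamental, Hz (0 disables).
#' @param gradient_harmonics number of harmonics k*f0, k = 1..harmonics.
#' @param gradient_amp amplitude per harmonic, mV.
#' @param baseline_drift_amp amplitude of a 0.2 Hz baseline wander, mV.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(white_noise_sd = 0.05,
                        gradient_fundamental = 150,
                        gradient_harmonics = 3L,
                        gradient_amp = 0.1,
                        baseline_drift_amp = 0.02) {
  stopifnot(white_noise_sd >= 0, gradient_fundamental >= 0,
            gradient_harmonics >= 0, gradient_amp >= 0, baseline_drift_amp >= 0)
  structure(list(white_noise_sd = white_noise_sd,
                 gradient_fundamental = gradient_fundamental,
                 gradient_harmonics = as.integer(gradient_harmonics),
                 gradient_amp = gradient_amp,
                 baseline_drift_amp = baseline_drift_amp),
            class = "noise_model")
}

#' Silent noise model (all components zero)
#' @return a [noise_model()] with every amplitude 0.
#' @export
noise_model_silent <- function() {
  noise_model(white_noise_sd = 0, gradient_fundamental = 0,
              gradient_harmonics = 0L, gradient_amp = 0, baseline_drift_amp = 0)
}

#' Expected blink peak amplitude for one trial
#'
#' Pulse trials follow `max(0, A0 + beta_true*log10(ordinal))`; PPI trials are
#' that expectation attenuated by `1 - ppi_true[soa]`; prepulse-alone trials
#' return the small fixed prepulse response amplitude.
#'
#' @param profile a [subject_profile()].
#' @param trial_type one of "pulse", "prepulse", "ppi_30", "ppi_60", "ppi_120".
#' @param ordinal 1-based ordinal of the trial among startle-eliciting trials
#'   (session-wide); ignored for prepulse-alone trials.
#' @return expected peak amplitude, mV.
#' @export
expected_amplitude <- function(profile, trial_type, ordinal = 1L) {
  if (!trial_type %in% trial_type_levels())
    stop("unknown trial type: ", trial_type)
  if (trial_type == "prepulse") return(profile$prepulse_response_amp)
  stopifnot(ordinal >= 1)
  pulse_amp <- max(0, profile$A0 + profile$beta_true * log10(ordinal))
  if (trial_type == "pulse") return(pulse_amp)
  soa <- as.character(soa_of(trial_type))
  (1 - profile$ppi_true[[soa]]) * pulse_amp
}

default_burst_duration_ms <- 50

#' Synthesise one blink burst
#'
#' A band-limited (100--500 Hz) noise burst under a smooth raised-cosine
#' envelope, zero before `latency_ms` and after `latency_ms + duration_ms`.
#' The burst is calibrated so that the default conditioning chain (band-pass,
#' rectify, smooth) yields an envelope peak equal to `peak_amp`; since every
#' stage of that chain is positively homogeneous the calibration is exact at
#' any amplitude.
#'
#' @param peak_amp target envelope peak, mV.
#' @param latency_ms burst onset after time zero, ms.
#' @param duration_ms burst duration, ms.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed for the burst carrier noise.
#' @param cfg [filter_config()] defining the conditioning chain used for the
#'   calibration.
#' @return numeric vector of length `round((latency_ms+duration_ms)/1000*fs)`.
#' @export
blink_waveform <- function(peak_amp, latency_ms = 60,
                           duration_ms = default_burst_duration_ms,
                           fs = 10000, seed = 1L,
                           cfg = filter_config(fs = fs)) {
  stopifnot(peak_amp >= 0, latency_ms >= 0, duration_ms > 0, fs > 0)
  n_lat <- round(latency_ms / 1000 * fs)
  n_dur <- round(duration_ms / 1000 * fs)
  out <- numeric(n_lat + n_dur)
  if (peak_amp == 0) return(out)
  burst <- with_seed(seed, {
    carrier <- stats::rnorm(n_dur)
    bp <- signal::butter(2, c(cfg$bp_low, cfg$bp_high) / (fs / 2), type = "pass")
    carrier <- as.numeric(signal::filter(bp, carrier))
    env <- 0.5 * (1 - cos(2 * pi * seq_len(n_dur) / (n_dur + 1)))  # raised cosine
    carrier * env
  })
  # exact calibration through the conditioning chain (pad to kill edge effects)
  pad <- round(0.2 * fs)
  probe <- c(numeric(pad), burst, numeric(pad))
  ref <- max(preprocess_emg(emg_recording(probe, fs), cfg)$envelope)
  if (ref <= 0) stop("burst calibration failed: zero envelope")
  out[(n_lat + 1):(n_lat + n_dur)] <- burst * (peak_amp / ref)
  out
}

#' Simulate a full session of orbicularis-oculi EMG for one subject
#'
#' For every startle-eliciting event a blink burst is inserted (with
#' probability `response_prob`) at the eliciting stimulus onset (pulse onset =
#' trial onset + SOA on PPI trials) plus a drawn latency, with the
#' ground-truth expected amplitude. Prepulse-alone trials receive the small
#' prepulse response. Spontaneous blinks arrive as a Poisson process; with
#' probability `artifact_prob` a spontaneous blink is additionally forced into
#' the pre-stimulus window of a trial (uniform in \[-180, -60\] ms before
#' trial onset) to emulate ongoing-blink artifacts. Gradient harmonics, white
#' noise, and baseline drift are then added per the noise model.
#'
#' @param profile a [subject_profile()].
#' @param session a [build_session()] schedule.
#' @param noise a [noise_model()].
#' @param seed master seed.
#' @param fs sampling rate, Hz.
#' @param artifact_prob per-trial probability of a forced pre-stimulus blink.
#' @param cfg [filter_config()] used for burst calibration.
#' @return list with `recordings` (one [emg_recording()] per run) and
#'   `ground_truth` (data.frame: run, index_in_run, trial_type, soa_ms,
#'   ordinal, intended_peak_amp, responded, injected_latency_ms,
#'   artifact_injected).
#' @export
simulate_subject <- function(profile, session, noise = noise_model(),
                             seed = 1L, fs = 10000, artifact_prob = 0,
                             cfg = filter_config(fs = fs)) {
  stopifnot(inherits(session, "session_schedule"))
  sched <- as.data.frame(session)
  elicit <- is_eliciting(sched$trial_type)
  sched$ordinal <- NA_integer_
  sched$ordinal[elicit] <- seq_len(sum(elicit))

  n_ev <- nrow(sched)
  gt <- with_seed(derive_seed(seed, 1L), {
    responded <- ifelse(elicit, stats::runif(n_ev) < profile$response_prob, TRUE)
    lat <- pmin(95, pmax(35, stats::rnorm(n_ev, profile$latency_mean,
                                          profile$latency_sd)))
    art <- stats::runif(n_ev) < artifact_prob
    amp <- vapply(seq_len(n_ev), function(i)
      expected_amplitude(profile, sched$trial_type[i],
                         if (elicit[i]) sched$ordinal[i] else 1L), 0)
    data.frame(run = sched$run, index_in_run = sched$index_in_run,
               trial_type = sched$trial_type, soa_ms = sched$soa_ms,
               onset = sched$onset, ordinal = sched$ordinal,
               intended_peak_amp = amp,
               responded = responded & amp > 0,
               injected_latency_ms = lat,
               artifact_injected = art)
  })

  recordings <- lapply(1:3, function(r) {
    ev <- gt[gt$run == r, ]
    dur <- max(ev$onset) + 2            # 2 s tail after last onset
    n <- ceiling(dur * fs)
    x <- numeric(n)
    add_at <- function(sig, t0) {       # add `sig` starting at time t0 (s)
      i0 <- round(t0 * fs)
      idx <- (i0 + 1):(i0 + length(sig))
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <<- x[idx[keep]] + sig[keep]
    }
    for (i in seq_len(nrow(ev))) {
      stim_on <- ev$onset[i] + ifelse(is.na(ev$soa_ms[i]), 0, ev$soa_ms[i] / 1000)
      if (ev$responded[i] && ev$intended_peak_amp[i] > 0)
        add_at(blink_waveform(ev$intended_peak_amp[i], ev$injected_latency_ms[i],
                              fs = fs, cfg = cfg,
                              seed = derive_seed(seed, 1000L + 200L * r + i)),
               stim_on)
      if (ev$artifact_injected[i]) {
        off <- with_seed(derive_seed(seed, 7000L + 200L * r + i),
                         stats::runif(1, -0.180, -0.060))
        amp <- with_seed(derive_seed(seed, 9000L + 200L * r + i),
                         stats::runif(1, 0.8, 2))
        add_at(blink_waveform(amp, 0, duration_ms = 40, fs = fs, cfg = cfg,
                              seed = derive_seed(seed, 11000L + 200L * r + i)),
               ev$onset[i] + off)
      }
    }
    # spontaneous blinks (Poisson process)
    if (profile$spontaneous_blink_rate > 0) {
      with_seed(derive_seed(seed, 500L + r), {
        n_spont <- stats::rpois(1, profile$spontaneous_blink_rate * dur / 60)
        if (n_spont > 0) {
          t_sp <- stats::runif(n_spont, 0, dur - 0.1)
          a_sp <- stats::runif(n_spont, 0.5, 1.5)
          for (j in seq_len(n_spont))
            add_at(blink_waveform(a_sp[j], 0, duration_ms = 40, fs = fs,
                                  cfg = cfg,
                                  seed = derive_seed(seed, 13000L + 50L * r + j)),
                   t_sp[j])
        }
      })
    }
    # additive noise
    with_seed(derive_seed(seed, 300L + r), {
      tt <- seq_len(n) / fs
      if (noise$white_noise_sd > 0)
        x <- x + stats::rnorm(n, 0, noise$white_noise_sd)
      if (noise$gradient_fundamental > 0 && noise$gradient_harmonics > 0 &&
          noise$gradient_amp > 0) {
        ph <- stats::runif(noise$gradient_harmonics, 0, 2 * pi)
        for (k in seq_len(noise$gradient_harmonics))
          x <- x + noise$gradient_amp *
            sin(2 * pi * k * noise$gradient_fundamental * tt + ph[k])
      }
      if (noise$baseline_drift_amp > 0)
        x <- x + noise$baseline_drift_amp * sin(2 * pi * 0.2 * tt +
                                                  stats::runif(1, 0, 2 * pi))
      x
    }) -> x
    emg_recording(x, fs, channel = "orbicularis_oculi")
  })
  gt$onset <- NULL
  list(recordings = recordings, ground_truth = gt)
}

#' Simulate per-trial scored amplitudes without waveform synthesis
#'
#' Amplitude-level counterpart of [simulate_subject()]: generates the
#' ground-truth expected amplitude for every trial of a session and adds
#' trial-to-trial measurement noise at the envelope level (truncated at 0).
#' Non-response trials score 0. Used for cohort-scale statistical studies
#' where synthesising and re-scoring continuous EMG would add nothing but
#' runtime: the waveform round trip is validated separately.
#'
#' @param profile a [subject_profile()].
#' @param session a [build_session()] schedule.
#' @param seed RNG seed.
#' @param trial_noise_sd SD of additive envelope-level amplitude noise, mV.
#' @return data.frame with columns run, index_in_run, trial_type, soa_ms,
#'   ordinal, intended_peak_amp, responded, rejected, peak_amp.
#' @export
simulate_trial_amplitudes <- function(profile, session, seed = 1L,
                                      trial_noise_sd = 0.3) {
  stopifnot(inherits(session, "session_schedule"), trial_noise_sd >= 0)
  sched <- as.data.frame(session)
  elicit <- is_eliciting(sched$trial_type)
  sched$ordinal <- NA_integer_
  sched$ordinal[elicit] <- seq_len(sum(elicit))
  n <- nrow(sched)
  with_seed(seed, {
    amp <- vapply(seq_len(n), function(i)
      expected_amplitude(profile, sched$trial_type[i],
                         if (elicit[i]) sched$ordinal[i] else 1L), 0)
    responded <- (ifelse(elicit, stats::runif(n) < profile$response_prob, TRUE)) &
      amp > 0
    peak <- pmax(0, amp + stats::rnorm(n, 0, trial_noise_sd))
    peak[!responded] <- 0
    data.frame(run = sched$run, index_in_run = sched$index_in_run,
               trial_type = sched$trial_type, soa_ms = sched$soa_ms,
               ordinal = sched$ordinal, intended_peak_amp = amp,
               responded = responded, rejected = FALSE, peak_amp = peak)
  })
}

#' Draw a cohort of random subject profiles
#'
#' Initial amplitude A0 ~ Uniform(2, 8) mV and habituation slope
#' beta_true ~ Uniform(-3, 0) mV/log10(trial), spanning the between-subject
#' variability of in-scanner startle amplitudes; PPI fractions are drawn
#' around `ppi_mean` with between-subject SD `ppi_sd` (truncated to keep the
#' attenuation fraction in [0, 1]).
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param A0_range,beta_range uniform ranges for A0 and beta_true.
#' @param ppi_mean named numeric, mean fractional attenuation per SOA.
#' @param ppi_sd between-subject SD of the attenuation fraction.
#' @param response_prob passed to [subject_profile()].
#' @return list of [subject_profile()] objects.
#' @export
sample_profiles <- function(n, seed = 1L, A0_range = c(2, 8),
                            beta_range = c(-3, 0),
                            ppi_mean = c(`30` = 0, `60` = 0.13, `120` = 0.10),
                            ppi_sd = 0.05, response_prob = 1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ppi <- pmin(1, pmax(0, stats::rnorm(3, ppi_mean, ppi_sd)))
      names(ppi) <- names(ppi_mean)
      subject_profile(A0 = stats::runif(1, A0_range[1], A0_range[2]),
                      beta_true = stats::runif(1, beta_range[1], beta_range[2]),
                      ppi_true = ppi, response_prob = response_prob)
    })
  })
}
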