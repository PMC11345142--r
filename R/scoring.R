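#' Blink-scoring configuration
#'
#' Window and criterion parameters for scoring startle eyeblinks from the
#' processed envelope. Peak and onset windows are anchored at the
#' startle-eliciting (pulse) onset — on PPI trials that is trial onset + SOA —
#' while the baseline and pre-stimulus artifact windows are anchored at trial
#' onset, i.e. before any stimulus. Defaults follow standard human-startle
#' scoring conventions; every value is configurable.
#'
#' @param baseline_window ms relative to trial onset, default c(-50, 0).
#' @param peak_window ms relative to pulse onset, default c(20, 150).
#' @param onset_window ms relative to pulse onset within which the criterion
#'   crossing must fall for a response, default c(21, 120).
#' @param criterion_k response criterion: peak must exceed baseline mean +
#'   `criterion_k` times the baseline SD.
#' @param criterion_floor absolute response floor added to the criterion, mV
#'   (guards the zero-noise case where the baseline SD is 0).
#' @param onset_frac onset-latency criterion as a fraction of the
#'   peak-above-baseline; the onset threshold is the larger of the response
#'   criterion and `baseline + onset_frac * (peak - baseline)`, which keeps
#'   latency detection robust to low pre-burst pedestals (e.g. residual
#'   ringing of narrow notch filters). 0 reduces to the response criterion.
#' @param prestim_window ms relative to trial onset scanned for ongoing
#'   blinks, default c(-200, 0).
#' @param prestim_k pre-stimulus artifact criterion in robust-noise SD units.
#' @param prestim_min_ms minimum sustained exceedance for rejection, ms.
#' @param response_prob_cutoff participant inclusion cutoff on pulse-trial
#'   response probability.
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(baseline_window = c(-50, 0),
                           peak_window = c(20, 150),
                           onset_window = c(21, 120),
                           criterion_k = 3,
                           criterion_floor = 0.05,
                           onset_frac = 0.2,
                           prestim_window = c(-200, 0),
                           prestim_k = 4,
                           prestim_min_ms = 10,
                           response_prob_cutoff = 0.70) {
  stopifnot(baseline_window[1] < baseline_window[2],
            peak_window[1] < peak_window[2],
            onset_window[1] < onset_window[2],
            prestim_window[1] < prestim_window[2],
            criterion_k >= 0, criterion_floor >= 0,
            onset_frac >= 0, onset_frac < 1,
            response_prob_cutoff > 0, response_prob_cutoff <= 1)
  structure(list(baseline_window = baseline_window, peak_window = peak_window,
                 onset_window = onset_window, criterion_k = criterion_k,
                 criterion_floor = criterion_floor, onset_frac = onset_frac,
                 prestim_window = prestim_window, prestim_k = prestim_k,
                 prestim_min_ms = prestim_min_ms,
                 response_prob_cutoff = response_prob_cutoff),
            class = "scoring_config")
}

# envelope slice for a window (ms) around an anchor time (s); errors if the
# window leaves the recording
env_window <- function(env, anchor_s, window_ms, what, trial = NULL) {
  i0 <- floor((anchor_s + window_ms[1] / 1000) * env$fs) + 1L
  i1 <- ceiling((anchor_s + window_ms[2] / 1000) * env$fs)
  if (i0 < 1L || i1 > length(env$envelope))
    stop(what, " window out of recording bounds",
         if (!is.null(trial)) paste0(" for trial ", trial) else "")
  env$envelope[i0:i1]
}

#' Score one trial's startle eyeblink
#'
#' Baseline mean and SD come from the pre-trial baseline window; the peak is
#' the maximum envelope in the peak window minus the baseline mean, clamped at
#' 0. The trial counts as a response when the peak exceeds
#' `baseline + max(criterion_k * baseline SD, criterion_floor)` and the first
#' criterion crossing falls inside the onset window.
#'
#' @param env a `processed_emg` from [preprocess_emg()].
#' @param ev one trial event: a list/row with `onset` (s), `trial_type`,
#'   `soa_ms`, and optionally `run`, `index_in_run`.
#' @param cfg a [scoring_config()].
#' @return one-row data.frame: run, index_in_run, trial_type, soa_ms,
#'   baseline_mean (mV), peak_amp (mV), onset_latency_ms (NA if no response),
#'   responded, rejected, reject_reason.
#' @export
score_trial <- function(env, ev, cfg = scoring_config()) {
  stopifnot(inherits(env, "processed_emg"))
  trial_id <- paste0(ev$run %||% NA, ":", ev$index_in_run %||% NA)
  stim_on <- ev$onset + (if (is.null(ev$soa_ms) || is.na(ev$soa_ms)) 0
                         else ev$soa_ms / 1000)
  base <- env_window(env, ev$onset, cfg$baseline_window, "baseline", trial_id)
  pk <- env_window(env, stim_on, cfg$peak_window, "peak", trial_id)
  baseline_mean <- mean(base)
  crit <- baseline_mean + max(cfg$criterion_k * stats::sd(base), cfg$criterion_floor)
  peak_amp <- max(0, max(pk) - baseline_mean)
  # response onset: start of the contiguous supra-criterion run containing the
  # peak (robust to isolated noise crossings before the window opens)
  search <- env_window(env, stim_on, c(0, cfg$peak_window[2]), "onset", trial_id)
  n_pre <- round(cfg$peak_window[1] / 1000 * env$fs)
  ipk <- min(length(search), n_pre + which.max(pk))
  onset_thr <- max(crit, baseline_mean + cfg$onset_frac * (max(pk) - baseline_mean))
  onset_ms <- NA_real_
  if (search[ipk] > crit) {
    below <- which(search[seq_len(ipk)] <= onset_thr)
    i_on <- if (length(below)) max(below) + 1L else 1L
    onset_ms <- (i_on - 1L) / env$fs * 1000
  }
  responded <- isTRUE(max(pk) > crit && !is.na(onset_ms) &&
                        onset_ms >= cfg$onset_window[1] &&
                        onset_ms <= cfg$onset_window[2])
  rejected <- reject_prestimulus_blink(env, ev, cfg)
  data.frame(run = ev$run %||% NA_integer_,
             index_in_run = ev$index_in_run %||% NA_integer_,
             trial_type = ev$trial_type,
             soa_ms = ev$soa_ms %||% NA_real_,
             baseline_mean = baseline_mean, peak_amp = peak_amp,
             onset_latency_ms = if (responded) onset_ms else NA_real_,
             responded = responded, rejected = rejected,
             reject_reason = if (rejected) "prestim_blink" else "none")
}

#' Detect ongoing blinks before stimulus onset
#'
#' A trial is rejected when the envelope inside the pre-stimulus window
#' exceeds a robust threshold (session envelope median + `prestim_k` times
#' the MAD-based noise SD, plus the absolute floor) for at least
#' `prestim_min_ms` consecutive milliseconds.
#'
#' @inheritParams score_trial
#' @return logical.
#' @export
reject_prestimulus_blink <- function(env, ev, cfg = scoring_config()) {
  stopifnot(inherits(env, "processed_emg"))
  w <- env_window(env, ev$onset, cfg$prestim_window, "prestim",
                  paste0(ev$run %||% NA, ":", ev$index_in_run %||% NA))
  med <- env$noise_med %||% stats::median(env$envelope)
  noise_sd <- env$noise_sd %||% stats::mad(env$envelope)  # robust to sparse bursts
  thr <- med + cfg$prestim_k * noise_sd + cfg$criterion_floor
  over <- w > thr
  if (!any(over)) return(FALSE)
  need <- max(1L, round(cfg$prestim_min_ms / 1000 * env$fs))
  r <- rle(over)
  any(r$values & r$lengths >= need)
}

#' Score every trial of a session
#'
#' @param envs list of `processed_emg`, one per run (or a single one).
#' @param session a [build_session()] schedule (or a data.frame of events with
#'   `run`, `index_in_run`, `trial_type`, `soa_ms`, `onset`).
#' @param cfg a [scoring_config()].
#' @return data.frame of per-trial scores (one [score_trial()] row per event).
#' @export
score_session <- function(envs, session, cfg = scoring_config()) {
  events <- if (inherits(session, "session_schedule")) as.data.frame(session)
            else session
  if (inherits(envs, "processed_emg")) envs <- list(envs)
  # cache the robust envelope noise statistics once per run
  envs <- lapply(envs, function(e) {
    e$noise_med <- stats::median(e$envelope)
    e$noise_sd <- stats::mad(e$envelope)
    e
  })
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- as.list(events[i, ])
    score_trial(envs[[ev$run]], ev, cfg)
  })
  do.call(rbind, rows)
}

#' Participant-level summary and inclusion decision
#'
#' Response probability is the fraction of non-rejected pulse trials on which
#' a response was scored; participants below the cutoff (default 70%) are
#' flagged excluded as non-responders.
#'
#' @param scores data.frame of trial scores (see [score_session()]).
#' @param cfg a [scoring_config()].
#' @param subject subject identifier carried into the result.
#' @return an object of class `participant_scores`: list with `subject`,
#'   `trials`, `response_probability_pulse`, `included`.
#' @export
participant_summary <- function(scores, cfg = scoring_config(), subject = NA) {
  usable <- scores$trial_type == "pulse" & !scores$rejected
  if (!any(usable)) stop("no usable (non-rejected) pulse trials")
  p <- mean(scores$responded[usable])
  structure(list(subject = subject, trials = scores,
                 response_probability_pulse = p,
                 included = p >= cfg$response_prob_cutoff),
            class = "participant_scores")
}

#' @export
print.participant_scores <- function(x, ...) {
  cat(sprintf("Participant %s: %d trials, pulse response probability %.3f (%s)\n",
              as.character(x$subject), nrow(x$trials),
              x$response_probability_pulse,
              if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Per-run, per-condition mean amplitudes
#'
#' `amplitude` mode (default) averages responded trials only; `magnitude` mode
#' includes non-response trials as zeros. Rejected trials are always excluded.
#' Empty cells yield NA with a warning.
#'
#' @param p a [participant_summary()] result, or a data.frame of trial scores.
#' @param mode "amplitude" or "magnitude".
#' @return data.frame with columns run, trial_type, soa_ms, n, mean_amp (mV).
#' @export
condition_means <- function(p, mode = c("amplitude", "magnitude")) {
  mode <- match.arg(mode)
  scores <- if (inherits(p, "participant_scores")) p$trials else p
  keep <- !scores$rejected
  if (mode == "amplitude") keep <- keep & scores$responded
  s <- scores
  s$peak_amp[!scores$responded] <- 0   # magnitude mode counts zeros
  cells <- unique(scores[, c("run", "trial_type", "soa_ms")])
  cells <- cells[order(cells$run, match(cells$trial_type, trial_type_levels())), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- keep & scores$run == cells$run[i] &
      scores$trial_type == cells$trial_type[i]
    m <- if (any(sel)) mean(s$peak_amp[sel]) else NA_real_
    data.frame(run = cells$run[i], trial_type = cells$trial_type[i],
               soa_ms = cells$soa_ms[i], n = sum(sel), mean_amp = m)
  }))
  if (anyNA(out$mean_amp))
    warning("empty condition cell(s): ",
            paste(out$trial_type[is.na(out$mean_amp)], "run",
                  out$run[is.na(out$mean_amp)], collapse = "; "))
  rownames(out) <- NULL
  out
}
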