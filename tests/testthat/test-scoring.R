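test_that("a flat envelope scores zero and no response", {
  env <- structure(list(envelope = numeric(3 * test_fs), fs = test_fs,
                        provenance = "smooth"), class = "processed_emg")
  s <- score_trial(env, pulse_event(onset = 1.0))
  expect_equal(s$peak_amp, 0)
  expect_false(s$responded)
  expect_false(s$rejected)
  expect_true(is.na(s$onset_latency_ms))
})

test_that("an injected burst is scored at its calibrated peak and latency", {
  env <- burst_env(peak_amp = 3, latency_ms = 60, seed = 2)
  s <- score_trial(env, pulse_event(onset = 1.0))
  expect_equal(s$peak_amp, 3, tolerance = 0.01)
  expect_true(s$responded)
  expect_equal(s$onset_latency_ms, 60, tolerance = 15)

  # PPI trial: windows anchor at pulse onset = trial onset + SOA
  env2 <- burst_env(peak_amp = 2, latency_ms = 60, seed = 3)
  ev <- list(run = 1L, index_in_run = 2L, trial_type = "ppi_60", soa_ms = 60,
             onset = 1.0 - 0.060)
  s2 <- score_trial(env2, ev)
  expect_equal(s2$peak_amp, 2, tolerance = 0.01)
  expect_true(s2$responded)
})

test_that("a burst outside the onset window is not a response", {
  env <- burst_env(peak_amp = 3, latency_ms = 300, fs = test_fs, seed = 2)
  s <- score_trial(env, pulse_event(onset = 1.0))
  expect_false(s$responded)   # peak window ends at 150 ms

  # window leaving the recording names the trial
  expect_error(score_trial(env, pulse_event(onset = 0.01)), "1:1")
})

test_that("pre-stimulus blinks are rejected, distant ones are not", {
  fs <- test_fs
  cfg <- filter_config(fs = fs)
  blink <- blink_waveform(1.5, 0, duration_ms = 40, fs = fs, seed = 6, cfg = cfg)
  startle <- blink_waveform(3, 60, fs = fs, seed = 7, cfg = cfg)

  # blink at -100 ms relative to a trial at 1.0 s
  x <- numeric(3 * fs)
  i0 <- round(0.9 * fs)
  x[i0 + seq_along(blink)] <- blink
  x[fs + seq_along(startle)] <- x[fs + seq_along(startle)] + startle
  env <- preprocess_emg(emg_recording(x, fs), cfg)
  expect_true(reject_prestimulus_blink(env, pulse_event(1.0)))
  s <- score_trial(env, pulse_event(1.0))
  expect_true(s$rejected)
  expect_identical(s$reject_reason, "prestim_blink")

  # same blink ending 500 ms before onset: outside the [-200, 0] window
  x2 <- numeric(3 * fs)
  x2[round(0.45 * fs) + seq_along(blink)] <- blink
  x2[fs + seq_along(startle)] <- x2[fs + seq_along(startle)] + startle
  env2 <- preprocess_emg(emg_recording(x2, fs), cfg)
  expect_false(reject_prestimulus_blink(env2, pulse_event(1.0)))

  # clean trial
  env3 <- burst_env(3, 60, seed = 8)
  expect_false(reject_prestimulus_blink(env3, pulse_event(1.0)))
})

test_that("participant inclusion follows the 70% response-probability rule", {
  mk <- function(n_resp, n_total) {
    data.frame(run = 1L, index_in_run = seq_len(n_total), trial_type = "pulse",
               soa_ms = NA_real_, baseline_mean = 0,
               peak_amp = ifelse(seq_len(n_total) <= n_resp, 3, 0),
               onset_latency_ms = NA_real_,
               responded = seq_len(n_total) <= n_resp,
               rejected = FALSE, reject_reason = "none")
  }
  p1 <- participant_summary(mk(28, 28), subject = "a")
  expect_equal(p1$response_probability_pulse, 1)
  expect_true(p1$included)

  p2 <- participant_summary(mk(19, 28), subject = "b")
  expect_equal(p2$response_probability_pulse, 19 / 28, tolerance = 1e-12)
  expect_false(p2$included)                      # 0.679 < 0.70

  p3 <- participant_summary(mk(20, 28), subject = "c")
  expect_equal(p3$response_probability_pulse, 20 / 28, tolerance = 1e-12)
  expect_true(p3$included)                       # 0.714 >= 0.70

  # rejected trials leave the denominator
  sc <- mk(19, 28)
  sc$rejected[28] <- TRUE                        # a non-responding trial
  expect_equal(participant_summary(sc)$response_probability_pulse, 19 / 27)

  sc_all <- mk(5, 5); sc_all$rejected <- TRUE
  expect_error(participant_summary(sc_all), "usable")
})

test_that("condition means honour amplitude vs magnitude modes", {
  sc <- data.frame(run = 1L, index_in_run = 1:3, trial_type = "pulse",
                   soa_ms = NA_real_, baseline_mean = 0,
                   peak_amp = c(2, 4, 0.4), onset_latency_ms = NA_real_,
                   responded = c(TRUE, TRUE, FALSE), rejected = FALSE,
                   reject_reason = "none")
  expect_equal(condition_means(sc, "amplitude")$mean_amp, 3)
  expect_equal(condition_means(sc, "magnitude")$mean_amp, 2)

  sc$rejected <- TRUE
  expect_warning(cm <- condition_means(sc, "amplitude"), "empty")
  expect_true(is.na(cm$mean_amp))
})

test_that("raising the response criterion never increases response probability", {
  set.seed(99)
  envs <- lapply(1:12, function(i)
    burst_env(peak_amp = stats::runif(1, 0.1, 2), latency_ms = 60,
              noise_sd = 0.05, seed = i))
  probs <- vapply(c(1, 3, 6, 12, 24), function(k) {
    resp <- vapply(envs, function(e)
      score_trial(e, pulse_event(1.0), scoring_config(criterion_k = k))$responded,
      TRUE)
    mean(resp)
  }, 0)
  expect_true(all(diff(probs) <= 0))
})
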