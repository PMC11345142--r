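# Shared fixtures, built in code. Waveform tests run at 2 kHz with short ISIs:
# the blink band (100-500 Hz) sits fully below Nyquist, so scoring fidelity is
# unchanged while the suite stays fast.

test_fs <- 2000

quick_schedule <- function(seed = 2) {
  build_session(seed = seed,
                config = schedule_config(isi_min = 3, isi_max = 5, lead_in = 2))
}

# one isolated blink in an otherwise silent (or white-noise) recording,
# stimulus onset at 1.0 s
burst_env <- function(peak_amp = 3, latency_ms = 60, fs = test_fs,
                      noise_sd = 0, seed = 1, cfg = filter_config(fs = fs)) {
  b <- blink_waveform(peak_amp, latency_ms, fs = fs, seed = seed, cfg = cfg)
  x <- c(numeric(fs), b, numeric(fs))
  if (noise_sd > 0) {
    set.seed(seed + 1)
    x <- x + stats::rnorm(length(x), 0, noise_sd)
  }
  preprocess_emg(emg_recording(x, fs), cfg)
}

pulse_event <- function(onset = 1.0) {
  list(run = 1L, index_in_run = 1L, trial_type = "pulse", soa_ms = NA_real_,
       onset = onset)
}

# independent brute-force oracles used by the statistics tests ---------------

# Friedman chi-square from first principles (mid-ranks, textbook formula)
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) R[i, ] <- rank(m[i, ])
  12 * n / (k * (k + 1)) * sum((colMeans(R) - (k + 1) / 2)^2)
}

# Spearman rho via the d^2 formula (valid for tie-free data)
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# ICC(3,1) from an explicit two-way ANOVA fit
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m), s = factor(rep(seq_len(n), k)),
                  r = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ s + r, d))[[1]]
  rn <- trimws(rownames(av))
  bms <- av[rn == "s", "Mean Sq"]
  ems <- av[rn == "Residuals", "Mean Sq"]
  (bms - ems) / (bms + (k - 1) * ems)
}

# Greenhouse-Geisser epsilon via the classical double-centered-covariance form
gg_oracle <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  sc <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  max(1 / (k - 1), min(1, sum(diag(sc))^2 / ((k - 1) * sum(sc^2))))
}
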