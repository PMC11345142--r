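---
title: "Startle EMG analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Startle EMG analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlekit)
```

## The measurement problem

The acoustic startle eyeblink is an involuntary orbicularis-oculi contraction
to a sudden loud stimulus. Two forms of startle plasticity are quantified
here: short-term habituation (the within-session decline of blink amplitude
over repeated pulse presentations) and prepulse inhibition (PPI; the
reduction of the blink when a weak prepulse precedes the pulse by a short
stimulus onset asynchrony, SOA). `startlekit` implements the full analysis
path for a three-run in-scanner paradigm — schedule construction, synthetic
EMG with known ground truth, signal conditioning, per-trial scoring with
exclusion rules, the habituation slope with intercept correction, PPI
percentages, and the group statistics battery — so every stage can be
validated against ground truth before it ever touches real data.

## The paradigm

A session has three runs presented in fixed order. Each run contains 8
pulse-alone trials (40 ms, 115 dB white noise), 8 prepulse-alone trials
(20 ms, 85 dB), and 8 PPI trials at each SOA of 30, 60 and 120 ms (24 PPI
trials per run). Run 1 prepends 4 extra acclimatisation pulses, so the runs
have 44/40/40 trials (124 total). Trials are pseudo-randomly ordered so that
no trial type repeats back-to-back; the acclimatisation block is exempt, but
the first randomised trial may not extend the pulse streak. Onset-to-onset
inter-stimulus intervals are drawn i.i.d. uniform on [9, 21] s — the
simplest distribution consistent with the stated range and 15 s mean — and
runs are separated by a 3-minute gap.

Ordering uses count-weighted random sequential construction with
restart-on-dead-end under a bounded retry budget. Plain rejection sampling
over permutations was evaluated first and discarded: with five types of
eight trials the probability that a uniform random permutation has no
adjacent repeat is on the order of 2 x 10^-4, so even a 10,000-draw budget
fails stochastically. Sequential construction is biased toward valid
orderings by design, remains deterministic given the seed, and still detects
genuinely unsatisfiable compositions (for example a run consisting only of
pulses) by exhausting the budget.

## The synthetic-data generator

The generator is the package's ground-truth oracle. Each subject is a
`subject_profile()`:

* pulse-trial amplitude follows `max(0, A0 + beta_true * log10(ordinal))`
  with A0 in mV and `beta_true` in mV per log10(trial); the ordinal counts
  startle-eliciting trials (pulse and PPI) across the whole session, so the
  very first trial of Run 1 — an acclimatisation pulse — is ordinal 1;
* PPI trials are attenuated multiplicatively by `1 - ppi_true[soa]`,
  defaults 0 / 0.13 / 0.10 at 30 / 60 / 120 ms, the inhibition scale
  reported for healthy adults inside a near-silent scanner;
* each eliciting trial responds with probability `response_prob`; blink
  onset latency is Normal(60, 10) ms truncated to [35, 95] ms so responses
  stay inside the default scoring windows;
* spontaneous blinks arrive as a Poisson process (default 5/min), and an
  `artifact_prob` argument forces additional blinks into the pre-stimulus
  window to exercise the rejection rule;
* non-responses are true zeros (no burst), not sub-threshold bursts.

A blink is a 100–500 Hz noise burst under a raised-cosine envelope,
calibrated so that the default conditioning chain returns exactly the
intended envelope peak — the chain is positively homogeneous (linear filters
plus rectification), so scaling one calibration probe is exact at any
amplitude. Scanner noise is modelled as stationary sinusoidal harmonics at
multiples of a configurable fundamental (default 150 Hz, three harmonics,
deliberately inside the EMG band so the comb filter is genuinely exercised),
plus white noise and slow baseline drift. Real gradient spectra are richer
and non-stationary; the comb-notch stage is documented as a configurable
stand-in, not a replication of any specific sequence.

Amplitude-level simulation (`simulate_trial_amplitudes()`) generates the
same generative model directly at the scored-amplitude level with additive
trial-to-trial noise (default SD 0.3 mV). Cohort-scale statistical studies
use it because the waveform round trip — synthesis, filtering, scoring — is
validated separately and adds only runtime at that scale.

## Signal conditioning

The chain is band-pass (Butterworth order 4, 100–500 Hz, mirroring the
amplifier's analog band) -> optional comb notch -> full-wave rectification ->
smoothing (Butterworth order 2 low-pass at 40 Hz, or a centred moving
average). All IIR stages run forward-backward (zero-phase) so scored
latencies are not biased by filter delay. Each comb notch is an Orfanidis
biquad with unity gain at DC and Nyquist and bandwidth `f/Q`. The default
Q of 10 balances two failure modes measured during development: very narrow
notches (Q near 35) ring for ~75 ms either side of a burst under zero-phase
filtering and corrupt pre-stimulus baselines, while very wide ones (Q near
5) attenuate between-harmonic content by almost 20%. At Q = 10 the harmonics
are suppressed by more than 30 dB, content halfway between harmonics is
preserved within 5%, and the residual ~20 ms ringing pedestal is handled by
the onset rule below.

## Scoring

Baseline is the mean envelope in [-50, 0] ms relative to trial onset
(before any stimulus). Peak amplitude is the envelope maximum in [20, 150]
ms after the startle-eliciting onset — on PPI trials that is trial onset +
SOA — minus baseline, clamped at 0. The response criterion is baseline +
max(3 x baseline SD, 0.05 mV); the absolute floor guards the noise-free case
where the baseline SD is exactly zero. A trial counts as a response when the
peak exceeds the criterion and the onset falls inside [21, 120] ms.

Onset latency is the crossing of max(criterion, baseline + 20% of
peak-above-baseline), found by walking backwards from the peak to the last
sub-threshold sample. The fraction-of-peak component exists because a
literal first-crossing-of-criterion rule dates onsets inside the low
ringing pedestal that the comb notch leaves before each burst, pushing
detected onsets before the 21 ms window and misclassifying true responses;
fraction-of-peak latency criteria are standard in human startle scoring, and
setting `onset_frac = 0` restores the literal rule.

Trials with ongoing blinks before stimulus onset are rejected: the envelope
in [-200, 0] ms must stay below the session median + 4 robust (MAD-based)
noise SDs + the absolute floor; exceedances must be sustained 10 ms to
count, so single-sample noise spikes do not reject trials. Participants are
excluded as non-responders when fewer than 70% of their usable (non-rejected)
pulse trials carry a response. Per-run condition means use responded trials
only by default ("amplitude"); the "magnitude" option includes non-response
trials as zeros.

## Habituation slope and intercept correction

For each participant the pulse-trial amplitudes Y are regressed on
X = log10(trial ordinal) with the intercept pinned to the trial-1 amplitude
`a`; the least-squares slope is then `b = sum(X*(Y - a)) / sum(X^2)`, and
the trial-1 point (X = 0) contributes nothing to it. The ordinal passed by
the pipeline is the same session-wide startle-eliciting ordinal the
generator uses. Keeping the generative and fitted predictors identical makes
slope recovery a well-posed estimand — fitting log10 of the pulse rank
(1..28) to data generated on the eliciting ordinal (1..100) produces a
systematic slope bias of roughly 20% because the acclimatisation block
compresses early pulse ranks — and with trial 1 of Run 1 being a pulse, the
intercept convention is self-consistent. Alternative orderings can be passed
through the `ordinals` argument. If a subject's trial-1 pulse is rejected or
unanswered, the intercept is undefined and the subject drops out of the
habituation cohort (the pipeline notes this in the manifest) rather than
silently substituting a later trial.

Across a cohort, raw slopes correlate with initial amplitude (strong
responders have more room to habituate), so a corrected slope
`b' = b - c * (a - abar)` is computed. The default `c` is the unstandardised
OLS coefficient of `b` on `a` across subjects, because that is the choice
under which `b'` is statistically independent of `a`; the standardised-beta
variant is available via `mode = "standardised"`. The default centring
`abar` is each subject's own mean pulse amplitude excluding trial 1;
`center = "group"` uses the group mean of `a`, the variant under which the
cohort-level regression of `b'` on `a` is exactly zero (verified to 1e-10 in
the tests). Group-level habituation is then a one-sample t of the corrected
slopes against zero with Cohen's d = |mean|/SD, and raw per-run pulse means
are compared with a Friedman rank test (mid-ranks, chi-square =
12n/(k(k+1)) * sum((Rbar_j - (k+1)/2)^2), no tie correction), chosen over
the RM-ANOVA because raw in-scanner startle amplitudes are typically
non-normal — the Shapiro–Wilk gate (`shapiro_gate()`, parametric iff
p >= 0.05) formalises that choice.

## PPI quantification and group statistics

PPI% = (pulse_mean - ppi_mean) / pulse_mean * 100 per SOA, positive when the
prepulse reduced the blink; the percentage is exactly invariant to rescaling
all amplitudes. Per-run PPI uses the same run's pulse mean as denominator;
overall PPI averages the per-run cell means across runs, and a missing run
propagates as NA with the overall value computed from the remaining runs
under a warning.

The group comparison of PPI across SOAs is a repeated-measures one-way ANOVA
in the multivariate-contrast formulation: the subjects x 3 matrix is
projected onto orthonormal condition contrasts and regressed on the
grand-mean-centered subject-level covariate design (age, sex, menstrual
phase, habituation slope in the motivating design). The condition main
effect and every condition-by-covariate interaction are tested against the
pooled within-subject residual, so they share error degrees of freedom, and
the Greenhouse–Geisser epsilon estimated from that residual covariance
multiplies both df — reproducing the convention of mainstream GLM software,
including its signature pattern of identical adjusted df across all
within-subject terms. Covariate main effects are tested on the subject
means. The implementation is pure matrix algebra and is cross-checked
against `car::Anova` (type III, GG-corrected) in the test suite; under the
null its epsilon-corrected condition test holds the nominal 5% size within
binomial error over 1,000 simulations. Run-to-run reliability uses
Spearman's rho with a Fisher-z 95% interval (SE = 1/sqrt(n-3)) for
pulse-trial amplitudes and ICC(3,1) — two-way mixed, single rater,
consistency, `(BMS - EMS) / (BMS + (k-1) EMS)` with the standard F-based
interval — for per-run PPI, matching the usual normality-based division of
labour between the two.

## What the synthetic validation does and does not show

Because the generator implements exactly the additive log-trial model and
the multiplicative PPI attenuation the analysis assumes, parameter recovery
shows that the pipeline is an unbiased, correctly-coded estimator of its own
model: noise-free waveform round trips recover injected amplitudes to
better than 0.1%; with A0 ~ U(2, 8) mV and beta_true ~ U(-3, 0), fitted
slopes are unbiased (|mean error| well below 0.1) and correlate above 0.95
with truth; 200 cohorts of n = 42 recover 0/13/10% PPI within two
Monte-Carlo standard errors. Two deliberate choices keep those estimands
clean. First, the PPI-recovery cohorts fix every subject's true attenuation
at the nominal fractions: the attenuation fraction lives in [0, 1], so
symmetric between-subject variation around 0 is impossible (a clamped normal
has mean about +2%) and would silently change the truth being recovered.
Second, those cohorts set beta_true = 0: with habituation active the
percentage estimator inherits a small positive bias because pulse-alone
trials systematically sample earlier (larger-amplitude) ordinals than PPI
trials — a property of the percentage measure under interleaved designs
worth knowing about, not an implementation error. None of this validates
the model against real EMG, where habituation need not be log-linear,
attenuation need not be multiplicative, and gradient noise is non-stationary.

## Numerical and reproducibility choices

Problem sizes are chosen so the full validation battery runs comfortably on
one CPU: waveform-level checks run at 2 kHz sampling (the blink band is
fully below Nyquist there, and chain homogeneity makes scoring fidelity
rate-independent above that point) with shortened ISIs, while schedule-level
quantities always use the full 9–21 s design; cohort statistics use the
amplitude-level generator. All randomness flows from one master seed through
a fixed affine sub-seed scheme (every derived seed stays below 2^31), so
adding a subject never perturbs another subject's data, and text outputs use
fixed 6-significant-digit formatting — identical config + seed reproduces
every output file byte-for-byte. Degenerate inputs fail loudly rather than
silently: zero-variance t tests, incomplete repeated-measures matrices,
collinear covariate designs (named columns), out-of-recording scoring
windows (named trials), and unsatisfiable schedule compositions all raise
errors.

## Known limitations

The comb notch assumes stationary harmonic interference; template-based or
adaptive artifact subtraction is out of scope. The habituation model is
additive in log trial number; a multiplicative-decay generator variant is
not fitted, only simulated. Scoring windows are fixed per session rather
than adapted per trial. The RM-ANOVA requires complete within-subject
matrices (no imputation), and the menstrual-phase covariate is accepted
only as a coded column.
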