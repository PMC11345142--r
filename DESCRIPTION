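Package: startlekit
Title: Acoustic Startle EMG Analysis: Habituation and Prepulse Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing acoustic startle eyeblink electromyography (EMG)
    recorded during functional MRI. Builds and validates the three-run startle
    paradigm (pulse, prepulse, and prepulse-inhibition trials at 30/60/120 ms
    stimulus onset asynchrony), simulates orbicularis-oculi EMG with known
    ground truth (log-trial habituation, SOA-specific prepulse inhibition,
    non-response trials, spontaneous blinks, scanner-gradient harmonics),
    implements the signal-conditioning chain (band-pass, comb notch,
    rectification, smoothing), scores per-trial blink amplitude and latency with
    trial and participant exclusion rules, fits the per-subject habituation
    regression slope with intercept correction, computes prepulse-inhibition
    percentages, and provides the group-level statistics battery: Friedman test,
    one-sample t with Cohen's d, Spearman correlation with confidence interval,
    Greenhouse-Geisser epsilon, repeated-measures ANOVA with subject-level
    covariates, and single-rater consistency intraclass correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
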