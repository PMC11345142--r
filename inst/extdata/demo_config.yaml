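# Demo pipeline configuration: 6 simulated subjects, 3 runs.
# The demo simulates at 2 kHz to keep the waveform stage light; the blink band
# (100-500 Hz) is fully below Nyquist so scoring fidelity is unaffected.
n_subjects: 6
fs: 2000
seed: 1
schedule:
  isi_min: 9
  isi_max: 21
  lead_in: 10
noise:
  white_noise_sd: 0.05
  gradient_fundamental: 150
  gradient_harmonics: 3
  gradient_amp: 0.1
stats:
  log_base: 10
  c_mode: unstandardised
  center: subject
  mode: amplitude
write_signals: false
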