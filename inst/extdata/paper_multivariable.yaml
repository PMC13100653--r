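# Horizon-mode multivariable effect (10-60 min ahead): below-threshold
# indicator OR 1.68, dRBV/dt OR 0.26 per %/min, SBP OR 0.94 per mmHg,
# delta-SBP OR 1.02 per mmHg, HR OR 1.02 per bpm. Events are driven by
# the covariates one vitals interval before the event.
mode: multivariable
intercept: 1.0391
sigma_b: 1.67
terms:
  below_threshold: 0.51879379
  drbv_dt: -1.34707365
  sbp: -0.06187540
  delta_sbp: 0.01980263
  hr: 0.01980263
threshold:
  t: [0, 240]
  tau: [96, 88]
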