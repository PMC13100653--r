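# Concurrent association effect: OR 1.053 per 1-point increase in
# delta-RBV (= 100 - RBV), with between-patient SD 1.67 on the logit
# scale. Intercept calibrated to ~29.7% session-level IDH incidence.
mode: continuous
intercept: -4.6562
sigma_b: 1.67
terms:
  delta_rbv: 0.05164485
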