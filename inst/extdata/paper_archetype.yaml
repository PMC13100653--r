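# Session-level association effect: OR 2.58 for membership of a high-risk
# trajectory archetype (steep or intermediate decline) vs the plateau
# reference.
mode: archetype
intercept: -4.4688
sigma_b: 1.67
terms:
  risk_group: 0.94779123
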