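outcome: outcome
seatbelt: seatbelt
period: period
covariates:
  male: "1 = male driver; 0 = otherwise"
  slope: "1 = crash on sloping road; 0 = otherwise"
  rors: "1 = vehicle ran off-road on a straight; 0 = otherwise"
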