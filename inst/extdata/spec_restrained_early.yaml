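# Example specification: the layout of an early-period restrained-driver
# model.  One random male-driver coefficient on the minor-injury utility
# (normal mixing distribution, sloped-road mean shifter), fixed coefficients
# elsewhere, constants on the two non-base severity levels.
alternatives: [minor, severe, fatal]
base: minor
constants: [severe, fatal]
terms:
  - {covariate: alcohol, alternative: fatal}
  - {covariate: flush_median, alternative: fatal}
  - {covariate: rors, alternative: minor}
  - {covariate: rorc, alternative: minor}
  - {covariate: rorcg, alternative: fatal}
  - {covariate: unlit_road, alternative: severe}
random:
  - covariate: male
    alternative: minor
    distribution: normal
    mean_shifters: [slope]
    variance_shifters: []
    sign: 1
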