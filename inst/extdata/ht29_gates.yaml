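mode: multiparametric_g0
priority:
- M
- G0
- S
- G1
- G2
- subG1
- '>G2/M'
gates:
  M:
    phh3_mean:
      low: 300.0
      high: .inf
    norm_dna:
      low: 1.4
      high: 2.5
  G0:
    norm_dna:
      low: 0.7
      high: 1.4
    log_edu:
      low: 3.2
      high: 4.3
    phh3_mean:
      low: -.inf
      high: 300.0
    ki67_mean:
      low: -.inf
      high: 200.0
  S:
    log_edu:
      low: 4.5
      high: .inf
  G1:
    norm_dna:
      low: 0.7
      high: 1.4
    log_edu:
      low: 3.2
      high: 4.3
    phh3_mean:
      low: -.inf
      high: 300.0
  G2:
    norm_dna:
      low: 1.4
      high: 2.5
    log_edu:
      low: 3.2
      high: 4.3
    phh3_mean:
      low: -.inf
      high: 300.0
  subG1:
    norm_dna:
      low: -.inf
      high: 0.7
  '>G2/M':
    norm_dna:
      low: 2.5
      high: .inf
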