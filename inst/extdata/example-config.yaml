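# Example run configuration: the default device operating point with a
# 0.1% surfactant fluid (higher k, lower sigma) and a smaller bead load.
fluid:
  sigma_mN_m: 34
  k_factor: 0.7
  label: "0.1% surfactant in PBS"
beads:
  count: 2000
loading:
  strategy: stepwise
  volume_ul: 45
seed: 7
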