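# small synthetic boosted-SIT trial: four 34-day exposure periods,
# 12 treated / 10 control traps at 1 trap/ha, deepening suppression
simulation:
  J_treated: 12
  J_control: 10
  lambda: [15, 15, 15, 15]
  theta_true: [1.0, 0.6, 0.3, 0.15]
  sigma_u: 0.4
  phi: 0.5
  sessions_per_period: 4
  seed: 20210601
species: albopictus
stage: egg
threshold: 0.20
alpha: 0.95
mcmc:
  chains: 2
  iter: 3000
  warmup: 1000
  seed: 11
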