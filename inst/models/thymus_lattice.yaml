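# 2-D thymus migration/selection model: geometry, selection thresholds,
# binding/migration rates. All values are placeholder magnitudes and can
# be overridden; time units are arbitrary "interaction time" units.
lattice:
  width: 50
  height: 50
  epithelial_fraction: 0.15
  bands:
    subcapsular: 0.15
    cortex: 0.45
thresholds:
  theta_pos_DP: 5      # interactions needed for DP positive selection
  theta_pos_SP: 3      # interactions needed for SP maturation
  T_neglect_DP: 30     # time limit before death by neglect (DP)
  T_neglect_SP: 20     # time limit before death by neglect (SP)
  T_neg: 12            # cumulative bound-time ceiling -> negative selection
  tau_lineage: 2.0     # longest-interaction cutoff: >= tau -> CD4, < tau -> CD8
rates:
  k_on: 5              # TCR/MHC binding rate (1/time)
  k_off: 1             # unbinding rate (1/time)
  noise: 0.2           # probability of a random (non-chemotactic) move
  dt: 0.1              # step length
  dn_dwell: 10         # cortical dwell time before DN -> DP
  influx: 1            # new DN agents per step
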