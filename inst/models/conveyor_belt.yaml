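name: conveyor_belt
parameters:
  Sn: 10000.0
  Pn: 0.2
  Pp: 0.2
  Ps: 0.2
  Dn: 0.05
  Dp: 0.05
  Ds: 0.05
  a4: 0.08
  a8: 0.02
  Us4: 0.5
  Us8: 0.5
  gamma: 1.0
  uN0: 0.05
  uP0: 0.05
  us: 0.05
regions:
- name: differentiation
  states:
  - DN
  - DP_early
  - DP_late
  - SP4
  - SP8
  initial: DN
  transitions:
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g1
    reset:
      generation: g1
      cell_cycle: G0
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g2
    reset:
      generation: g2
      cell_cycle: G0
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g3
    reset:
      generation: g2
      cell_cycle: G0
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g4
    reset:
      generation: g2
      cell_cycle: G0
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g5
    reset:
      generation: g2
      cell_cycle: G0
  - from: DP_early
    to: DP_late
    rate: uP0 + us*(i-1)
    kind: flow
    guard: generation == g6
    reset:
      generation: g2
      cell_cycle: G0
  - from: DN
    to: DP_early
    rate: uN0 + us*(i-1)
    kind: flow
    reset:
      generation: g1
  - from: DP_late
    to: SP4
    rate: a4
    kind: flow
    reset:
      generation: g1
  - from: DP_late
    to: SP8
    rate: a8
    kind: flow
    reset:
      generation: g1
  - from: DN
    to: EXIT
    rate: Dn
    kind: death
  - from: DP_early
    to: EXIT
    rate: Dp
    kind: death
  - from: DP_late
    to: EXIT
    rate: Dp
    kind: death
  - from: SP4
    to: EXIT
    rate: Ds
    kind: death
  - from: SP8
    to: EXIT
    rate: Ds
    kind: death
  - from: SP4
    to: EXIT
    rate: Us4
    kind: export
  - from: SP8
    to: EXIT
    rate: Us8
    kind: export
- name: cell_cycle
  states:
  - G0
  - SM
  initial: G0
  transitions:
  - from: G0
    to: SM
    rate: Pn
    kind: flow
    guard: differentiation == DN
  - from: G0
    to: SM
    rate: Pp
    kind: flow
    guard: differentiation == DP_early
  - from: G0
    to: SM
    rate: Ps
    kind: flow
    guard: differentiation == SP4
  - from: G0
    to: SM
    rate: Ps
    kind: flow
    guard: differentiation == SP8
- name: generation
  states:
  - g1
  - g2
  - g3
  - g4
  - g5
  - g6
  initial: g1
  transitions:
  - from: g1
    to: g2
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g2
    to: g3
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g3
    to: g4
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g4
    to: g5
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g5
    to: g6
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g6
    to: g6
    rate: Pn
    kind: division
    guard: cell_cycle == SM && differentiation == DN
    reset:
      cell_cycle: G0
  - from: g1
    to: g2
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g2
    to: g3
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g3
    to: g4
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g4
    to: g5
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g5
    to: g6
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g6
    to: g6
    rate: Pp
    kind: division
    guard: cell_cycle == SM && differentiation == DP_early
    reset:
      cell_cycle: G0
  - from: g1
    to: g2
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g2
    to: g3
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g3
    to: g4
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g4
    to: g5
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g5
    to: g6
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g6
    to: g6
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP4
    reset:
      cell_cycle: G0
  - from: g1
    to: g2
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
  - from: g2
    to: g3
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
  - from: g3
    to: g4
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
  - from: g4
    to: g5
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
  - from: g5
    to: g6
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
  - from: g6
    to: g6
    rate: Ps
    kind: division
    guard: cell_cycle == SM && differentiation == SP8
    reset:
      cell_cycle: G0
sources:
- into: differentiation == DN && cell_cycle == G0 && generation == g1
  rate: Sn
exclusions:
- differentiation == DN && generation == g5
- differentiation == DN && generation == g6
- differentiation == DP_late && generation == g3
- differentiation == DP_late && generation == g4
- differentiation == DP_late && generation == g5
- differentiation == DP_late && generation == g6
- differentiation == SP4 && generation == g3
- differentiation == SP4 && generation == g4
- differentiation == SP4 && generation == g5
- differentiation == SP4 && generation == g6
- differentiation == SP8 && generation == g3
- differentiation == SP8 && generation == g4
- differentiation == SP8 && generation == g5
- differentiation == SP8 && generation == g6
- differentiation == DP_late && cell_cycle == SM

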