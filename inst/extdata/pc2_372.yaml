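# Twofold-symmetric single-chain pseudocycle, 372 nt total (186 nt/subunit).
# Each subunit: three hairpins (h1, h2, h3) and a kissing-loop pair (kissA
# pairs the next subunit's kissB), separated by hinge-like loops.
segments:
  - {name: h1a,    min: 24, max: 24, role: helix_side}
  - {name: loop1,  min: 4,  max: 8,  role: loop}
  - {name: h1b,    min: 24, max: 24, role: helix_side}
  - {name: hinge1, min: 6,  max: 10, role: hinge}
  - {name: h2a,    min: 18, max: 18, role: helix_side}
  - {name: kissA,  min: 10, max: 10, role: helix_side}
  - {name: spacer, min: 2,  max: 6,  role: loop}
  - {name: kissB,  min: 10, max: 10, role: helix_side}
  - {name: h2b,    min: 18, max: 18, role: helix_side}
  - {name: hinge2, min: 6,  max: 10, role: hinge}
  - {name: h3a,    min: 24, max: 24, role: helix_side}
  - {name: loop3,  min: 4,  max: 8,  role: loop}
  - {name: h3b,    min: 24, max: 24, role: helix_side}
  - {name: hinge3, min: 1,  max: 3,  role: hinge}
intra_edges:
  - {a: h1a, b: h1b, orientation: antiparallel}
  - {a: h2a, b: h2b, orientation: antiparallel}
  - {a: h3a, b: h3b, orientation: antiparallel}
inter_edges:
  - {a: kissA, b: kissB, orientation: antiparallel}
symmetry_order: 2
target_total: 372
seed: 20260925
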