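# Scaled-down preset for desk-scale validation runs: demes of 100
# diploids (scale 5 rescales m and mu_neutral to preserve 4*N*m and
# 4*N*mu), short burn-in, few replicates.
island:
  d: 10
  N_local: 500
  m: 0.009
selection:
  t: 0.015
  U: 0.007
  M: 0
  L_selected: 700
neutral:
  mu_neutral: 1.0e-5
  L_neutral: 100
run:
  generations: 20000
  replicates: 50
  seed: 1
  scale: 5
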