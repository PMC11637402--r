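# Reference experimental design: 10 demes x 500 diploids, selection-
# strength sweep at three migration rates and two map lengths.
island:
  d: 10
  N_local: 500
  m: [0.00045, 0.009, 0.09]
selection:
  # N_local * t in {0, 0.25, 0.5, 1, 2.5, 5, 7.5, 15}
  t: [0, 0.0005, 0.001, 0.002, 0.005, 0.01, 0.015, 0.03]
  U: 0.007
  M: [0, 0.01]
  L_selected: 700
neutral:
  mu_neutral: 1.0e-5
  L_neutral: 10000
run:
  # full scale: 50 * N_global generations, 750 replicates
  replicates: 750
  seed: 1
  scale: 1
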