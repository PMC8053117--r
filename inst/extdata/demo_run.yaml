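# Demo pipeline configuration: two simulated enzymes, one synthetic target.
target:
  protospacer: GGTGATCCAGGCACTTAAGC
  pam: TGG
  pam_side: 3prime
  seed_len: 10
doping:
  f: 0.15
simulate:
  time_points: [0, 1, 5, 30, 60, 180]
  depth: 20000
  n_members: 20000
  prep_nick: 0.05
  seed: 1
  render_fastq: true
enzymes:
  WT: wt
  HF: hf
reference_enzyme: WT
strata: [1, 2, 3, 4, 5]
plots: false
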