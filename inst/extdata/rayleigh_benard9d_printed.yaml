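name: rayleigh_benard9d_printed
# Historical hand-typed symbol matrix for the 9D Rayleigh-Benard
# truncation, kept verbatim for comparison. It disagrees with the matrix
# derived from the equations at entries (6,6), (7,6), (8,5), (8,6) and
# (9,5); the derived variant (see rayleigh_benard9d.yaml) is the default
# everywhere in this package because the out-strength walkthroughs are
# only consistent with it.
variables: [x1, x2, x3, x4, x5, x6, x7, x8, x9]
jacobian:
  - ["1",  "1b", "1b", "1b", "1b", "0",  "1",  "0",  "0"]
  - ["1b", "1b", "0",  "1b", "1b", "0",  "0",  "0",  "1"]
  - ["1b", "1b", "1",  "1b", "1b", "0",  "0",  "1",  "0"]
  - ["0",  "1b", "1b", "1b", "1b", "0",  "0",  "0",  "1"]
  - ["0",  "1b", "0",  "1b", "1",  "0",  "0",  "0",  "0"]
  - ["0",  "1b", "0",  "1b", "0",  "0",  "0",  "0",  "1b"]
  - ["1",  "0",  "0",  "1b", "1b", "1",  "1",  "1b", "1b"]
  - ["0",  "1b", "1",  "0",  "0",  "1b", "1b", "1b", "1b"]
  - ["0",  "1b", "0",  "1b", "1b", "1b", "1b", "1b", "1"]
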