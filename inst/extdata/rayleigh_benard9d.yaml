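name: rayleigh_benard9d
# Nine-mode second-order Fourier truncation of Rayleigh-Benard convection
# in a three-dimensional cell with square platform. sigma is the Prandtl
# number, R the reduced Rayleigh number, b1..b6 cell-geometry constants.
# All nonlinearities are quadratic (polynomial), none rational.
variables: [x1, x2, x3, x4, x5, x6, x7, x8, x9]
equations:
  - "-sigma*b1*x1 - x2*x4 + b4*x4^2 + b3*x3*x5 - sigma*b2*x7"
  - "-sigma*x2 + x1*x4 - x2*x5 + x4*x5 - sigma*x9/2"
  - "-sigma*b1*x3 + x2*x4 - b4*x2^2 - b3*x1*x5 + sigma*b2*x8"
  - "-sigma*x4 - x2*x3 - x2*x5 + x4*x5 + sigma*x9/2"
  - "-sigma*b5*x5 + x2^2/2 - x4^2/2"
  - "-b6*x6 + x2*x9 - x4*x9"
  - "-b1*x7 - R*x1 + 2*x5*x8 - x4*x9"
  - "-b1*x8 + R*x3 - 2*x5*x7 + x2*x9"
  - "-x9 - R*x2 + R*x4 - 2*x2*x6 + 2*x4*x6 + x4*x7 - x2*x8"
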