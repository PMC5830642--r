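name: dna13d
# Novak-Tyson model of DNA replication / cell-cycle control in fission
# yeast (wee1- cdc25OP double mutant). Concentration variables:
# x1 G2K, x2 R, x3 G1K, x4 G2R, x5 IE, x6 UbE2, x7 Wee1, x8 PG2,
# x9 G1R, x10 PG2R, x11 UbE, x12 Cdc25; x13 is the cell mass
# (exponential growth). Primed rate constants are written k2p, k6p.
variables: [x1, x2, x3, x4, x5, x6, x7, x8, x9, x10, x11, x12, x13]
equations:
  - "k1 - (k2 + kwee + k7*x2)*x1 + k25*x8 + (k7r + k4)*x4"
  - >-
    k3 - k4*x2 - kp*x2*(x1 + beta*x8 + alpha*x3)*x13/(Kmp + x2)
    - k7*x2*(x1 + x8) - k8*x2*x3 + (k8r + k6p)*x9
    + (k7r + k2 + k2p)*(x4 + x10)
  - "k5 - (k6 + k8*x2)*x3 + (k8r + k4)*x9"
  - "k7*x2*x1 - (k7r + k4 + k2 + k2p)*x4"
  - "ki*(x1 + beta*x8)*(1 - x5)/(Kmi + 1 - x5) - kir*x5/(Kmir + x5)"
  - "ku2*(x1 + beta*x8)*(1 - x6)/(Kmu2 + 1 - x6) - kur2*x6/(Kmur2 + x6)"
  - "kwr*(1 - x7)/(Kmwr + 1 - x7) - kw*(x1 + beta*x8)*x7/(Kmw + x7)"
  - "kwee*x1 - (k25 + k2 + k7*x2)*x8 + (k7r + k4)*x10"
  - "k8*x2*x3 - (k8r + k4 + k6p)*x9"
  - "k7*x2*x8 - (k7r + k4 + k2 + k2p)*x10"
  - "ku*x5*(1 - x11)/(Kmu + 1 - x11) - kur*x11/(Kmur + x11)"
  - "kc*(x1 + beta*x8)*(1 - x12)/(Kmc + 1 - x12) - kcr*x12/(Kmcr + x12)"
  - "mu*x13"
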