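name: goldbeter5d
# Goldbeter's five-variable model of circadian PER oscillations in
# Drosophila: x1 per mRNA, x2-x4 phosphorylation states of PER protein,
# x5 nuclear PER. All kinetics are Michaelis-Menten, so most couplings
# are rational.
variables: [x1, x2, x3, x4, x5]
equations:
  - "vs*KI^4/(KI^4 + x5^4) - vm*x1/(Km + x1)"
  - "ks*x1 - V1*x2/(K1 + x2) + V2*x3/(K2 + x3)"
  - "V1*x2/(K1 + x2) + V4*x4/(K4 + x4) - x3*(V2/(K2 + x3) + V3/(K3 + x3))"
  - "V3*x3/(K3 + x3) - x4*(V4/(K4 + x4) + k1 + vd/(Kd + x4)) + k2*x5"
  - "k1*x4 - k2*x5"
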