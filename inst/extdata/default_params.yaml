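# Energy and damping parameters of the subcellular-element wing-disc model.
# One block per energy term; unknown keys are rejected by read_param_config().
# Units: amplitudes/stiffnesses nN or nN/um, lengths um, k_vol nN/um^3,
# damping nN*AU/um. These are the package defaults.

E_v:                 # Morse, volume exclusion between non-bonded nodes
  U0: 2.956          # 0.4 * exp(2): equilibrium separation exactly 0.2 um
  xi0: 0.06
  W0: 1.0
  ga0: 0.15
  cutoff: 0.5

E_nuc:               # Morse, nucleus cohesion (10-node cluster per cell)
  U0: 14.328         # 4/3 * exp(100/42): equilibrium spacing 1.1 um
  xi0: 0.308
  W0: 4.0
  ga0: 0.924
  cutoff: 2.5

E_memb:              # spring, membrane cortex (rest lengths set per bond)
  k: 25

E_adhL:              # spring, E-cadherin lateral cell-cell adhesion
  k: 20
  r0: 0.2
  breakable: true
  break_distance: 0.6

E_adhB:              # spring, integrin cell-ECM adhesion
  k: 20
  r0: 0.2
  breakable: true
  break_distance: 0.6

E_adhA:              # spring, columnar-squamous interlayer adhesion
  k: 10
  r0: 0.2
  breakable: true
  break_distance: 1.5

E_cont:              # spring, basal actomyosin contractility (k = k_cont)
  k: 0
  r0: 0

E_ecm:               # spring, ECM chain stiffness
  k: 40

E_vol:               # quadratic area penalty (2D volume conservation)
  k_vol: 5

damping:
  C_nuc: 1
  C_memb: 1
  C_ECM: 1
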