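# Per-element parameter table for the fluctuating-charge surrogate engine
# and the classical terms.
#
#   chi        electronegativity-like site parameter, hartree / e
#   eta        hardness (diagonal self-repulsion), hartree / e^2
#   vdw_radius Bondi van der Waals radius, angstrom (ESP grid construction)
#   mm_charge  default MM point charge, e (waters use TIP3P charges instead)
#   lj_eps     Lennard-Jones well depth, hartree
#   lj_sigma   Lennard-Jones sigma, angstrom
#
# The chi/eta ordering is chosen so that nitrogen sites are the softest:
# on removal of an electron from the solute anion the hole then
# concentrates on the nitrogen-rich nucleobase rather than on the sugar
# or the phosphate, which is the qualitative physics the engine must
# exhibit.  Hydrogens carry no Lennard-Jones well (TIP3P convention); the
# oxygen parameters are the TIP3P values.
elements:
  "H":
    chi: 0.30
    eta: 3.50
    vdw_radius: 1.20
    mm_charge: 0.15
    lj_eps: 2.0e-5
    lj_sigma: 1.00
  "C":
    chi: 0.35
    eta: 0.62
    vdw_radius: 1.70
    mm_charge: 0.10
    lj_eps: 1.743e-4
    lj_sigma: 3.3997
  "N":
    chi: 0.45
    eta: 0.38
    vdw_radius: 1.55
    mm_charge: -0.40
    lj_eps: 2.709e-4
    lj_sigma: 3.2500
  "O":
    chi: 0.55
    eta: 2.50
    vdw_radius: 1.52
    mm_charge: -0.60
    lj_eps: 2.424e-4
    lj_sigma: 3.1507
  "P":
    chi: 0.25
    eta: 0.95
    vdw_radius: 1.80
    mm_charge: 1.00
    lj_eps: 3.187e-4
    lj_sigma: 3.7400
water:
  o_charge: -0.834
  h_charge: 0.417
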