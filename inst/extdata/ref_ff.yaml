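# Reference vacuum classical force field, element-keyed.
# Units: lengths Angstrom, energies kcal/mol, angles degrees (converted to
# radians internally). Nonbonded: 12-6 Lennard-Jones with Lorentz-Berthelot
# mixing of the per-element sigma/epsilon below, plus Coulomb
# 332.0637 * qi * qj / (dielectric * r). 1-2 and 1-3 pairs are excluded;
# 1-4 pairs enter at full strength. No distance cutoff: sums are exact.
coulomb:
  dielectric: 1.0
lj:
  H:  {sigma: 2.50, epsilon: 0.030}
  C:  {sigma: 3.40, epsilon: 0.086}
  N:  {sigma: 3.25, epsilon: 0.170}
  O:  {sigma: 3.12, epsilon: 0.210}
  S:  {sigma: 3.56, epsilon: 0.250}
  P:  {sigma: 3.74, epsilon: 0.200}
  F:  {sigma: 3.12, epsilon: 0.061}
  Cl: {sigma: 3.52, epsilon: 0.265}
  Br: {sigma: 3.73, epsilon: 0.320}
  I:  {sigma: 3.96, epsilon: 0.400}
bonds:          # harmonic k*(b-b0)^2; k kcal/mol/A^2, b0 A
  C-C: {k: 310, b0: 1.526}
  C-H: {k: 340, b0: 1.090}
  C-N: {k: 337, b0: 1.475}
  C-O: {k: 320, b0: 1.410}
  C-S: {k: 227, b0: 1.810}
  C-F: {k: 367, b0: 1.380}
  C-Cl: {k: 232, b0: 1.766}
  C-Br: {k: 159, b0: 1.944}
  N-H: {k: 434, b0: 1.010}
  N-N: {k: 350, b0: 1.420}
  N-O: {k: 300, b0: 1.400}
  O-H: {k: 553, b0: 0.960}
  O-O: {k: 300, b0: 1.460}
  O-P: {k: 230, b0: 1.610}
  S-H: {k: 274, b0: 1.336}
  S-S: {k: 166, b0: 2.038}
angles:         # harmonic k*(theta-theta0)^2 keyed by the central element
  H: {k: 35, theta0: 109.5}
  C: {k: 40, theta0: 109.5}
  N: {k: 50, theta0: 109.5}
  O: {k: 55, theta0: 104.5}
  S: {k: 62, theta0: 92.0}
  P: {k: 45, theta0: 109.5}
torsions:       # v*(1+cos(mult*phi - phi0)) keyed by the central bond's elements
  C-C: {v: 0.15, mult: 3, phi0: 0}
  C-N: {v: 0.20, mult: 3, phi0: 0}
  C-O: {v: 0.18, mult: 3, phi0: 0}
  C-S: {v: 0.20, mult: 3, phi0: 0}
  N-N: {v: 0.20, mult: 3, phi0: 0}
  O-P: {v: 0.25, mult: 3, phi0: 0}
  S-S: {v: 0.60, mult: 2, phi0: 0}
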