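---
title: "Ionization-energy decomposition for solvated nucleotides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionization-energy decomposition for solvated nucleotides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices
behind `qmmmion`: what each stage computes, which parameters matter and
why their defaults are what they are, what the synthetic-data module
does and does not emulate, and the known limitations of the surrogate
engine.

## The physical setting

A deoxyribonucleotide 5'-monophosphate in water is an anion (total
charge −1 e). Ionization removes one electron, producing a neutral
radical. Three energies characterize the process within one embedding
framework $f$:

* the **vertical ionization energy**,
  $\mathrm{VIE}_f = E_f(\text{neutral}) - E_f(\text{anion})$, both
  single points at the anion-optimized geometry;
* the **adiabatic ionization energy**,
  $\mathrm{AIE}_f = E_f(\text{neutral at its own minimum}) -
  E_f(\text{anion at its own minimum})$;
* the **released (relaxation) energy**,
  $E_f(\text{neutral at anion geometry}) -
  E_f(\text{neutral at neutral geometry})$, which equals
  $\mathrm{VIE}_f - \mathrm{AIE}_f$ when all three are assembled from
  the same four state energies. The pipeline computes it that way, so
  the identity holds to floating-point accuracy on every record.

The three frameworks are **QM/MM** (total energy of the embedded
system), **pol-QM** (the QM-region energy evaluated with the MM
point-charge background present) and **gas-QM** (the same QM region
with the background removed; always a single point at the
embedding-optimized geometry, never re-optimized). The total energy
decomposes as

$$E_\mathrm{QM/MM} = E_\text{pol-QM} + E_\text{QM-MM,VDW} + E_\mathrm{MM},$$

and because the van der Waals and MM terms do not depend on the
electronic state at fixed geometry, the QM/MM and pol-QM VIEs are
identical. `compute_vie()` exploits this: the QM/MM value *is* the
pol-QM difference by assembly, and the engine is checked at run time
for any state-dependence of the classical terms. For the AIE the
geometries differ between states, so
$\mathrm{AIE}_\mathrm{QM/MM} = \mathrm{AIE}_\text{pol-QM} +
\Delta E_\text{QM-MM,VDW} + \Delta E_\mathrm{MM}$ with generally
nonzero classical contributions; the closure of this decomposition is
one of the package's invariant tests.

## QM-region selection

The region radius $R_\mathrm{QM}$ is the minimal distance between a
water *oxygen* and any solute atom; a water joins the QM region, with
both hydrogens following its oxygen, when that distance is
$\le R_\mathrm{QM}$ (a closed threshold, so boundary waters are
included deterministically; hydrogen distances are not consulted).
Distances are plain Euclidean — the droplet is finite, with no periodic
images. The region is therefore monotone (nested) in $R_\mathrm{QM}$,
which `region_size_scan()` checks, and the solute is always QM, so the
QM/MM boundary never cuts a covalent bond and no link atoms are needed.

The convergence protocol mirrors standard practice: for each radius in
an ascending scan (default 1.6–4.2 Å in 0.2 Å steps), run a neutral
polarized single point, fit ESP charges on the QM region, and record
the total fitted charge on the solute; average over snapshots; declare
convergence at the smallest radius from which successive changes stay
below a threshold. The threshold (default 0.02 e) is a reporting knob,
surfaced in the output, because "small variation" is inherently a
judgment call; convergence is judged per system.

## ESP charges and hole profiles

Charges are fitted to the engine's electrostatic potential sampled on
Merz–Kollman-style shells: deterministic Fibonacci-lattice points on
each atom's van der Waals sphere scaled by 1.4, 1.6, 1.8 and 2.0, at a
density of 1.0 point/Å², with points inside any atom's innermost scaled
sphere removed. vdW radii default to the Bondi set. The fit minimizes
the squared potential deviation subject to the *exact* linear
constraint $\sum_i q_i = Q$ via the Lagrange-constrained normal
equations; the constraint holds to solver accuracy (well below 1e−8 e),
and a rank-deficiency check turns conditioning problems into an
actionable error. A quadratic restraint toward zero charge is available
but off by default — the scheme is plain ESP, not RESP. Because the
surrogate's "true" potential is itself a point-charge potential, the
fit recovers planted charges to machine precision on non-degenerate
geometries, which the test suite exploits as an oracle.

The **hole profile** is the per-atom difference
$q_\text{neutral} - q_\text{anion}$, aggregated over the BASE, RIBOSE,
PHOSPHATE and WATER components; the solute total (dRT) is the sum of
the first three. With both totals constrained, the vertical profile
sums to exactly +1. Vertical holes use the polarized charge sets by
default (a `vertical_gas_holes` option also fits the gas-embedding
pair); adiabatic holes compare the neutral fit at the neutral geometry
with the anion fit at the anion geometry, and the **hole transfer** is
their difference, which sums to zero.

## The surrogate engine

The quantum backend is a fluctuating-charge (electronegativity-
equalization) model: site charges minimize

$$E(q) = \sum_i \chi_i q_i + \tfrac12 \eta_i q_i^2
       + \tfrac12 \sum_{i \ne j} q_i q_j J(r_{ij})
       + \sum_i q_i V_\mathrm{ext}(r_i),
\qquad \sum_i q_i = Q,$$

solved exactly through the KKT linear system.
$J(r) = 1/\sqrt{r^2 + s_{ij}^2}$ with the Ohno-style screening
$s_{ij} = 2/(\eta_i + \eta_j)$, which keeps the hardness matrix
positive definite at chemical distances and removes the bare-Coulomb
singularity. Because the energy is variational in $q$, geometry
gradients follow from the envelope theorem (derivatives at fixed
minimizing charges), and the implementation's analytic gradients agree
with finite differences to ~1e−11 hartree/bohr.

Around the electronic term sit the classical pieces: Lennard-Jones
interactions (TIP3P oxygen parameters; hydrogens carry a small
repulsive core so that no atom can collapse onto them during
relaxation), screened point-charge Coulomb among MM molecules, harmonic
distance restraints that keep molecules bound (waters restrained to the
rigid TIP3P geometry; solute bonds and 1–3 pairs restrained at the
lengths of the snapshot the network was built on), and a soft spherical
wall about the solute centroid that keeps the droplet from evaporating.
The wall is centered on a coordinate-dependent centroid and every term
is a function of interatomic distances only, so the total energy is
invariant under rigid translation and rotation. One restraint network
is built per snapshot and threaded through every energy evaluation of
that snapshot's analysis, so all states and geometries sit on a single
well-defined surface — this is essential for the released-energy
identity to be meaningful.

**Parameter table.** The per-element $\chi$ (hartree/e), $\eta$
(hartree/e²), vdW radius, MM charge and LJ parameters ship as YAML
(`inst/extdata/eem_params.yaml`). Electronegativities follow the
familiar O > N > C > H > P ordering so oxygens acquire negative charge
in neutral water. The hardnesses are deliberately contrasted — nitrogen
softest (0.38), carbon soft (0.62), oxygen and hydrogen hard (2.5,
3.5) — so that on electron removal the hole concentrates on the
nitrogen-rich nucleobase rather than on the sugar, the phosphate or the
water. This is a qualitative calibration: the engine must *exhibit* the
physics (base-dominant holes, polarization-raised VIEs), not fit any
particular published number. The default was chosen once, against the
positive-definiteness limit of the hardness matrix, and frozen.

**Relaxation.** Geometry optimization is quasi-Newton (L-BFGS with the
engine's analytic gradients) to a maximum force component below 1e−4
hartree/bohr, with up to 500 iterations per round, a small number of
restarts that always resume from the lowest-energy point seen (a failed
line search can report an uphill point), and a backtracking
steepest-descent polish for the last factor of two when L-BFGS
terminates on its relative-reduction criterion. Everything is
deterministic for identical inputs. Scope `FULL` relaxes all atoms (the
QM/MM adiabatic path — the neutral is relaxed starting from the
anion-optimized structure, full system free); `QM_ONLY` freezes the MM
atoms and is exposed because published protocols are not always
explicit about which scope produced their adiabatic numbers.

## Synthetic data: what it emulates

`generate_snapshot()` stands in for classical MD sampling of the
solvated anion. Defaults are the study conditions of the emulated
protocol: a 30.0 Å water sphere, liquid-water number density
(0.0334 molecules/Å³), 40 snapshots at 25 ps intervals over a final
1000 ps window (labels S1025–S2000), and a small per-atom thermal
jitter (0.05 Å), chosen as a modest fraction of a typical room-
temperature RMS fluctuation so that jittered waters remain intact under
the 1.2 Å O–H grouping rule. Water oxygens are placed by rejection
sampling — uniform in the sphere, at least 2.4 Å from every solute atom
and 2.5 Å from every other oxygen — with the target count set by the
accessible volume (sphere minus solute contact region, estimated by
seeded hit-or-miss integration). Each water's dipole is oriented toward
the droplet center with random wobble: hydrogens inward, as in the
ordered first solvation shell of an anion. This orientation bias is
what makes the embedding potential positive inside the droplet and
hence the polarized VIE larger than the gas one, emulating the ordered
solvation response that in reality develops during equilibration.

What the generator does **not** emulate: hydrogen-bond network
topology, thermalized Boltzmann ensembles, conformational sampling of
the solute (the idealized planar-ring templates only jitter), or any
selection of "DNA-like" conformers. Tests that pass on these snapshots
therefore validate the *pipeline* — identities, conservation,
selection, statistics — not the force-field realism of any particular
trajectory.

`generate_records()` is a table-level emulator: given per-quantity
means and standard errors at ensemble size $n$, it draws normal
per-snapshot values with $\mathrm{sd} = \mathrm{se}\sqrt{n}$ and
assembles records that satisfy the record identities *by construction*
(released = VIE − AIE per framework; each hole profile's WATER entry
closes the sum to +1). It exists so that the ensemble-statistics layer
can be validated against known ground truth independently of the
engine.

## Statistics

Ensemble summaries report the mean, the sample standard deviation with
the $n-1$ denominator, and the standard error
$\mathrm{SE} = \mathrm{sd}/\sqrt{n}$. The $n-1$ choice is the estimator
convention appropriate for an SE of the mean; snapshots are treated as
independent (no autocorrelation correction), consistent with
fixed-interval extraction. Tables render as "mean ± se" at two
decimals; unrounded values are always written alongside.

## Numerical conventions

Coordinates are in angstrom at every interface and in bohr internally;
energies are hartree internally and eV in reports
(1 bohr = 0.52917721 Å, 1 hartree = 27.211386 eV). Classical
electrostatics (embedding and MM–MM) use a fixed 0.7 bohr screening
length; intramolecular pairs are excluded from classical Coulomb and LJ
sums, while the EEM term retains all QM-site pairs, as the model
requires. ESP grids are deterministic, so fitted charges — and
therefore entire pipeline outputs — are bit-stable across runs; the
command-layer determinism test diffs serialized artifacts byte for
byte. Degenerate inputs fail loudly: coincident atoms, rank-deficient
fits, singular hardness systems, broken water groups and non-ascending
scans all raise typed, situated errors.

## Known limitations

* The EEM energy is quadratic in the charges, so the linear-response
  hole profile at fixed geometry is independent of the external
  potential: polarized and gas-embedding *vertical* hole profiles are
  identical in this surrogate. Embedding-driven hole contrast (a real
  electronic-structure effect) is outside the model; the package still
  exposes both fits so a real backend slots in without interface
  changes.
* Polarized-QM released energies can come out negative: the neutral
  relaxation minimizes the *total* energy, and the pol-QM component of
  that minimum may rise even as the total falls. Only the total-energy
  (QM/MM) released energy is guaranteed non-negative at convergence.
* Absolute energies are not comparable to density-functional values;
  only identities, orderings and conservation laws are meaningful.
* The droplet generator's orientation bias is static; it approximates
  the mean solvation response, not its fluctuations, so SEs measured on
  generated geometric ensembles understate true configurational
  variability.

## Problem sizes used in the shipped tests

The test and acceptance runs use the TOY solute in 6–6.5 Å droplets
(~20–30 waters; full relaxations in seconds) and the dAMP template in
11 Å droplets (~170 waters, ~20 first-shell waters at
$R_\mathrm{QM}$ = 3.4 Å; single points) — sizes chosen so the whole
suite exercises every stage, including full-system relaxations and the
region scan, at interactive turnaround. The defaults of
`synthetic_config()` remain the full study conditions (30 Å, 40
snapshots); nothing in the code depends on the smaller study sizes.
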