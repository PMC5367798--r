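---
title: "Grid-free docking by tensor-train global optimization: methods"
author: "ttdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-free docking by tensor-train global optimization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttdock)
```

# The problem and the docking paradigm

Docking asks where a small flexible molecule (the ligand) binds in the
active site of a receptor. Under the *docking paradigm*, the native pose
sits at or near the global minimum of the complex's potential energy, so
docking reduces to global minimization of `E(x)` over the joint
conformational coordinates `x`. `ttdock` does this *grid-free*: there is no
precalculated potential grid — every visited conformation is scored
directly by a force-field backend — which is what makes receptor-atom
mobility and genuine local minimization possible in the first place.

The search coordinates are, in order: three translations of the ligand's
geometric center inside an axis-aligned *docking cube*, three rigid-rotation
parameters, one torsion per rotatable ligand bond, and three Cartesian
coordinates per *moveable* receptor atom, each confined to a small cube
around its crystallographic position. The dimension is therefore
`d = 6 + n_torsions + 3 * n_moveable`.

# The tensor-train optimizer

Each dimension is discretized on `n = 2^m` nodes, turning `E` into an
implicit `d`-dimensional tensor whose entries are only computed on demand.
Minimization becomes magnitude maximization of the transformed tensor

```
f(x, E*) = exp(100 * arccot(E(x) - E*)),
```

where `E*` is the lowest raw energy seen so far, `arccot` is the continuous
decreasing branch onto `(0, pi)`, and the range of `f` is `(1, exp(100*pi))`.
The transform is strictly decreasing in `E`, flattens huge van der Waals
clash energies towards 1, and sharply separates low minima — the global
minimum of `E` is the largest-magnitude element of `f`.

The maximizer is a cross-interpolation loop. A tensor train (TT) represents
a `d`-dimensional array as a chain of 3-way cores with ranks bounded by
`r_max`; TT-cross builds this interpolant from a small set of adaptively
chosen entries. Per iteration:

1. build crossed index sets per unfolding matrix (prefix and suffix pools);
2. interpolate with maxvol-pivoted sweeps at rank at most `r_max`;
3. harvest the maxvol interpolation points — rows of dominant (maximal
   `|det|`) submatrices carry large-magnitude entries;
4. refine each harvested point with a rough bounded Subplex (simplex)
   search in the continuous coordinates, project the result back to the
   nearest grid node, and evaluate it;
5. merge neighboring unfoldings' interpolation sets;
6. inject the best points seen so far into the sets, and repeat.

Step 4 performs at most `r_max` refinements per mode and iteration —
`O(d * r_max)` local optimizations — and never refines the same grid point
twice. One sweep evaluates `n * r_max^2` entries per mode (interior modes as
`r x r` crosses expanded along the mode; boundary modes as oversampled
panels), so a sweep costs exactly `d * n * r_max^2` oracle calls. Panel
columns are drawn half from the interpolation-point pools and half at
random: the pools provide exploitation of known good regions, the random
half keeps the cross from collapsing onto the first basin found. Ranks
start at `min(2, r_max)` and grow by one per iteration, which makes early
iterations cheap.

Every oracle call is counted on the `ImplicitTensor`, and the returned log
contains each evaluated index and value, so budget laws and determinism are
directly testable. The whole run is a deterministic function of the seed.

## Grid geometry

Grid nodes sit at cell centers, `x_i = a + (i - 0.5) (b - a) / n` for
1-based `i`: no node lies on a box face, and periodic dimensions (torsions,
rotation angles on `[0, 2*pi)`) do not duplicate endpoints. Continuous
points project to the containing cell, ties to the lower index.

Decoding applies torsions first (root-to-leaf over the torsion tree, root =
largest rigid fragment, ties to the lowest atom index), recenters the
conformer, rotates it about its geometric center, and translates that
center to the decoded cube position. With this order the ligand's geometric
center equals the decoded translation exactly, so every decoded pose has
its center inside the docking cube by construction; applying torsions after
placement would let the center drift out of the box for flexible ligands.
Rotations use three box-shaped parameters (axis azimuth on `[0, 2*pi)`,
cosine of the axis polar angle on `[-1, 1]`, spin on `[0, 2*pi)`); the
induced measure on orientations is not uniform, which is irrelevant for
optimization (every orientation remains reachable).

# Energy backends

The engine depends only on the `EnergyModel` contract: coordinates in,
total energy (kcal/mol, vacuum) out, optionally with an analytic gradient.
Backends are validated on entry — rigid-motion invariance on random
rotations plus translations, and finite-difference agreement of the
gradient. The packaged reference backend is a classical vacuum force field:

* harmonic bonds `k_b (b - b_0)^2` and angles `k_theta (theta - theta_0)^2`,
* cosine torsions `v (1 + cos(mult * phi - phi_0))`,
* 12-6 Lennard-Jones with Lorentz-Berthelot mixing plus Coulomb
  `332.0637 q_i q_j / (eps r)` with dielectric 1 (vacuum), 1-2 and 1-3
  pairs excluded, 1-4 pairs at full strength, and no distance cutoff (the
  sums are exact; this is recorded in the parameter file).

Parameters live in a packaged YAML table keyed by element (Lennard-Jones,
angles) or element pair (bonds, torsions); a missing entry raises an error
naming the pair. Atom types are element-derived small integers, with
aromatic-ring members shifted by +20 so that the chemical-digest machinery
(below) sees the aromatic/aliphatic distinction real force-field typing
provides. This backend is a testing vehicle, not a chemistry-grade force
field: an MMFF94 adapter satisfying the same contract can replace it
without touching the engine.

Rotatable bonds are single, non-ring ligand bonds whose removal leaves a
moving non-hydrogen atom on both sides — methyl and hydroxyl rotors are
excluded, matching how docking programs count ligand torsions.

# Post-processing

Docking appends every refined candidate to an append-only little-endian
binary store (`.ttm`; magic bytes, versioned header with seed and
configuration checksum, CRC32-checked records), because full coordinate
sets for thousands of minima are too large for molecular text formats. The
analysis chain then runs:

1. **Sorter dedup** — records sorted ascending by raw energy; a record
   survives iff its plain atom-ordered ligand RMSD to every survivor is at
   least 0.1 Å (keep-lowest rule; no symmetry, no moveable atoms).
2. **Full optimization** — box-constrained L-BFGS-B over the Cartesian
   coordinates of all ligand atoms and moveable receptor atoms (a change of
   variables from the docking DOFs), moveable atoms kept inside their small
   cubes, to a projected-gradient max-norm of 1e-4 kcal/mol/Å (cap 2000
   iterations; stalled line searches are polished with a trust-region
   quasi-Newton pass and a short backtracking descent step, then retried).
3. **Unique dedup** — the same greedy keep-lowest sweep, but under the
   symmetry-corrected RMSD with moveable atoms included, so symmetric ring
   flips and equivalent-atom swaps collapse to one minimum. The threshold
   defaults to the Sorter's 0.1 Å.
4. **Spectrum analysis** — minima indexed 1, 2, ... ascending in energy
   (ties by discovery order). INON is the smallest index within 2 Å
   symmetry-RMSD of the *optimized native* pose (the local minimum reached
   from the input crystallographic pose); EN additionally requires the
   energy within ±1 kcal/mol of the optimized native energy; both are
   infinite when no minimum qualifies, and INON = 1 means the docking
   paradigm is satisfied. The report is a TSV of index, energy, RMSD to
   native and ligand-center distance.

## Symmetry-corrected RMSD

Each ligand atom gets a *chemical digest*: its bonded neighborhood to depth
13 is ordered by (bond distance ascending, atom type ascending), the type
sequence is serialized one byte per atom type, and hashed with CRC32 (the
zlib convention: reflected polynomial 0xEDB88320, initial value 0xFFFFFFFF,
final xor). Equally distant atoms of equal type contribute identical bytes,
so their mutual order cannot matter. Atoms related by a type-preserving
graph automorphism share a digest; the converse can fail, which makes the
digest a heuristic — the computed RMSD never exceeds the naive ordered RMSD
and never goes below the true automorphism-constrained minimum. Within each
digest group the squared-distance matrix between the two conformations is
assigned optimally by the Hungarian method (squared distances, because RMSD
minimizes summed squared deviation); moveable receptor atoms enter as
identity pairs.

# Fixtures: what they emulate, and what they do not

`makeAnalyticTensor()` provides separable, Gaussian-mixture and
Rastrigin-style positive landscapes with dense-scan ground truth up to
3e5 entries, exercising the optimizer with no molecular machinery.

`makeToyComplex()` builds a Lennard-Jones cage — two rings of four carbon
atoms at `z = ±1.4` Å, radius 3.6 Å — around a template ligand (2-6
atoms, 0-3 rotatable bonds) whose input pose is the planted global
minimum; the tests verify that directly against coarse-grid scans and
1000-pose random sweeps. The clash variant adds one receptor atom 2.45 Å
above the ligand's top atom on the cage's open axis (a strong overlap with
the planted pose that a half-cube displacement relieves) and a floor atom
3.59 Å below the bottom atom that blocks the cheap escape of sliding the
ligand down the axis. Relieving the clash with a rigid receptor therefore
requires moving the *ligand* well away from the planted pose, while making
the clash atom moveable restores the planted pose as the global minimum —
the desk-scale analogue of docking runs where receptor-atom mobility turns
a failed pose prediction into a successful one.

These toys emulate the *structure* of the docking problem — a funnel-shaped
binding site, competing exterior minima, symmetry-equivalent poses, a
clash that mobility relieves — at sizes where exhaustive oracles run in
seconds. They do not emulate real energetics (no hydrogen-bond
directionality, no solvent, generic parameters), so a passing suite
certifies the machinery, not chemical accuracy on real complexes.

# Problem sizes and defaults

Published-scale runs of this family of methods use `r_max = 4` with
`n = 2^16`, or `r_max` 8-16 with `n = 2^12`, 15 iterations, docking cube
edge 10 Å, atom cube edge 1 Å, moveable-layer thickness up to 3 Å — those
are the CLI defaults. The package's own verification runs are desk-scale so
that every claim has an exhaustive or analytic oracle: cavity docking at
`m = 5` (`n = 32`), `r_max = 4`, 10 iterations, rough-refine budget 200;
clash-fixture docking at `m = 5`, 15 iterations, budget 500, cube edge 8 Å
(a binding-site-sized box around the planted pose); analytic-landscape
checks at `d = 6`, `n = 8` against full 262,144-entry scans; budget-law
checks at `n = 16`, `d` up to 16. The rough-refine budget keeps step 4
rough by design — the thorough polishing belongs to the L-BFGS-B stage.

# Numerical choices

* maxvol: partial-pivot LU initialization, greedy row swaps, dominance
  tolerance 1e-2, at most 100 swaps; rank-deficient input is an error, and
  non-convergence returns the best selection with a warning.
* Cross panels: numerical rank is cut at `max(dim) * eps * sigma_1`; ranks
  adapt downward on low-rank data, so exactness tests pass at machine
  precision rather than 1e-8.
* Interpolation-set pools are capped (64 entries per unfolding; best-point
  injection cap `2 * r_max`) and deduplicated.
* Angle gradients clamp `sin(theta)` at 1e-8; dihedral gradients use the
  standard end-atom formulas with the inner-atom terms determined by
  translation invariance — both are tested against central finite
  differences term by term.
* The energy transform never overflows: its range is bounded by
  `exp(100 * pi)` which is representable in a double.
* Dedup ties in energy keep discovery order, so outputs are deterministic.
* The store writes IEEE doubles little-endian; records round-trip
  bit-exactly and corrupt records are skipped with a warning and counted.

# Known limitations

* The reference force field is deliberately simple; INON/EN values on real
  complexes require a production force field behind the `EnergyModel`
  contract (e.g. an MMFF94 adapter) and protonated structures.
* The digest heuristic can merge atoms that no automorphism relates;
  symmetry RMSD is then a lower bound on the structure-preserving RMSD
  (never below the assignment optimum, never above the naive RMSD).
* Whole-side-chain and loop motions are out of scope: receptor flexibility
  is per-atom displacements inside small cubes.
* Macrocycle flexibility is not represented by the torsion model.
* Execution is single-process; the per-unfolding work is independent by
  construction, so a parallel map over modes is a natural extension, but
  the tested contract is sequential and deterministic.
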