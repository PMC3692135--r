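---
title: "Geometric ligand unbinding with ML-RRT: models, parameters and design choices"
author: "LigandEgress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric ligand unbinding with ML-RRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LigandEgress)
```

## The model

`LigandEgress` answers a narrow question: *is there a continuous,
sterically feasible motion that takes a bound ligand out of its protein,
and which side-chains does it have to push aside?* The molecular system
is mechanistic, not energetic:

* Atoms are spheres with Bondi van der Waals radii; bond lengths and
  angles are fixed at their input values. The only internal motions are
  rotations about acyclic single bonds (torsions).
* The **ligand** carries the active degrees of freedom: a rigid-body pose
  — translation plus quaternion orientation of a reference frame at the
  ligand's geometric center in the input structure — and one torsion per
  rotatable ligand bond.
* Flexible **protein side-chains** carry the passive degrees of freedom:
  one torsion per acyclic heavy-atom side-chain bond from CA outward.
  The backbone is rigid in this version.
* A conformation is *feasible* iff no non-bonded atom pair overlaps at a
  fraction `f` of the sum of their vdW radii (default `f = 0.75`).

All torsion values are stored as *offsets* from the input geometry, so
the identity conformation is the zero vector and maps exactly to the
input coordinates. This makes preprocessing bookkeeping (which residue
was perturbed, by how much) trivial to read off a conformation.

### Which bonds rotate

A bond is a torsional DOF iff it is acyclic (a bridge of the bond
graph), both atoms are heavy, and both endpoints have at least two heavy
neighbors. The last condition drops terminal-group spins (–OH, –NH3+,
–CH3): without hydrogens these rotations move no atom, and structures
are typically used without hydrogens here. Consequently prolines and
aromatic rings contribute nothing (ring bonds are not bridges), glycine
and alanine contribute nothing (no qualifying side-chain bond), and a
histidine ring can still flip about its CB–CG bond. Bonds themselves are
perceived geometrically — `|x_i − x_j| ≤ covrad_i + covrad_j + 0.45 Å`
within one molecule — because inputs may lack hydrogens and contain
nonstandard residues, which defeats template-based perception.

### Collision model

Feasibility checks exclude pairs whose distance cannot change: 1-2 and
1-3 bonded paths (fixed by rigid geometry), pairs inside one rigid piece
(the connected components left after deleting all torsion bonds), and
static–static pairs. 1-4 pairs *are* checked by default
(`check14 = TRUE`): their distances change with the torsion between
them, and they are the physically meaningful steric limit of a torsion
sweep. Whether to exclude them is exposed as a flag since conventions
differ between tools.

Contacts, used only for reporting, enlarge the collision scale by 20
percentage points (75% planning → 95% contacts) and consider only
ligand-vs-environment pairs.

## The search

The planner is a Manhattan-like RRT. Each iteration: draw a random
active sample (translation uniform over the receptor bounding box
inflated by the exit distance; orientation uniform over SO(3) by
Shoemake's method; torsions uniform within bounds); select the nearest
non-exhausted tree node; step toward the sample; validate the motion;
on collision involving flexible side-chains, perturb those side-chains
to clear the way.

Design choices the literature leaves open, with the rationale used here:

* **Active-space metric.** Translation distance + geodesic quaternion
  angle × ligand circumradius + Σ wrapped torsion difference × distal-set
  circumradius about its axis. Every term is an upper bound on an
  Å-scale atom displacement, so the metric compares heterogeneous DOFs
  in common units.
* **Step size.** One step caps that displacement bound at 1.0 Å.
  RRT-Connect (the default) repeats steps toward the sample until
  blocked or reached; RRT-Extend takes a single step per iteration.
* **Edge validation = output discretization.** A candidate edge is
  subdivided uniformly until the *true* maximum ligand-atom displacement
  between consecutive points is ≤ 0.5 Å, and each point is
  collision-checked. The same subdivision routine later produces the
  output frames, so every written frame is, by construction, a
  collision-checked conformation — validation and reporting cannot
  drift apart. The resolution is defined on ligand atoms; side-chain
  sweeps between checkpoints are not separately resolved.
* **Passive resolution.** When an edge is blocked and every blocking
  pair involves a flexible side-chain, up to 10 random Gaussian
  perturbations (σ = 0.4 rad, wrapped) of the blocking residues'
  torsions are tried from the parent's values; if the remaining clashes
  implicate additional flexible side-chains, those are recruited and the
  trials repeat, at most 3 recruitment rounds deep. A clash between the
  ligand and a static atom ends the attempt immediately. These constants
  are exposed in `plannerConfig()`.
* **Node exhaustion.** A node failing 50 consecutive expansions
  (`nFailMax`) is dropped from nearest-neighbor selection — the standard
  ML-RRT heuristic for not hammering on dead ends. Failed passive
  resolutions count as expansion failures of the selected node.
* **Goal and exit distance.** Success is ligand-center-to-receptor-center
  distance ≥ the exit distance. "Auto" uses
  `R_receptor + R_ligand + 2 Å` with `R_X` the circumradius of X's vdW
  envelope about its geometric center — beyond this the envelopes cannot
  touch, with margin. The receptor center averages *all* non-mobile
  atoms, including waters, ions and static ligand copies.
* **Preprocessing.** Input structures frequently contain overlaps at the
  working fraction. `resolveInitialClashes()` hill-climbs on the clash
  count with uniform per-trial perturbations ≤ 0.3 rad of the involved
  residues' torsions, 200 trials. Overlapping static atoms, or clashes
  involving no flexible side-chain, cannot be repaired this way and
  abort with advice to lower the vdW percentage.
* **Determinism.** Every stochastic element draws from one seeded RNG
  stream (the caller's RNG state is saved and restored), so a seed plus
  a configuration reproduces a run bit-for-bit; multiple requested paths
  use seeds `rngSeed + run index`.

## The `.amc` flexibility format

Per-residue binary flags (backbone, side-chain — backbone must be 0;
side-chains default to flexible) and per-ligand-bond dihedral lines
(four atom serials, angular bounds in degrees). The dialect — `#`
comments, `molecule …` block headers, whitespace-separated fields, the
template's self-documenting header — is fixed by this package. The
default torsion bounds are the full circle, the least restrictive
choice; bounds are configurable per dihedral. A ligand block, when
present, *replaces* the default dihedral set, so deleting a line freezes
that torsion. Interpolation follows the shorter angular arc for
full-circle torsions and stays linear (hence within bounds) for
restricted ones; antipodal quaternions are sign-flipped before slerp.

## The synthetic fixtures

Real complexes cannot ship with the package, and validation against one
downloads poorly and proves little at unit scale. Instead the generator
builds channels whose feasibility is known *analytically*:

* a cylindrical cage of carbon pseudo-atoms (ring spacing 3.5 Å —
  wide enough that no bonds are perceived between cage atoms, tight
  enough that the worst lattice hole is covered at 75% vdW and the
  blocked chord through it, ≥ 1.2 Å, cannot be tunneled by a 0.5 Å
  resolution check), closed at one end;
* a ligand (single atom, rigid ring, or 4-atom chain with one torsion)
  at the closed end; corridor clearance
  `R − (ligand radial extent + f·(r_lig + r_wall))` is reported and
  cross-checked against a brute-force axial probe;
* optionally a *gate*: a pseudo-residue whose static anchor plugs the
  wall holes it needs and whose two-torsion arm rests with its tip near
  the channel axis. Closed, the sampled worst-case crossing margin at
  the gate plane is negative (−0.13 Å at the default tip position,
  ≤ −0.5 Å at `gateTipRho = 0.2`); a ~0.5 rad swing of the arm's first
  torsion opens a corridor. Freezing the gate's side-chain flag in the
  `.amc` file makes the same geometry impassable.

Construction is fully deterministic, so the clearances are exact
properties, not expectations. What the fixtures do **not** emulate:
chemical realism (everything is carbon), dense packing, concerted
multi-residue gating, backbone motion, or the rugged narrow channels of
real proteins — passing tests here demonstrates algorithmic correctness
(soundness, goal satisfaction, recruitment, determinism), not predictive
accuracy on proteins.

Test and acceptance runs use these sizes: channels of ~40–50 atoms, 20–25
seeds per condition, iteration budgets of 700 (rigid-gate failure cases)
to 8000 (flexible-gate searches); the whole suite runs in a few minutes
on one core.

## Numerical details and degenerate inputs

* Angles are wrapped into (−π, π]; torsion distances use wrapped
  arithmetic for full-circle bounds.
* Quaternion slerp falls back to normalized linear interpolation below
  1e-9 rad; `quatAngle` folds the double cover, so q and −q are the same
  rotation everywhere.
* Written PDB coordinates carry 3 decimals; archive re-validation
  therefore shrinks clash thresholds by 5e-3 Å and allows 2e-3 Å on the
  displacement bound, and the contact report is computed from the
  rounded coordinates so it regenerates identically from the files.
* Atom serials above 99999 wrap on output; the first MODEL is read;
  altlocs other than ' '/'A' are dropped; unknown elements get a
  1.70 Å radius with a warning.
* Degenerate torsion bounds (lower = upper) pin the torsion; an atom
  with more than 8 perceived bonds aborts parsing as corrupt geometry.

## Limitations

Geometry only: no energies, electrostatics, pH or solvent — a feasible
path is a candidate, not a prediction; an infeasible search proves
nothing (RRT cannot certify infeasibility, it only fails to find).
Backbone flexibility is out of scope, so tightly gated systems that
require backbone breathing will fail at 75% and may need a reduced
fraction, which trades realism for reach. Exactly one ligand is mobile;
other copies are static obstacles. Side-chain sweeps between ligand-
resolution checkpoints are unresolved, a deliberate trade documented
above.
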