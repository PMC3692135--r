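# LigandEgress

Geometric simulation of protein–ligand unbinding pathways in R.

When a ligand leaves a buried binding site, interactions along the exit
route — far from the active site — can shape specificity and kinetics, yet
they are hard to observe experimentally and expensive to reach with
molecular dynamics. `LigandEgress` computes *geometrically feasible*
unbinding paths in seconds by treating the problem as robotic disassembly
planning:

- the **ligand** is an articulated mobile body whose pose (position +
  orientation of a frame at its geometric center) and rotatable-bond
  torsions are the **active** search variables;
- **protein side-chains** are articulated with freely rotatable bonds and
  form the **passive** variables, moved only when they obstruct progress;
- **scaled van der Waals overlap** between non-bonded atoms is the *only*
  feasibility condition: atoms `i, j` collide when
  `|x_i − x_j| < f · (r_i + r_j)`, with `f = 0.75` (75% of the Bondi
  radii) by default. No energies, electrostatics or solvent.

The search is a **Manhattan-like RRT (ML-RRT)**: a rapidly-exploring
random tree grown over the active variables alone; when an extension is
blocked by a collision involving a flexible side-chain, that side-chain's
torsions are perturbed randomly to let the ligand through (and a blocked
side-chain may recruit further side-chains, in a bounded cascade). A run
succeeds when the ligand's geometric center reaches a set **exit
distance** from the receptor's center — by default
`R_receptor + R_ligand + 2 Å`, where `R_X` is the radius of X's vdW
envelope around its center.

Outputs follow the conventions of geometric unbinding tools: each
solution is a sequence of PDB frames discretized so that no ligand atom
moves more than ~0.5 Å between consecutive frames, plus a ligand–protein
**contact report** (contacts detected at the collision scale enlarged by
20 percentage points, e.g. 95% when planning at 75%, each atom pair
listed once at its first frame) and an execution report.

Paths found this way are first approximations — candidate egress routes
and the side-chains they disturb — to be refined with energy-based
methods when needed.

## Worked example

The package ships deterministic synthetic systems with known geometry. A
carbon-atom channel, sealed by a two-torsion pseudo-side-chain "gate"
whose tip blocks the corridor (clearance −0.13 Å: geometrically
impassable while the gate is closed):

```r
library(LigandEgress)

fx <- makeChannelFixture(gate = TRUE)
model <- buildArticulatedModel(fx$system, fx$spec)
model
#> ArticulatedModel: 47 atoms
#>   active DOFs : 6 ( pose 6 + 0 ligand torsions )
#>   passive DOFs: 2 side-chain torsions in 1 residues

conf0 <- resolveInitialClashes(model)
path <- planUnbinding(model, conf0, plannerConfig(rngSeed = 1))
diagnostics(path)[c("success", "iterations", "finalDistance", "exitDistance")]
#> $success        [1] TRUE
#> $iterations     [1] 100
#> $finalDistance  [1] 14.05
#> $exitDistance   [1] 13.66
```

The planner recruited the gate torsions (the only passive DOFs), swung
the arm open and drove the ligand out: the final ligand–receptor center
distance (14.05 Å) exceeds the automatic exit distance (13.66 Å).
Discretize and inspect the first contacts:

```r
path <- discretizePath(model, path)
path
#> SolutionPath: 25 nodes, 69 frames
#>   success: TRUE, final center distance 14.05 A

head(buildContactsReport(model, path@frames), 3)
#>   frame ligSerial ligName ligRes envSerial envName envRes envChain envSeq distance
#> 1     2        47      C1    LIG         9       C    WAL        Z      9 3.133776
#> 2     4        47      C1    LIG        16       C    WAL        Z     16 3.175204
#> 3     6        47      C1    LIG        17       C    WAL        Z     17 3.109035
```

Each line: the frame at which that ligand–environment contact first
appears (95% vdW overlap), the two atoms, and their distance. Re-running
with the same seed reproduces all of this bit-for-bit; with the gate
frozen (`makeChannelFixture(gate = TRUE, gateFlexible = FALSE)`) every
seed fails, as it must.

`writeSolutionArchive()` writes `frame_0000.pdb … frame_NNNN.pdb`,
`contacts.txt` and `report.txt` per solution; `runJob()` runs the whole
pipeline for a PDB file (plus an optional `.amc` flexibility file), and
the `exec/ligand-egress` script exposes `run`, `template`, `fixtures`
and `check` subcommands from the shell.

For real complexes, per-residue flexibility is controlled by a plain-text
`.amc` file: one line per residue (`RESTYPE CHAIN:SEQ BACKBONE SIDECHAIN`,
backbone must be 0; side-chains default to 1) and one line per ligand
rotatable-bond dihedral (four atom serials + angular bounds). Generate a
template with `generateTemplateAMC()` or `ligand-egress template`.
`inst/scripts/insulin-validation.R` applies the pipeline to a locally
provided insulin-hexamer–phenol complex with the zinc-coordinating
histidines blocked.

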