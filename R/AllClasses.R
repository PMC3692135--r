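#' MolecularSystem: atoms, bonds and the mobile-ligand designation
#'
#' Container for a parsed protein-ligand complex. Atoms are stored as a
#' data.frame (one row per atom: serial, name, altloc, residue, chain,
#' sequence number + insertion code, coordinates, element, vdW and covalent
#' radii, HETATM flag, molecule id); bonds as a two-column integer matrix of
#' atom indices; the mobile ligand as an index set. All remaining atoms —
#' including static waters, ions and additional copies of the ligand — form
#' the receptor (environment) set.
#'
#' @slot atoms data.frame of per-atom records.
#' @slot bonds integer matrix, two columns, each row one covalent bond
#'   (atom indices, i < j). Empty until [perceiveBonds()] is run.
#' @slot ligand integer vector of mobile-ligand atom indices (one residue).
#' @slot warnings character vector of parse-time warnings.
#' @export
setClass("MolecularSystem",
  representation(atoms = "data.frame", bonds = "matrix",
                 ligand = "integer", warnings = "character"),
  prototype(bonds = matrix(integer(0), ncol = 2L), ligand = integer(0),
            warnings = character(0)))

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  msgs <- character(0)
  need <- c("serial", "name", "resname", "chain", "resseq", "icode",
            "x", "y", "z", "element", "vdw", "covr", "hetero", "molecule")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms lacks columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0L && !all(is.finite(c(a$x, a$y, a$z))))
      msgs <- c(msgs, "non-finite coordinates")
    if (nrow(a) > 0L && any(a$vdw <= 0))
      msgs <- c(msgs, "non-positive vdW radius")
    if (nrow(a) > 0L && any(!nzchar(a$element)))
      msgs <- c(msgs, "empty element symbol")
  }
  if (ncol(object@bonds) != 2L) msgs <- c(msgs, "bonds must have 2 columns")
  if (length(object@ligand) &&
      (min(object@ligand) < 1L || max(object@ligand) > nrow(a)))
    msgs <- c(msgs, "ligand indices out of range")
  if (nrow(object@bonds) > 0L && length(object@ligand)) {
    inL1 <- object@bonds[, 1L] %in% object@ligand
    inL2 <- object@bonds[, 2L] %in% object@ligand
    if (any(inL1 != inL2))
      msgs <- c(msgs, "bond connects ligand to receptor")
  }
  if (length(msgs)) msgs else TRUE
})

#' FlexibilitySpec: which torsions may move
#'
#' Per-residue backbone/side-chain binary flags for the protein, and
#' explicit dihedral definitions (four atoms plus angular bounds) for the
#' mobile ligand's rotatable bonds. This mirrors the `.amc` flexibility
#' file format read and written by [parseAMC()] / [writeAMC()].
#'
#' @slot protein data.frame: restype, chain, resseq, icode, backbone (0/1),
#'   sidechain (0/1); one row per residue.
#' @slot ligandDihedrals data.frame: a1..a4 (atom indices into the system),
#'   lower, upper (radians).
#' @export
setClass("FlexibilitySpec",
  representation(protein = "data.frame", ligandDihedrals = "data.frame"))

setValidity("FlexibilitySpec", function(object) {
  msgs <- character(0)
  p <- object@protein
  if (nrow(p) > 0L) {
    if (!all(p$backbone %in% c(0L, 1L)) || !all(p$sidechain %in% c(0L, 1L)))
      msgs <- c(msgs, "flags must be binary")
    if (any(p$backbone == 1L))
      msgs <- c(msgs, paste("backbone flexibility is not supported:",
                            "only the side-chains can be flexible"))
  }
  d <- object@ligandDihedrals
  if (nrow(d) > 0L && any(d$lower > d$upper))
    msgs <- c(msgs, "dihedral lower bound exceeds upper bound")
  if (length(msgs)) msgs else TRUE
})

#' ArticulatedModel: the kinematic tree
#'
#' Maps degrees of freedom (DOFs) to Cartesian coordinates. Active DOFs are
#' the ligand base pose (translation + unit quaternion, frame at the
#' ligand's input geometric center) and the ligand bond torsions; passive
#' DOFs are the side-chain torsions of flexible residues. All DOF values
#' are offsets from the input geometry, so the zero/identity conformation
#' reproduces the input coordinates exactly.
#'
#' @slot system the [MolecularSystem-class] the model was built from.
#' @slot refCoords n x 3 matrix of input coordinates.
#' @slot ligandTorsions list of torsion descriptors (atoms, axis, distal
#'   set, bounds, reference dihedral, circumradius about the axis).
#' @slot passiveTorsions list of torsion descriptors, each tagged with its
#'   residue key; ordered proximal-first within residues.
#' @slot pieces integer rigid-piece id per atom (connected components of
#'   the bond graph with all torsion edges removed). Pieces containing no
#'   moving atom are mutually static.
#' @slot movingAtoms indices of atoms that any DOF can displace.
#' @slot ligandCenter,receptorCenter geometric centers of the input
#'   ligand / of all non-ligand atoms.
#' @slot ligandCircumradius max distance of a ligand atom from the center.
#' @export
setClass("ArticulatedModel",
  representation(system = "MolecularSystem", refCoords = "matrix",
                 ligandTorsions = "list", passiveTorsions = "list",
                 pieces = "integer", movingAtoms = "integer",
                 ligandCenter = "numeric", receptorCenter = "numeric",
                 ligandCircumradius = "numeric"))

#' Conformation: one value per degree of freedom
#'
#' DOF values are offsets from the model's input geometry: `trans` shifts
#' the ligand base frame, `quat` rotates it about the ligand center,
#' `ligTorsions` and `passive` are torsion offsets in radians. The identity
#' conformation (zero translation, identity quaternion, zero torsions)
#' maps to the input coordinates.
#'
#' @slot trans length-3 numeric, Angstrom.
#' @slot quat length-4 unit quaternion (w, x, y, z).
#' @slot ligTorsions numeric, radians (possibly empty).
#' @slot passive numeric, radians (possibly empty).
#' @export
setClass("Conformation",
  representation(trans = "numeric", quat = "numeric",
                 ligTorsions = "numeric", passive = "numeric"))

setValidity("Conformation", function(object) {
  msgs <- character(0)
  if (length(object@trans) != 3L) msgs <- c(msgs, "trans must be length 3")
  if (length(object@quat) != 4L) msgs <- c(msgs, "quat must be length 4")
  else if (abs(sqrt(sum(object@quat^2)) - 1) > 1e-6)
    msgs <- c(msgs, "quaternion not normalized")
  if (length(msgs)) msgs else TRUE
})

#' CollisionSettings: which atom pairs are ever tested, at what thresholds
#'
#' Precomputed candidate pair list for scaled van der Waals clash testing.
#' Exclusions: directly bonded (1-2) and angle (1-3) pairs, pairs within
#' the same rigid piece, and static-static pairs (their distances never
#' change). 1-4 pairs are checked. The contact threshold used for
#' reporting is `fraction + 0.20` applied to the same radii sums.
#'
#' @slot fraction vdW fraction in (0, 1] used for collision detection.
#' @slot pairs two-column integer matrix of candidate atom pairs.
#' @slot thresholds clash distance threshold per candidate pair (Angstrom).
#' @slot radsum vdW radii sum per candidate pair (Angstrom).
#' @export
setClass("CollisionSettings",
  representation(fraction = "numeric", pairs = "matrix",
                 thresholds = "numeric", radsum = "numeric"))

#' SolutionPath: a discretized unbinding path
#'
#' Root-to-goal conformation sequence returned by the planner, the
#' discretized coordinate frames (max ligand-atom displacement between
#' consecutive frames bounded), and run diagnostics.
#'
#' @slot nodeConfs list of [Conformation-class] (tree nodes, root first).
#' @slot frames list of n x 3 coordinate matrices (discretized; empty until
#'   [discretizePath()] is run).
#' @slot diagnostics named list: success, reason, seed, iterations, nodes
#'   created/exhausted, final center-center distance, exit distance.
#' @export
setClass("SolutionPath",
  representation(nodeConfs = "list", frames = "list",
                 diagnostics = "list"),
  prototype(frames = list(), diagnostics = list()))
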