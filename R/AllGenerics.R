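#' @import methods
NULL

#' Accessors for molecular containers
#'
#' `atoms()` returns the per-atom data.frame; `bonds()` the two-column bond
#' index matrix; `nAtoms()` the atom count; `ligandAtoms()` /
#' `receptorAtoms()` the mobile-ligand / environment index sets;
#' `coords()` the n x 3 coordinate matrix.
#'
#' @param x a [MolecularSystem-class] or [ArticulatedModel-class].
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))
#' @rdname accessors
#' @export
setGeneric("receptorAtoms", function(x) standardGeneric("receptorAtoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' DOF counts of an articulated model
#'
#' `nActiveDOFs()` counts ligand pose (6) plus ligand torsions;
#' `nPassiveDOFs()` counts side-chain torsions.
#'
#' @param x an [ArticulatedModel-class].
#' @return integer count.
#' @export
setGeneric("nActiveDOFs", function(x) standardGeneric("nActiveDOFs"))
#' @rdname nActiveDOFs
#' @export
setGeneric("nPassiveDOFs", function(x) standardGeneric("nPassiveDOFs"))

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularSystem", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "MolecularSystem", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("ligandAtoms", "MolecularSystem", function(x) x@ligand)
#' @rdname accessors
#' @export
setMethod("receptorAtoms", "MolecularSystem",
  function(x) setdiff(seq_len(nrow(x@atoms)), x@ligand))
#' @rdname accessors
#' @export
setMethod("coords", "MolecularSystem",
  function(x) unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname accessors
#' @export
setMethod("atoms", "ArticulatedModel", function(x) x@system@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "ArticulatedModel", function(x) nrow(x@system@atoms))
#' @rdname accessors
#' @export
setMethod("ligandAtoms", "ArticulatedModel", function(x) x@system@ligand)
#' @rdname accessors
#' @export
setMethod("coords", "ArticulatedModel", function(x) x@refCoords)

#' @rdname nActiveDOFs
#' @export
setMethod("nActiveDOFs", "ArticulatedModel",
  function(x) 6L + length(x@ligandTorsions))
#' @rdname nActiveDOFs
#' @export
setMethod("nPassiveDOFs", "ArticulatedModel",
  function(x) length(x@passiveTorsions))

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  cat("MolecularSystem:", nrow(a), "atoms,", nrow(object@bonds), "bonds\n")
  if (nrow(a)) {
    cat("  chains:", paste(unique(a$chain), collapse = " "), "\n")
    if (length(object@ligand)) {
      li <- object@ligand[1L]
      cat("  mobile ligand:", a$resname[li], paste0(a$chain[li], a$resseq[li]),
          "(", length(object@ligand), "atoms )\n")
    } else cat("  mobile ligand: none selected\n")
  }
  invisible(object)
})

setMethod("show", "ArticulatedModel", function(object) {
  cat("ArticulatedModel:", nAtoms(object), "atoms\n")
  cat("  active DOFs :", nActiveDOFs(object),
      "( pose 6 +", length(object@ligandTorsions), "ligand torsions )\n")
  cat("  passive DOFs:", nPassiveDOFs(object), "side-chain torsions in",
      length(unique(vapply(object@passiveTorsions, `[[`, "", "residue"))),
      "residues\n")
  invisible(object)
})

setMethod("show", "Conformation", function(object) {
  cat("Conformation: |t| =", round(sqrt(sum(object@trans^2)), 3),
      "A, rot =", round(quatAngle(object@quat, quatIdentity()) * 180 / pi, 1),
      "deg,", length(object@ligTorsions), "ligand +",
      length(object@passive), "passive torsions\n")
  invisible(object)
})

setMethod("show", "SolutionPath", function(object) {
  d <- object@diagnostics
  cat("SolutionPath:", length(object@nodeConfs), "nodes,",
      length(object@frames), "frames\n")
  if (length(d)) {
    cat("  success:", isTRUE(d$success))
    if (!is.null(d$finalDistance))
      cat(", final center distance", round(d$finalDistance, 2), "A")
    cat("\n")
  }
  invisible(object)
})

setMethod("show", "FlexibilitySpec", function(object) {
  cat("FlexibilitySpec:", nrow(object@protein), "protein residues (",
      sum(object@protein$sidechain == 1L), "side-chain flexible ),",
      nrow(object@ligandDihedrals), "ligand dihedrals\n")
  invisible(object)
})
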