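## Articulated model construction and forward kinematics. DOF values are
## offsets from the input geometry: the identity conformation maps to the
## input coordinates. Torsions rotate their distal atom set about the bond
## axis (proximal -> distal direction, right-handed), applied
## proximal-first so nested axes are already in place.

backboneHeavyNames <- c("N", "CA", "C", "O", "OXT")

## enumerate side-chain torsions of one flexible residue; returns a list
## of descriptors (atoms a/b/c/d, distal set, circumradius, residue key)
sideChainTorsions <- function(system, chain, resseq, icode, nb, acyc) {
  a <- system@atoms
  res <- which(a$chain == chain & a$resseq == resseq & a$icode == icode &
                 !a$hetero)
  if (!length(res)) return(list())
  heavy <- a$element != "H"
  bnd <- system@bonds
  inRes <- bnd[, 1L] %in% res & bnd[, 2L] %in% res
  banned <- a$name %in% setdiff(backboneHeavyNames, "CA")
  cand <- which(inRes & acyc & heavy[bnd[, 1L]] & heavy[bnd[, 2L]] &
                  !banned[bnd[, 1L]] & !banned[bnd[, 2L]] &
                  lengths(nb)[bnd[, 1L]] >= 2L & lengths(nb)[bnd[, 2L]] >= 2L)
  caIdx <- res[a$name[res] == "CA"][1L]
  if (is.na(caIdx)) return(list())
  out <- list()
  for (k in cand) {
    b <- bnd[k, 1L]; cc <- bnd[k, 2L]
    dist <- distalSet(system, b, cc)
    if (caIdx %in% dist) {      # proximal side must contain CA
      tmp <- b; b <- cc; cc <- tmp
      dist <- distalSet(system, b, cc)
    }
    if (any(a$name[dist] %in% backboneHeavyNames)) next  # safety
    aA <- setdiff(nb[[b]], cc)
    if (b == caIdx) {
      nIdx <- aA[a$name[aA] == "N"]
      aA <- if (length(nIdx)) nIdx[1L] else aA[1L]
    } else aA <- aA[1L]
    dA <- setdiff(nb[[cc]], b)[1L]
    if (is.na(aA) || is.na(dA)) next
    out[[length(out) + 1L]] <- list(
      atoms = c(aA, b, cc, dA), axis = c(b, cc), distal = dist,
      residue = resKeyOf(chain, resseq, icode))
  }
  out
}

torsionCircumradius <- function(xyz, tor) {
  b <- xyz[tor$axis[1L], ]; cc <- xyz[tor$axis[2L], ]
  u <- cc - b; u <- u / sqrt(sum(u^2))
  p <- sweep(xyz[tor$distal, , drop = FALSE], 2L, b)
  par <- p %*% u
  perp2 <- rowSums(p^2) - par^2
  sqrt(max(0, max(perp2)))
}

#' Build the articulated kinematic model
#'
#' Active DOFs: ligand base pose (translation + orientation about the
#' ligand's input geometric center) and the spec's ligand dihedrals.
#' Passive DOFs: the side-chain torsions (acyclic heavy-atom bonds from CA
#' outward whose endpoints both have >= 2 heavy neighbors) of every
#' residue whose side-chain flag is 1. Residues with no such bonds (Gly,
#' Ala, Pro) contribute nothing.
#'
#' @param system a [MolecularSystem-class] with bonds perceived and a
#'   mobile ligand selected.
#' @param spec a [FlexibilitySpec-class]; defaults to
#'   [defaultFlexibilitySpec()] of the system.
#' @return an [ArticulatedModel-class].
#' @export
buildArticulatedModel <- function(system, spec = defaultFlexibilitySpec(system)) {
  if (!length(system@ligand))
    stop("model error: no mobile ligand selected")
  a <- system@atoms
  xyz <- coords(system)
  lig <- system@ligand
  nb <- heavyNeighborList(system)
  acyc <- acyclicBonds(system)

  # ligand torsions from the spec's dihedral lines
  rb <- rotatableLigandBonds(system)
  rbKey <- paste(rb[, 1L], rb[, 2L])
  d <- spec@ligandDihedrals
  ligTor <- list()
  for (k in seq_len(nrow(d))) {
    b <- d$a2[k]; cc <- d$a3[k]
    if (!(paste(min(b, cc), max(b, cc)) %in% rbKey))
      stop("model error: ligand dihedral middle bond ", a$serial[b], "-",
           a$serial[cc], " lies in a ring or is not rotatable")
    dist <- distalSet(system, b, cc)
    ligTor[[length(ligTor) + 1L]] <- list(
      atoms = c(d$a1[k], b, cc, d$a4[k]), axis = c(b, cc),
      distal = dist, lower = d$lower[k], upper = d$upper[k],
      ref = measureDihedral(xyz[d$a1[k], ], xyz[b, ], xyz[cc, ],
                            xyz[d$a4[k], ]))
  }
  # passive torsions for flexible residues
  p <- spec@protein
  pasTor <- list()
  for (r in which(p$sidechain == 1L)) {
    pasTor <- c(pasTor, sideChainTorsions(system, p$chain[r], p$resseq[r],
                                          p$icode[r], nb, acyc))
  }
  # proximal-first: nested torsions have strictly smaller distal sets
  ordBy <- function(lst) lst[order(-vapply(lst, function(t) length(t$distal),
                                           0L))]
  ligTor <- ordBy(ligTor)
  pasTor <- ordBy(pasTor)
  for (k in seq_along(ligTor))
    ligTor[[k]]$circumradius <- torsionCircumradius(xyz, ligTor[[k]])
  for (k in seq_along(pasTor)) {
    pasTor[[k]]$circumradius <- torsionCircumradius(xyz, pasTor[[k]])
    pasTor[[k]]$ref <- measureDihedral(
      xyz[pasTor[[k]]$atoms[1L], ], xyz[pasTor[[k]]$atoms[2L], ],
      xyz[pasTor[[k]]$atoms[3L], ], xyz[pasTor[[k]]$atoms[4L], ])
  }

  # rigid pieces: bond graph minus torsion edges; merge static pieces as 0
  g <- bondGraph(system)
  torAxes <- do.call(rbind, c(lapply(ligTor, `[[`, "axis"),
                              lapply(pasTor, `[[`, "axis"),
                              list(matrix(integer(0), ncol = 2L))))
  if (nrow(torAxes)) {
    eids <- igraph::get_edge_ids(g, t(torAxes))
    g <- igraph::delete_edges(g, eids[eids > 0])
  }
  pieces <- as.integer(igraph::components(g)$membership)
  moving <- sort(unique(c(lig, unlist(lapply(pasTor, `[[`, "distal")))))

  ligCenter <- colMeans(xyz[lig, , drop = FALSE])
  recIdx <- setdiff(seq_len(nrow(a)), lig)
  recCenter <- colMeans(xyz[recIdx, , drop = FALSE])
  circ <- sqrt(max(rowSums(sweep(xyz[lig, , drop = FALSE], 2L,
                                 ligCenter)^2)))
  new("ArticulatedModel", system = system, refCoords = xyz,
      ligandTorsions = ligTor, passiveTorsions = pasTor,
      pieces = pieces, movingAtoms = as.integer(moving),
      ligandCenter = ligCenter, receptorCenter = recCenter,
      ligandCircumradius = circ)
}

#' Construct a conformation
#'
#' @param model an [ArticulatedModel-class].
#' @param trans length-3 translation of the ligand base frame (Angstrom).
#' @param quat unit quaternion (w, x, y, z) rotating the ligand about its
#'   input geometric center.
#' @param ligTorsions,passive torsion offsets (radians); default zero.
#' @return a [Conformation-class]. `identityConformation(model)` is the
#'   all-zero conformation that reproduces the input coordinates.
#' @export
newConformation <- function(model, trans = c(0, 0, 0),
                            quat = quatIdentity(),
                            ligTorsions = numeric(length(model@ligandTorsions)),
                            passive = numeric(length(model@passiveTorsions))) {
  stopifnot(length(ligTorsions) == length(model@ligandTorsions),
            length(passive) == length(model@passiveTorsions))
  new("Conformation", trans = as.numeric(trans),
      quat = quatNormalize(as.numeric(quat)),
      ligTorsions = as.numeric(ligTorsions), passive = as.numeric(passive))
}

#' @rdname newConformation
#' @export
identityConformation <- function(model) newConformation(model)

#' Map a conformation to Cartesian coordinates
#'
#' Static atoms are returned unchanged from the input; side-chain distal
#' sets are rotated about their bond axes by the passive values
#' (proximal-first); ligand torsions are applied to the input ligand
#' geometry, then the base pose (rotation about the input ligand center,
#' then translation). Bond lengths and angles within every rigid group are
#' preserved exactly (rigid rotations only).
#'
#' @param model an [ArticulatedModel-class].
#' @param conf a [Conformation-class].
#' @return n x 3 coordinate matrix.
#' @export
forwardKinematics <- function(model, conf) {
  X <- model@refCoords
  # rotating the distal set right-handed about the proximal->distal axis
  # by v makes the measured IUPAC dihedral come out as (input + v)
  for (k in seq_along(model@passiveTorsions)) {
    v <- conf@passive[k]
    if (v == 0) next
    tor <- model@passiveTorsions[[k]]
    X[tor$distal, ] <- rotateAboutAxis(
      X[tor$distal, , drop = FALSE], X[tor$axis[1L], ],
      X[tor$axis[2L], ] - X[tor$axis[1L], ], v)
  }
  for (k in seq_along(model@ligandTorsions)) {
    v <- conf@ligTorsions[k]
    if (v == 0) next
    tor <- model@ligandTorsions[[k]]
    X[tor$distal, ] <- rotateAboutAxis(
      X[tor$distal, , drop = FALSE], X[tor$axis[1L], ],
      X[tor$axis[2L], ] - X[tor$axis[1L], ], v)
  }
  lig <- model@system@ligand
  R <- quatRotationMatrix(conf@quat)
  Xl <- sweep(X[lig, , drop = FALSE], 2L, model@ligandCenter)
  Xl <- Xl %*% t(R)
  X[lig, ] <- sweep(Xl, 2L, model@ligandCenter + conf@trans, "+")
  X
}

## current ligand geometric center under a conformation (no full FK needed:
## torsions move atoms but the base frame tracks the rotated center)
ligandCenterOf <- function(model, conf) {
  lig <- model@system@ligand
  X <- forwardKinematics(model, conf)
  colMeans(X[lig, , drop = FALSE])
}

fullCircle <- function(lower, upper) (upper - lower) >= 2 * pi - 1e-9

## per-torsion signed difference b - a (wrapped on full-circle bounds)
torsionDiff <- function(av, bv, lowers, uppers) {
  if (!length(av)) return(numeric(0))
  d <- bv - av
  fc <- fullCircle(lowers, uppers)
  d[fc] <- wrapAngle(d[fc])
  d
}

ligTorBounds <- function(model) {
  list(lower = vapply(model@ligandTorsions, `[[`, 0, "lower"),
       upper = vapply(model@ligandTorsions, `[[`, 0, "upper"))
}

#' Interpolate between two conformations
#'
#' Translation linear; orientation spherical-linear along the shorter arc
#' (antipodal quaternion representatives are sign-flipped); torsions along
#' the shorter angular arc for full-circle bounds, linearly (hence within
#' bounds) otherwise. `t = 0` gives `a`, `t = 1` gives `b`.
#'
#' @param model the common [ArticulatedModel-class].
#' @param a,b [Conformation-class] endpoints.
#' @param t fraction in `[0, 1]`.
#' @return a [Conformation-class].
#' @export
interpolateConformations <- function(model, a, b, t) {
  lb <- ligTorBounds(model)
  dl <- torsionDiff(a@ligTorsions, b@ligTorsions, lb$lower, lb$upper)
  dp <- torsionDiff(a@passive, b@passive,
                    rep(-pi, length(a@passive)), rep(pi, length(a@passive)))
  ligv <- a@ligTorsions + t * dl
  fc <- fullCircle(lb$lower, lb$upper)
  ligv[fc] <- wrapAngle(ligv[fc])
  new("Conformation",
      trans = a@trans + t * (b@trans - a@trans),
      quat = quatSlerp(a@quat, b@quat, t),
      ligTorsions = ligv,
      passive = wrapAngle(a@passive + t * dp))
}

#' Uniform edge subdivision at the ligand displacement resolution
#'
#' Splits the straight-line motion from `a` to `b` into uniform
#' parameter steps, refining until the true maximum ligand-atom
#' displacement between consecutive points is at most `maxDisp`. The
#' same rule drives both the planner's collision validation of tree
#' edges and the output discretization, so every written frame is a
#' collision-checked conformation.
#'
#' @inheritParams interpolateConformations
#' @param maxDisp per-step ligand displacement bound (Angstrom).
#' @return list of conformations at the interior points and the
#'   endpoint `b` (excluding `a`).
#' @export
subdivideEdge <- function(model, a, b, maxDisp = 0.5) {
  d <- maxLigandDisplacement(model, a, b)
  if (d <= maxDisp) return(list(b))
  n <- max(2L, ceiling(d / maxDisp))
  repeat {
    pts <- lapply(seq_len(n), function(k)
      interpolateConformations(model, a, b, k / n))
    steps <- vapply(seq_len(n), function(k)
      maxLigandDisplacement(model, if (k == 1L) a else pts[[k - 1L]],
                            pts[[k]]), 0)
    if (all(steps <= maxDisp)) return(pts)
    n <- n + max(1L, ceiling(n * 0.2))
  }
}

#' Maximum ligand-atom displacement between two conformations
#'
#' True Cartesian displacement (via forward kinematics), maximized over
#' the ligand atoms.
#'
#' @inheritParams interpolateConformations
#' @return displacement in Angstrom.
#' @export
maxLigandDisplacement <- function(model, a, b) {
  lig <- model@system@ligand
  Xa <- forwardKinematics(model, a)[lig, , drop = FALSE]
  Xb <- forwardKinematics(model, b)[lig, , drop = FALSE]
  sqrt(max(rowSums((Xa - Xb)^2)))
}

## upper bound on max ligand-atom displacement between two conformations,
## from the active-space metric (used for step-size capping)
activeDisplacementBound <- function(model, a, b) {
  lb <- ligTorBounds(model)
  dl <- abs(torsionDiff(a@ligTorsions, b@ligTorsions, lb$lower, lb$upper))
  circ <- vapply(model@ligandTorsions, `[[`, 0, "circumradius")
  sqrt(sum((b@trans - a@trans)^2)) +
    quatAngle(a@quat, b@quat) * model@ligandCircumradius +
    sum(dl * circ)
}
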