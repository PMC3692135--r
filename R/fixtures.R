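## Synthetic test systems with known geometric properties: a cylindrical
## channel of carbon pseudo-atoms (optionally gated by a movable
## pseudo-side-chain arm) and a trivial free-ligand system. Everything is
## constructed deterministically so analytic clearances are exact.
##
## Geometry notes (75% vdW, carbon radii 1.70 -> pair threshold 2.55 A):
##  - wall atoms sit on rings of the channel radius, ring spacing 3.5 A,
##    staggered half a step between rings: the worst lattice hole is
##    ~2.3 A from its four neighbors, i.e. covered, and the blocked chord
##    through any hole exceeds 1.2 A, so a 0.5 A-resolution edge check
##    cannot tunnel through the cage;
##  - 3.5 A spacing also exceeds the covalent bond threshold (1.97 A for
##    C-C), so no bonds are perceived between cage atoms;
##  - the gate arm (residue GAT: static N/CA/C/O anchor, movable CB-CG-CD
##    chain) rests with its tip CD near the channel axis, sealing the
##    corridor; rotating the CA-CB torsion by ~1 rad swings the arm tip
##    up and out of the corridor. Two wall atoms overlapping the anchor
##    are removed; both removed positions stay within the clash radius of
##    the anchor atoms, so the holes remain plugged in every conformation.

pdbAtomLine <- function(record, serial, name, resname, chain, resseq,
                        x, y, z, element) {
  nm <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, " ", resname, chain, resseq, " ",
          x, y, z, 1, 0, element)
}

channelWallCoords <- function(innerRadius, length, spacing) {
  zs <- seq(0, length, by = spacing)
  nPer <- max(3L, ceiling(2 * pi * innerRadius / spacing))
  out <- NULL
  for (k in seq_along(zs)) {
    off <- if (k %% 2L == 0L) pi / nPer else 0   # stagger alternate rings
    th <- off + 2 * pi * (seq_len(nPer) - 1L) / nPer
    out <- rbind(out, cbind(innerRadius * cos(th), innerRadius * sin(th),
                            zs[k]))
  }
  rbind(out, c(0, 0, 0))                         # closed-end cap atom
}

gateCoords <- function(zg, tipRho, scale = 1) {
  tipDir <- c(0.5, 0.866)
  g <- rbind(
    N  = c(3.70, -0.55, zg + 1.05),
    CA = c(2.90,  0.00, zg),
    C  = c(3.50, -0.90, zg - 1.00),
    O  = c(4.00, -1.85, zg - 1.50),
    CB = c(2.45,  1.25, zg),
    CG = c(1.05,  0.85, zg),
    CD = c(tipRho * tipDir[1L], tipRho * tipDir[2L], zg))
  g[, 1:2] <- g[, 1:2] * scale
  g
}

#' Synthetic channel fixture
#'
#' A cylindrical cage of carbon pseudo-atoms (chain Z, one residue per
#' atom) with an axial channel closed at the bottom, a mobile ligand
#' (HETATM residue LIG) placed at the closed end, and optionally a gate: a
#' pseudo-side-chain arm (residue GAT) whose tip occludes the channel and
#' whose CA-CB torsion can swing it open. The analytic corridor clearance
#' is `innerRadius - (ligand radial extent + vdwFraction * (r_lig +
#' r_wall))`: positive means the corridor admits the ligand without any
#' side-chain motion.
#'
#' @param innerRadius channel (wall ring) radius, Angstrom.
#' @param length channel length, Angstrom.
#' @param spacing wall atom spacing, Angstrom (also the ring spacing).
#' @param ligand `"single"` (one carbon), `"ring"` (rigid 5-ring) or
#'   `"chain"` (4 carbons, one torsional DOF).
#' @param gate add the gate arm.
#' @param gateFlexible gate side-chain flag in the `.amc` (`FALSE` freezes
#'   the arm, making the gated channel geometrically impassable).
#' @param gateTipRho distance of the resting arm tip from the channel
#'   axis, Angstrom.
#' @param scale multiplies the channel radius and all gate x/y
#'   coordinates (values below 1 narrow the whole construction).
#' @param vdwFraction fraction used for the reported clearances.
#' @return list: `pdb` and `amc` text lines, the parsed `system` (bonds
#'   perceived, ligand selected), the `spec`, `clearance` (analytic),
#'   `bruteClearance` (sampled axial probe vs the cage), `gateClearance`
#'   (best crossing-point margin at the gate plane; `NA` without a gate),
#'   and `params`.
#' @export
makeChannelFixture <- function(innerRadius = 4.0, length = 14.0,
                               spacing = 3.5,
                               ligand = c("single", "chain", "ring"),
                               gate = FALSE, gateFlexible = TRUE,
                               gateTipRho = 0.695, scale = 1,
                               vdwFraction = 0.75) {
  ligand <- match.arg(ligand)
  R <- innerRadius * scale
  rC <- 1.70
  thr <- vdwFraction * (rC + rC)
  if (length <= 7) stop("parameter error: channel length too short")
  if (R <= 0) stop("parameter error: non-positive channel radius")

  wall <- channelWallCoords(R, length, spacing)
  zg <- length - spacing                     # gate ring plane
  gateXYZ <- if (gate) gateCoords(zg, gateTipRho, scale) else NULL
  if (gate) {
    # drop wall atoms within the scaled-vdW clash range (plus a small
    # margin) of any gate atom at rest; holes must stay plugged by the
    # anchor atoms, which never move
    gateR <- vdwRadius(substr(rownames(gateXYZ), 1L, 1L))
    keep <- apply(wall, 1L, function(w) {
      d <- sqrt(rowSums(sweep(gateXYZ, 2L, w)^2))
      all(d > vdwFraction * (gateR + rC) + 0.04)
    })
    removed <- wall[!keep, , drop = FALSE]
    wall <- wall[keep, , drop = FALSE]
    anchor <- gateXYZ[c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    for (k in seq_len(nrow(removed))) {
      plug <- min(sqrt(rowSums(sweep(anchor, 2L, removed[k, ])^2)))
      if (plug > 2.45)
        stop("parameter error: gate geometry opens an unplugged wall hole")
    }
  }

  ligXYZ <- switch(ligand,
    single = matrix(c(0, 0, 3.3), 1L),
    chain = cbind(0, c(0.6, -0.3, 0.6, -0.3), c(3.0, 4.2, 5.4, 6.6)),
    ring = {
      th <- 2 * pi * (0:4) / 5
      cbind(1.2 * cos(th), 1.2 * sin(th), 3.3)
    })
  ligExtent <- max(sqrt(ligXYZ[, 1L]^2 + ligXYZ[, 2L]^2))

  lines <- character(0)
  s <- 0L
  for (k in seq_len(nrow(wall))) {
    s <- s + 1L
    lines <- c(lines, pdbAtomLine("ATOM", s, "C", "WAL", "Z", k,
                                  wall[k, 1L], wall[k, 2L], wall[k, 3L], "C"))
  }
  if (gate) {
    gres <- nrow(wall) + 1L
    for (nm in rownames(gateXYZ)) {
      s <- s + 1L
      el <- substr(nm, 1L, 1L)
      lines <- c(lines, pdbAtomLine("ATOM", s, nm, "GAT", "Z", gres,
                                    gateXYZ[nm, 1L], gateXYZ[nm, 2L],
                                    gateXYZ[nm, 3L], el))
    }
  }
  for (k in seq_len(nrow(ligXYZ))) {
    s <- s + 1L
    lines <- c(lines, pdbAtomLine("HETATM", s, paste0("C", k), "LIG", "L", 1L,
                                  ligXYZ[k, 1L], ligXYZ[k, 2L], ligXYZ[k, 3L],
                                  "C"))
  }
  lines <- c(lines, "END")

  sys <- perceiveBonds(parsePDB(lines, ligandSelector = "LIG"))
  spec <- defaultFlexibilitySpec(sys)
  if (gate && !gateFlexible) {
    row <- which(spec@protein$restype == "GAT")
    spec@protein$sidechain[row] <- 0L
  }
  amc <- writeAMC(spec, sys)

  clearance <- R - (ligExtent + thr)
  probeZ <- seq(3, length - 0.5, by = 0.25)
  cage <- wall[wall[, 3L] > 1e-9 | wall[, 1L]^2 + wall[, 2L]^2 > 1e-9, ,
               drop = FALSE]               # rings only, not the cap
  bruteClearance <- min(vapply(probeZ, function(z)
    min(sqrt(cage[, 1L]^2 + cage[, 2L]^2 + (cage[, 3L] - z)^2)), 0)) - thr
  gateClearance <- NA_real_
  if (gate) {
    env <- rbind(wall, gateXYZ)
    qr <- seq(0, R - thr + 0.4, by = 0.1)
    qth <- seq(0, 2 * pi, by = 0.1)
    qs <- cbind(as.vector(outer(qr, cos(qth))), as.vector(outer(qr, sin(qth))))
    margins <- vapply(seq_len(nrow(qs)), function(k)
      min(sqrt((env[, 1L] - qs[k, 1L])^2 + (env[, 2L] - qs[k, 2L])^2 +
                 (env[, 3L] - zg)^2)) - thr, 0)
    gateClearance <- max(margins)
  }

  list(pdb = lines, amc = amc, system = sys, spec = spec,
       clearance = clearance, bruteClearance = bruteClearance,
       gateClearance = gateClearance,
       params = list(innerRadius = innerRadius, length = length,
                     spacing = spacing, ligand = ligand, gate = gate,
                     gateFlexible = gateFlexible, gateTipRho = gateTipRho,
                     scale = scale, vdwFraction = vdwFraction))
}

#' Free-ligand fixture
#'
#' A rigid three-atom ligand 25 Angstrom away from a ten-atom receptor
#' blob: trivially solvable (the start already satisfies the automatic
#' exit distance), with zero passive DOFs, so the planner degenerates to
#' plain RRT.
#'
#' @return list as [makeChannelFixture()] (without clearances).
#' @export
makeFreeLigandFixture <- function() {
  blob <- rbind(expand.grid(x = c(0, 3, 6), y = c(0, 3, 6))[1:9, ],
                data.frame(x = 3, y = 3))
  blob$z <- c(rep(0, 9L), 3)
  lines <- character(0)
  for (k in seq_len(10L))
    lines <- c(lines, pdbAtomLine("ATOM", k, "C", "BLB", "Z", k,
                                  blob$x[k], blob$y[k], blob$z[k], "C"))
  ligz <- c(0, 1.5, 3.0)
  for (k in 1:3)
    lines <- c(lines, pdbAtomLine("HETATM", 10L + k, paste0("C", k), "LIG",
                                  "L", 1L, 25 + ligz[k], 0, 0, "C"))
  lines <- c(lines, "END")
  sys <- perceiveBonds(parsePDB(lines, ligandSelector = "LIG"))
  spec <- defaultFlexibilitySpec(sys)
  list(pdb = lines, amc = writeAMC(spec, sys), system = sys, spec = spec)
}
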