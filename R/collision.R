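## Scaled van der Waals clash detection (feasibility) and ligand contact
## identification (reporting). A pair (i, j) clashes iff
## |xi - xj| < fraction * (ri + rj). Exclusions for feasibility: 1-2 and
## 1-3 bonded paths, pairs within the same rigid piece, and static-static
## pairs (whose distances can never change). 1-4 pairs are checked by
## default. Contacts use threshold (fraction + 0.20) * (ri + rj) and only
## ligand-vs-environment pairs.

pairKey <- function(i, j, n) pmin(i, j) * (n + 1) + pmax(i, j)

## keys of 1-2, 1-3 (and optionally 1-4) bonded pairs
bondedPairKeys <- function(system, upTo = 3L) {
  b <- system@bonds
  n <- nAtoms(system)
  if (!nrow(b)) return(numeric(0))
  keys <- pairKey(b[, 1L], b[, 2L], n)
  nb <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nb[[b[k, 1L]]] <- c(nb[[b[k, 1L]]], b[k, 2L])
    nb[[b[k, 2L]]] <- c(nb[[b[k, 2L]]], b[k, 1L])
  }
  for (k in seq_len(n)) {               # 1-3: pairs of neighbors of k
    v <- nb[[k]]
    if (length(v) >= 2L) {
      pr <- utils::combn(v, 2L)
      keys <- c(keys, pairKey(pr[1L, ], pr[2L, ], n))
    }
  }
  if (upTo >= 4L) {                     # 1-4: across each bond
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1L]; j <- b[k, 2L]
      vi <- setdiff(nb[[i]], j); vj <- setdiff(nb[[j]], i)
      if (length(vi) && length(vj)) {
        g <- expand.grid(vi, vj)
        keep <- g[, 1L] != g[, 2L]
        keys <- c(keys, pairKey(g[keep, 1L], g[keep, 2L], n))
      }
    }
  }
  unique(keys)
}

#' Build collision settings for an articulated model
#'
#' Precomputes the candidate atom-pair list (every pair whose distance can
#' change and that is not excluded) with per-pair clash thresholds.
#'
#' @param model an [ArticulatedModel-class].
#' @param vdwFraction fraction of the van der Waals radii sum used as the
#'   clash threshold, in (0, 1]. 0.75 is the standard default.
#' @param check14 check 1-4 bonded pairs (default) or exclude them too.
#' @return a [CollisionSettings-class].
#' @export
collisionSettings <- function(model, vdwFraction = 0.75, check14 = TRUE) {
  stopifnot(vdwFraction > 0, vdwFraction <= 1)
  sys <- model@system
  n <- nAtoms(sys)
  moving <- model@movingAtoms
  radii <- sys@atoms$vdw
  isMoving <- logical(n); isMoving[moving] <- TRUE
  # candidate pairs: at least one moving atom, deduplicated
  pi_ <- integer(0); pj <- integer(0)
  all_ <- seq_len(n)
  for (i in moving) {
    j <- all_[all_ > i | !isMoving[all_]]
    j <- j[j != i]
    pi_ <- c(pi_, rep.int(i, length(j))); pj <- c(pj, j)
  }
  lo <- pmin(pi_, pj); hi <- pmax(pi_, pj)
  keep <- !duplicated(pairKey(lo, hi, n))
  lo <- lo[keep]; hi <- hi[keep]
  # exclusions
  samePiece <- model@pieces[lo] == model@pieces[hi]
  excl <- bondedPairKeys(sys, upTo = if (check14) 3L else 4L)
  bonded <- pairKey(lo, hi, n) %in% excl
  keep <- !samePiece & !bonded
  lo <- lo[keep]; hi <- hi[keep]
  rs <- radii[lo] + radii[hi]
  new("CollisionSettings", fraction = vdwFraction,
      pairs = cbind(lo, hi), thresholds = vdwFraction * rs, radsum = rs)
}

#' Collision settings over an explicit pair list
#'
#' Low-level constructor used for unstructured atom sets (no exclusions
#' unless given): all pairs, or the supplied pairs, are candidates.
#'
#' @param radii per-atom vdW radii.
#' @param vdwFraction clash threshold fraction.
#' @param pairs optional two-column index matrix; default all i < j pairs.
#' @return a [CollisionSettings-class].
#' @export
pairCollisionSettings <- function(radii, vdwFraction = 0.75, pairs = NULL) {
  n <- length(radii)
  if (is.null(pairs)) {
    pr <- utils::combn(n, 2L)
    pairs <- cbind(pr[1L, ], pr[2L, ])
  }
  rs <- radii[pairs[, 1L]] + radii[pairs[, 2L]]
  new("CollisionSettings", fraction = vdwFraction, pairs = pairs,
      thresholds = vdwFraction * rs, radsum = rs)
}

setMethod("show", "CollisionSettings", function(object) {
  cat("CollisionSettings:", nrow(object@pairs), "candidate pairs at",
      object@fraction * 100, "% vdW\n")
  invisible(object)
})

#' Detect scaled van der Waals clashes
#'
#' Reports every candidate pair whose distance is below
#' `fraction * (ri + rj)`.
#'
#' @param coordinates n x 3 coordinate matrix.
#' @param settings a [CollisionSettings-class].
#' @return data.frame with columns `i`, `j` (atom indices), `distance`,
#'   `threshold`; zero rows when the conformation is clash-free.
#' @export
detectClashes <- function(coordinates, settings) {
  p <- settings@pairs
  if (!nrow(p))
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), threshold = numeric(0)))
  d2 <- (coordinates[p[, 1L], 1L] - coordinates[p[, 2L], 1L])^2 +
    (coordinates[p[, 1L], 2L] - coordinates[p[, 2L], 2L])^2 +
    (coordinates[p[, 1L], 3L] - coordinates[p[, 2L], 3L])^2
  hit <- d2 < settings@thresholds^2
  data.frame(i = p[hit, 1L], j = p[hit, 2L],
             distance = sqrt(d2[hit]), threshold = settings@thresholds[hit])
}

## fast boolean: any candidate pair clashing?
anyClash <- function(coordinates, settings) {
  p <- settings@pairs
  if (!nrow(p)) return(FALSE)
  d2 <- (coordinates[p[, 1L], 1L] - coordinates[p[, 2L], 1L])^2 +
    (coordinates[p[, 1L], 2L] - coordinates[p[, 2L], 2L])^2 +
    (coordinates[p[, 1L], 3L] - coordinates[p[, 2L], 3L])^2
  any(d2 < settings@thresholds^2)
}

#' Detect ligand-environment contacts
#'
#' A contact is an overlap at radii enlarged by 20 percentage points over
#' the collision scale: threshold `(vdwFraction + 0.20) * (ri + rj)`.
#' With the standard 75% collision scale, contacts are identified at 95%
#' of the van der Waals radii. Only ligand-vs-environment pairs are
#' considered.
#'
#' @param coordinates n x 3 coordinate matrix.
#' @param radii per-atom vdW radii (Angstrom).
#' @param ligandSet integer indices of the mobile-ligand atoms.
#' @param vdwFraction the collision fraction (contact fraction is this
#'   plus 0.20).
#' @return data.frame with columns `i` (ligand atom), `j` (environment
#'   atom), `distance`, `threshold`.
#' @export
detectContacts <- function(coordinates, radii, ligandSet, vdwFraction = 0.75) {
  n <- length(radii)
  env <- setdiff(seq_len(n), ligandSet)
  if (!length(ligandSet) || !length(env))
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), threshold = numeric(0)))
  g <- expand.grid(i = as.integer(ligandSet), j = as.integer(env))
  frac <- vdwFraction + 0.20
  thr <- frac * (radii[g$i] + radii[g$j])
  d2 <- (coordinates[g$i, 1L] - coordinates[g$j, 1L])^2 +
    (coordinates[g$i, 2L] - coordinates[g$j, 2L])^2 +
    (coordinates[g$i, 3L] - coordinates[g$j, 3L])^2
  hit <- d2 < thr^2
  out <- data.frame(i = g$i[hit], j = g$j[hit],
                    distance = sqrt(d2[hit]), threshold = thr[hit])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Overlaps among static atoms of a model
#'
#' Scans atom pairs that no degree of freedom can separate (both atoms
#' outside the moving set, different rigid pieces, not 1-2/1-3 bonded).
#' Such overlaps in the input structure cannot be resolved by side-chain
#' perturbation and abort preprocessing.
#'
#' @param model an [ArticulatedModel-class].
#' @param vdwFraction clash threshold fraction.
#' @return data.frame as [detectClashes()].
#' @export
staticOverlaps <- function(model, vdwFraction = 0.75) {
  sys <- model@system
  n <- nAtoms(sys)
  static <- setdiff(seq_len(n), model@movingAtoms)
  if (length(static) < 2L)
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), threshold = numeric(0)))
  pr <- utils::combn(static, 2L)
  lo <- pr[1L, ]; hi <- pr[2L, ]
  keep <- model@pieces[lo] != model@pieces[hi]
  excl <- bondedPairKeys(sys, upTo = 3L)
  keep <- keep & !(pairKey(lo, hi, n) %in% excl)
  st <- pairCollisionSettings(sys@atoms$vdw, vdwFraction,
                              cbind(lo[keep], hi[keep]))
  detectClashes(coords(sys), st)
}
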