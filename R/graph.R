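## Bond-graph utilities: ring perception (bridge detection), heavy-atom
## neighbor counts, distal sets, rotatable-bond enumeration.

bondGraph <- function(system) {
  g <- igraph::make_empty_graph(n = nAtoms(system), directed = FALSE)
  if (nrow(system@bonds)) g <- igraph::add_edges(g, t(system@bonds))
  g
}

## logical, one per bond row: TRUE iff the bond is acyclic (a bridge)
acyclicBonds <- function(system) {
  if (nrow(system@bonds) == 0L) return(logical(0))
  g <- bondGraph(system)
  br <- igraph::bridges(g)
  out <- rep(FALSE, nrow(system@bonds))
  out[as.integer(br)] <- TRUE
  out
}

## neighbor index list restricted to heavy (non-H) atoms
heavyNeighborList <- function(system) {
  n <- nAtoms(system)
  nb <- vector("list", n)
  b <- system@bonds
  heavy <- system@atoms$element != "H"
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1L]; j <- b[k, 2L]
    if (heavy[j]) nb[[i]] <- c(nb[[i]], j)
    if (heavy[i]) nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

## atoms on the far side of bond (b, c): the connected component that
## contains c once the edge is removed (the bond must be a bridge)
distalSet <- function(system, bAtom, cAtom) {
  g <- bondGraph(system)
  eid <- igraph::get_edge_ids(g, c(bAtom, cAtom))
  if (eid == 0L) stop("no bond between atoms ", bAtom, " and ", cAtom)
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)$membership
  which(comp == comp[cAtom])
}

#' Rotatable bonds of the mobile ligand
#'
#' A ligand bond is a torsional degree of freedom iff it is acyclic (not in
#' a ring), both atoms are heavy, and both endpoints have at least two
#' heavy-atom neighbors (terminal -OH/-NH3/-CH3 spins move no heavy atom
#' when hydrogens are absent).
#'
#' @param system a [MolecularSystem-class] with bonds perceived and a
#'   mobile ligand selected.
#' @return two-column integer matrix of bonded atom index pairs.
#' @export
rotatableLigandBonds <- function(system) {
  lig <- system@ligand
  b <- system@bonds
  if (!length(lig) || nrow(b) == 0L)
    return(matrix(integer(0), ncol = 2L))
  heavy <- system@atoms$element != "H"
  nb <- heavyNeighborList(system)
  deg <- lengths(nb)
  acyc <- acyclicBonds(system)
  keep <- b[, 1L] %in% lig & b[, 2L] %in% lig & acyc &
    heavy[b[, 1L]] & heavy[b[, 2L]] &
    deg[b[, 1L]] >= 2L & deg[b[, 2L]] >= 2L
  b[keep, , drop = FALSE]
}
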