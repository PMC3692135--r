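# Miniature molecular fixtures built in code: idealized residues and
# small ligands with hand-checked bond distances (bonds ~1.4-1.6 A,
# 1-3 distances > the 1.97 A C-C bond threshold).

atomLine <- function(record, serial, name, resname, chain, resseq,
                     x, y, z, element)
  LigandEgress:::pdbAtomLine(record, serial, name, resname, chain, resseq,
                             x, y, z, element)

# coordinates of one idealized residue, rows named by atom name
residueCoords <- function(restype) {
  bb <- rbind(N = c(0, 1.4, 0), CA = c(0, 0, 0), C = c(1.4, -0.5, 0),
              O = c(2.4, 0.2, 0))
  side <- switch(restype,
    GLY = NULL,
    LYS = rbind(CB = c(-1.0, -0.7, 0.9), CG = c(-2.3, -0.1, 1.3),
                CD = c(-3.4, -1.0, 1.9), CE = c(-4.7, -0.4, 2.3),
                NZ = c(-5.8, -1.3, 2.9)),
    PHE = {
      CB <- c(-1.05, -0.65, 0.95)
      M <- c(-2.4, -0.1, 1.3) + c(-1.39, 0, 0)   # ring center, flat ring
      ring <- t(vapply(0:5, function(k)
        M + 1.39 * c(cos(pi * k / 3), sin(pi * k / 3), 0), numeric(3)))
      rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      rbind(CB = CB, ring)
    },
    stop("unknown residue type ", restype))
  xyz <- rbind(bb, side)
  elem <- stats::setNames(substr(rownames(xyz), 1L, 1L), rownames(xyz))
  list(xyz = xyz, element = elem)
}

# PDB lines for a set of residues at given offsets; returns the text
residuesPDB <- function(restypes, offsets = NULL) {
  if (is.null(offsets))
    offsets <- lapply(seq_along(restypes) - 1L, function(k) c(12 * k, 0, 0))
  lines <- character(0); s <- 0L
  for (r in seq_along(restypes)) {
    rc <- residueCoords(restypes[r])
    for (nm in rownames(rc$xyz)) {
      s <- s + 1L
      p <- rc$xyz[nm, ] + offsets[[r]]
      lines <- c(lines, atomLine("ATOM", s, nm, restypes[r], "A", r,
                                 p[1L], p[2L], p[3L], rc$element[nm]))
    }
  }
  lines
}

# idealized phenol heavy atoms (6-ring + hydroxyl O) as HETATM lines
phenolPDB <- function(startSerial = 1L, center = c(0, 0, 0),
                      chain = "B", resseq = 301L) {
  ring <- t(vapply(0:5, function(k)
    center + 1.39 * c(cos(pi * k / 3), sin(pi * k / 3), 0), numeric(3)))
  oxy <- center + c(2.75, 0, 0)
  nm <- c("C1", "C2", "C3", "C4", "C5", "C6")
  lines <- character(0)
  for (k in 1:6)
    lines <- c(lines, atomLine("HETATM", startSerial + k - 1L, nm[k], "IPH",
                               chain, resseq, ring[k, 1L], ring[k, 2L],
                               ring[k, 3L], "C"))
  c(lines, atomLine("HETATM", startSerial + 6L, "O1", "IPH", chain, resseq,
                    oxy[1L], oxy[2L], oxy[3L], "O"))
}

# butane-like 4-carbon ligand (one rotatable central bond)
butanePDB <- function(startSerial = 1L, offset = c(0, 0, 0)) {
  xyz <- cbind(0, c(0.6, -0.3, 0.6, -0.3), c(0, 1.2, 2.4, 3.6))
  lines <- character(0)
  for (k in 1:4) {
    p <- xyz[k, ] + offset
    lines <- c(lines, atomLine("HETATM", startSerial + k - 1L,
                               paste0("C", k), "BUT", "B", 401L,
                               p[1L], p[2L], p[3L], "C"))
  }
  lines
}

parseSystem <- function(lines, selector = "auto")
  perceiveBonds(parsePDB(lines, ligandSelector = selector))
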