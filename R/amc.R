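## The `.amc` flexibility file: per-residue backbone/side-chain binary
## flags for the protein, and explicit dihedral lines (four atom serials
## plus angular bounds, degrees) for the mobile ligand's rotatable bonds.
## Dialect: '#' comments; one block per molecule opened by a
## "molecule protein <chain>" or "molecule ligand <resname> <chain:seq>"
## header; whitespace-separated fields; residue ids written chain:seq[icode].

resKeyOf <- function(chain, resseq, icode) paste0(chain, ":", resseq, icode)

## polymer (ATOM-record) residues of the system, one row each, input order
proteinResidues <- function(system) {
  a <- system@atoms
  keep <- !a$hetero & !(seq_len(nrow(a)) %in% system@ligand)
  a <- a[keep, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(restype = character(0), chain = character(0),
                      resseq = integer(0), icode = character(0)))
  key <- paste(a$chain, a$resseq, a$icode)
  first <- !duplicated(key)
  data.frame(restype = a$resname[first], chain = a$chain[first],
             resseq = a$resseq[first], icode = a$icode[first],
             stringsAsFactors = FALSE)
}

#' Generate the default flexibility specification
#'
#' One protein line per polymer residue with flags `0 1` (backbone fixed,
#' side-chain free — the default), and one ligand dihedral line per
#' rotatable ligand bond (see [rotatableLigandBonds()]) with full-circle
#' bounds. The companion `.amc` text, whose header documents the format,
#' is produced by [writeAMC()] and is valid input unchanged.
#'
#' @param system a [MolecularSystem-class] with bonds perceived.
#' @return a [FlexibilitySpec-class].
#' @export
defaultFlexibilitySpec <- function(system) {
  pres <- proteinResidues(system)
  pres$backbone <- if (nrow(pres)) 0L else integer(0)
  pres$sidechain <- if (nrow(pres)) 1L else integer(0)
  rb <- rotatableLigandBonds(system)
  nb <- heavyNeighborList(system)
  d <- data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                  a4 = integer(0), lower = numeric(0), upper = numeric(0))
  for (k in seq_len(nrow(rb))) {
    b <- rb[k, 1L]; cc <- rb[k, 2L]
    a1 <- setdiff(nb[[b]], cc)[1L]
    a4 <- setdiff(nb[[cc]], b)[1L]
    d <- rbind(d, data.frame(a1 = a1, a2 = b, a3 = cc, a4 = a4,
                             lower = -pi, upper = pi))
  }
  new("FlexibilitySpec", protein = pres, ligandDihedrals = d)
}

#' @rdname defaultFlexibilitySpec
#' @param ... passed to `defaultFlexibilitySpec`.
#' @export
generateTemplateAMC <- function(system, ...) {
  spec <- defaultFlexibilitySpec(system, ...)
  list(spec = spec, text = writeAMC(spec, system))
}

#' Write a flexibility specification as `.amc` text
#'
#' @param spec a [FlexibilitySpec-class].
#' @param system the [MolecularSystem-class] the spec refers to (for atom
#'   serials and ligand identity).
#' @param file optional output path.
#' @return character vector of `.amc` lines (invisibly when `file` given).
#' @export
writeAMC <- function(spec, system, file = NULL) {
  a <- system@atoms
  out <- c(
    "# Molecular flexibility description (.amc)",
    "# Protein blocks: one line per residue:",
    "#   RESTYPE RESID BACKBONE_FLAG SIDECHAIN_FLAG",
    "#   RESID is chain:seq (insertion code appended); flag 0 = fixed,",
    "#   flag 1 = freely rotatable. Only side-chain flexibility is",
    "#   supported: the backbone flag must be 0.",
    "# Ligand block: one line per rotatable-bond dihedral:",
    "#   SERIAL1 SERIAL2 SERIAL3 SERIAL4 LOWER UPPER",
    "#   atom serials of the four dihedral atoms; bounds in degrees.",
    "#   Delete a line to freeze that torsion; edit bounds to restrict it.")
  p <- spec@protein
  for (ch in unique(p$chain)) {
    out <- c(out, paste("molecule protein", ch))
    rows <- which(p$chain == ch)
    out <- c(out, sprintf("%s %s %d %d", p$restype[rows],
                          resKeyOf(p$chain[rows], p$resseq[rows],
                                   p$icode[rows]),
                          p$backbone[rows], p$sidechain[rows]))
  }
  d <- spec@ligandDihedrals
  if (length(system@ligand)) {
    li <- system@ligand[1L]
    out <- c(out, paste("molecule ligand", a$resname[li],
                        resKeyOf(a$chain[li], a$resseq[li], a$icode[li])))
    if (nrow(d))
      out <- c(out, sprintf("%d %d %d %d %g %g",
                            a$serial[d$a1], a$serial[d$a2], a$serial[d$a3],
                            a$serial[d$a4],
                            round(d$lower * 180 / pi, 6),
                            round(d$upper * 180 / pi, 6)))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse an `.amc` flexibility file
#'
#' Residues absent from the file keep the defaults (backbone fixed,
#' side-chain free). A ligand block, when present, fully replaces the
#' default dihedral set: lines removed from the template remove that
#' torsional DOF. Bounds are read in degrees and stored in radians.
#'
#' @param text `.amc` content: string, lines, or a path to a file.
#' @param system the [MolecularSystem-class] (bonds perceived) the file
#'   refers to.
#' @return a [FlexibilitySpec-class].
#' @export
parseAMC <- function(text, system) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]

  spec <- defaultFlexibilitySpec(system)
  p <- spec@protein
  pkey <- resKeyOf(p$chain, p$resseq, p$icode)
  a <- system@atoms
  serialToIdx <- function(s) {
    idx <- match(as.integer(s), a$serial)
    if (anyNA(idx))
      stop("amc reference error: atom serial(s) not found: ",
           paste(s[is.na(idx)], collapse = ", "))
    idx
  }

  mode <- "protein"
  sawLigandBlock <- FALSE
  dih <- spec@ligandDihedrals[0L, ]
  for (ln in text) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "molecule") {
      mode <- tok[2L]
      if (mode == "ligand") sawLigandBlock <- TRUE
      next
    }
    if (mode == "protein") {
      if (length(tok) != 4L)
        stop("amc parse error: expected 'RESTYPE RESID B S', got: ", ln)
      bb <- as.integer(tok[3L]); sc <- as.integer(tok[4L])
      if (is.na(bb) || is.na(sc) || !bb %in% 0:1 || !sc %in% 0:1)
        stop("amc parse error: flags must be 0 or 1 in: ", ln)
      if (bb == 1L)
        stop("unsupported-feature error: only the side-chains (and not ",
             "the backbone) can be defined as flexible (line: ", ln, ")")
      row <- match(tok[2L], pkey)
      if (is.na(row)) {
        warning("amc: residue ", tok[2L], " not found in structure; line ignored")
        next
      }
      if (toupper(tok[1L]) != toupper(p$restype[row]))
        warning("amc: residue type mismatch for ", tok[2L], ": file says ",
                tok[1L], ", structure says ", p$restype[row])
      p$backbone[row] <- bb
      p$sidechain[row] <- sc
    } else {
      if (length(tok) != 6L)
        stop("amc parse error: expected 'S1 S2 S3 S4 LOWER UPPER', got: ", ln)
      idx <- serialToIdx(tok[1:4])
      lo <- as.numeric(tok[5L]) * pi / 180
      hi <- as.numeric(tok[6L]) * pi / 180
      if (is.na(lo) || is.na(hi))
        stop("amc parse error: unreadable bounds in: ", ln)
      if (lo > hi)
        stop("amc parse error: lower bound exceeds upper bound in: ", ln)
      dih <- rbind(dih, data.frame(a1 = idx[1L], a2 = idx[2L], a3 = idx[3L],
                                   a4 = idx[4L], lower = lo, upper = hi))
    }
  }
  if (sawLigandBlock) spec@ligandDihedrals <- dih
  spec@protein <- p

  # each ligand dihedral's middle bond must be a perceived acyclic ligand bond
  d <- spec@ligandDihedrals
  if (nrow(d)) {
    rb <- rotatableLigandBonds(system)
    rbKey <- paste(rb[, 1L], rb[, 2L])
    mid <- paste(pmin(d$a2, d$a3), pmax(d$a2, d$a3))
    bad <- !(mid %in% rbKey)
    if (any(bad))
      stop("amc reference error: dihedral middle bond(s) ",
           paste(a$serial[d$a2[bad]], "-", a$serial[d$a3[bad]], collapse = ", "),
           " are not acyclic rotatable ligand bonds")
  }
  validObject(spec)
  spec
}
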