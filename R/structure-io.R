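#' Parse a PDB protein-ligand complex
#'
#' Reads ATOM/HETATM records (wwPDB v3.3 columns), assigns elements (from
#' columns 77-78 when present, otherwise inferred from the atom name) and
#' Bondi van der Waals / covalent radii, and designates the mobile ligand.
#' Only the first MODEL is read; alternate locations other than ' ' or 'A'
#' are dropped; hydrogens, if present, are kept as ordinary atoms.
#'
#' @param text PDB content: a single string, a character vector of lines,
#'   or a path to an existing file.
#' @param ligandSelector which residue is the mobile ligand. `"auto"`
#'   picks the first HETATM residue that is not a water or a monatomic
#'   ion (empty ligand set, with a warning, if there is none); `"none"`
#'   leaves the ligand unset; otherwise a string
#'   `"RESNAME [CHAIN [RESSEQ]]"` (e.g. `"IPH"`, `"IPH A 301"`) that must
#'   match exactly one residue.
#' @return a [MolecularSystem-class] (bonds empty; run [perceiveBonds()]).
#' @examples
#' pdb <- c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
#'   "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00")
#' sys <- parsePDB(pdb, ligandSelector = "none")
#' nAtoms(sys)
#' @export
parsePDB <- function(text, ligandSelector = "auto") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]

  warns <- character(0)
  rec <- substr(text, 1L, 6L)
  # first MODEL only
  mstart <- which(trimws(rec) == "MODEL")
  if (length(mstart) > 1L) {
    mend <- which(trimws(rec) == "ENDMDL")
    stopTo <- if (length(mend)) mend[1L] else mstart[2L]
    keepIdx <- seq_len(stopTo)
    warns <- c(warns, sprintf("multiple MODEL blocks; reading the first (%d models ignored)",
                              length(mstart) - 1L))
  } else keepIdx <- seq_along(text)

  isAtom <- rec %in% c("ATOM  ", "HETATM") & seq_along(text) %in% keepIdx
  lineNo <- which(isAtom)
  if (!length(lineNo)) stop("PDB parse error: no ATOM/HETATM records found")
  lines <- text[lineNo]

  # validate coordinate fields before handing the text to the reader,
  # so errors can name the offending line
  for (k in seq_along(lines)) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[k], 31L, 38L), substr(lines[k], 39L, 46L),
      substr(lines[k], 47L, 54L))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop(sprintf("PDB parse error at line %d: unparsable coordinate field",
                   lineNo[k]))
  }

  alt <- substr(lines, 17L, 17L)
  keepAlt <- alt %in% c(" ", "A", "")
  if (any(!keepAlt))
    warns <- c(warns, sprintf("%d alternate-location records dropped (kept ' '/'A')",
                              sum(!keepAlt)))
  lines <- lines[keepAlt]
  if (!length(lines)) stop("PDB parse error: no atoms left after altloc filtering")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  p <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom

  blank <- function(v, fill = "") ifelse(is.na(v), fill, v)
  element <- withCallingHandlers(
    inferElement(at$elety, at$elesy, at$type == "HETATM"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  vdw <- withCallingHandlers(vdwRadius(element), warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })

  hetero <- at$type == "HETATM"
  chain <- blank(at$chain, " ")
  icode <- blank(at$insert, "")
  resname <- trimws(blank(at$resid))
  molecule <- ifelse(hetero,
                     paste0("het:", chain, ":", at$resno, ":", icode, ":", resname),
                     paste0("chain:", chain))
  atomsDF <- data.frame(
    serial = at$eleno, name = trimws(blank(at$elety)),
    altloc = blank(at$alt, " "), resname = resname, chain = chain,
    resseq = at$resno, icode = icode,
    x = at$x, y = at$y, z = at$z,
    element = element, vdw = vdw, covr = covalentRadius(element),
    hetero = hetero, molecule = molecule,
    stringsAsFactors = FALSE)

  sys <- new("MolecularSystem", atoms = atomsDF, warnings = warns)
  selectLigand(sys, ligandSelector)
}

#' Designate the mobile ligand of a system
#'
#' @param system a [MolecularSystem-class].
#' @param selector see `ligandSelector` in [parsePDB()].
#' @return the system with its mobile-ligand index set assigned.
#' @export
selectLigand <- function(system, selector = "auto") {
  a <- system@atoms
  resKey <- paste(a$chain, a$resseq, a$icode, a$resname)
  if (identical(selector, "none")) {
    system@ligand <- integer(0)
    return(system)
  }
  if (identical(selector, "auto")) {
    ok <- a$hetero & !isWaterName(a$resname) & !isIonName(a$resname)
    if (!any(ok)) {
      system@warnings <- c(system@warnings,
        "auto ligand selection: no suitable HETATM residue; ligand unset")
      system@ligand <- integer(0)
      return(system)
    }
    key <- resKey[which(ok)[1L]]
    system@ligand <- which(resKey == key)
    validObject(system)
    return(system)
  }
  {
    if (is.list(selector)) {
      sel <- rep(TRUE, nrow(a))
      if (!is.null(selector$resname)) sel <- sel & a$resname == selector$resname
      if (!is.null(selector$chain)) sel <- sel & a$chain == selector$chain
      if (!is.null(selector$resseq)) sel <- sel & a$resseq == selector$resseq
    } else {
      tok <- strsplit(trimws(selector), "[[:space:]:]+")[[1L]]
      sel <- a$resname == tok[1L]
      if (length(tok) >= 2L) sel <- sel & a$chain == tok[2L]
      if (length(tok) >= 3L) sel <- sel & a$resseq == as.integer(tok[3L])
    }
    keys <- unique(resKey[sel])
    if (length(keys) == 0L)
      stop("ligand selection error: selector matches no residue")
    if (length(keys) > 1L)
      stop("ligand selection error: selector matches ", length(keys),
           " residues; add chain and/or sequence number")
    system@ligand <- which(resKey == keys)
  }
  validObject(system)
  system
}

#' Perceive covalent bonds by interatomic distance
#'
#' Atoms i and j of the same molecule are bonded iff
#' `0.4 < |xi - xj| <= covrad(i) + covrad(j) + tolerance`. Molecules are
#' polymer chains (ATOM records, per chain id) and individual HETATM
#' residues, so no bond can connect the mobile ligand to its environment.
#'
#' @param system a [MolecularSystem-class].
#' @param tolerance slack added to the covalent radii sum (Angstrom).
#' @return the system with its bond graph filled.
#' @export
perceiveBonds <- function(system, tolerance = 0.45) {
  a <- system@atoms
  n <- nrow(a)
  xyz <- coords(system)
  covr <- a$covr
  mol <- a$molecule
  bi <- integer(0); bj <- integer(0)
  molIdx <- split(seq_len(n), mol)
  for (idx in molIdx) {
    m <- length(idx)
    if (m < 2L) next
    for (u in seq_len(m - 1L)) {
      i <- idx[u]
      j <- idx[(u + 1L):m]
      dx <- xyz[j, 1L] - xyz[i, 1L]
      dy <- xyz[j, 2L] - xyz[i, 2L]
      dz <- xyz[j, 3L] - xyz[i, 3L]
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      hit <- d <= covr[i] + covr[j] + tolerance & d > 0.4
      if (any(hit)) {
        bi <- c(bi, rep.int(i, sum(hit)))
        bj <- c(bj, j[hit])
      }
    }
  }
  bnd <- cbind(pmin(bi, bj), pmax(bi, bj))
  storage.mode(bnd) <- "integer"
  deg <- tabulate(c(bi, bj), nbins = n)
  if (any(deg > 8L))
    stop("geometry-corruption error: atom(s) with more than 8 bonds: ",
         paste(a$serial[deg > 8L], collapse = ", "))
  system@bonds <- bnd
  validObject(system)
  system
}

#' Write one path frame as PDB text
#'
#' Emits the system with replaced coordinates as a wwPDB v3.3 record set
#' (`%8.3f` coordinate fields) with the frame index in a leading REMARK.
#' The output re-parses to the same atoms and coordinates to 1e-3 Angstrom.
#' Serials above 99999 wrap around.
#'
#' @param system a [MolecularSystem-class].
#' @param coordinates n x 3 matrix (defaults to the input coordinates).
#' @param frameIndex integer frame number recorded in the REMARK line.
#' @param file optional path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
writePDBFrame <- function(system, coordinates = coords(system),
                          frameIndex = 0L, file = NULL) {
  a <- system@atoms
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(a) || ncol(coordinates) != 3L)
    stop("coordinates must be a ", nrow(a), " x 3 matrix")
  if (any(!is.finite(coordinates)))
    stop("write error: non-finite coordinate")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  serial <- ((a$serial - 1L) %% 99999L) + 1L
  suppressWarnings(bio3d::write.pdb(
    file = tf,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    xyz = as.vector(t(coordinates)),
    eleno = serial, elety = a$name, resid = a$resname,
    chain = ifelse(a$chain == " ", "", a$chain), resno = a$resseq,
    insert = ifelse(a$icode == "", NA, a$icode),
    alt = ifelse(a$altloc %in% c(" ", ""), NA, a$altloc),
    elesy = ifelse(nchar(a$element) > 2L, "", a$element),
    o = rep(1, nrow(a)), b = rep(0, nrow(a))))
  out <- c(sprintf("REMARK 250 FRAME %d", as.integer(frameIndex)),
           readLines(tf, warn = FALSE))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
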