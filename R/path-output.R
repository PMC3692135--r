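## Path discretization to a fixed per-frame ligand displacement, the
## first-occurrence contacts report, the execution report and the
## per-solution output archive.

#' Discretize a solution path into frames
#'
#' Subdivides every tree edge uniformly (via
#' [interpolateConformations()]), refining the subdivision until the true
#' maximum ligand-atom displacement between consecutive frames is at most
#' `maxDisp` (~0.5 Angstrom by default): a pure 5 Angstrom translation
#' yields exactly ten 0.5 Angstrom segments. Endpoints are preserved;
#' identical endpoints yield the two frames unchanged.
#'
#' @param model an [ArticulatedModel-class].
#' @param path a [SolutionPath-class] (or list of conformations).
#' @param maxDisp per-frame ligand displacement bound (Angstrom).
#' @return the path with `frames` filled (list of n x 3 coordinate
#'   matrices, frame 0 first) and per-frame displacement statistics in
#'   the diagnostics (`maxLigandStep`, `maxSideChainStep`).
#' @export
discretizePath <- function(model, path, maxDisp = 0.5) {
  confs <- if (is(path, "SolutionPath")) path@nodeConfs else path
  stopifnot(length(confs) >= 1L)
  seqConfs <- confs[1L]
  for (k in seq_len(length(confs) - 1L))
    seqConfs <- c(seqConfs,
                  subdivideEdge(model, confs[[k]], confs[[k + 1L]], maxDisp))
  frames <- lapply(seqConfs, function(cf) forwardKinematics(model, cf))
  lig <- model@system@ligand
  oth <- setdiff(model@movingAtoms, lig)
  stepOf <- function(idx) {
    if (!length(idx)) return(0)
    vapply(seq_len(length(frames) - 1L), function(t) {
      sqrt(max(rowSums((frames[[t + 1L]][idx, , drop = FALSE] -
                          frames[[t]][idx, , drop = FALSE])^2)))
    }, 0)
  }
  out <- if (is(path, "SolutionPath")) path else new("SolutionPath",
                                                     nodeConfs = confs)
  out@frames <- frames
  dg <- out@diagnostics
  dg$maxLigandStep <- if (length(frames) > 1L) max(stepOf(lig)) else 0
  dg$maxSideChainStep <- if (length(frames) > 1L) max(stepOf(oth)) else 0
  dg$nFrames <- length(frames)
  out@diagnostics <- dg
  out
}

#' First-occurrence ligand contact report
#'
#' Runs [detectContacts()] on every frame; each ligand-environment atom
#' pair is listed once, at the first frame where the contact appears (set
#' `perEpisode = TRUE` to re-list a contact that breaks and re-forms at
#' the first frame of each episode). Frames are numbered from 0, so
#' contacts present in the bound start conformation carry frame 0.
#'
#' @param model an [ArticulatedModel-class].
#' @param frames list of coordinate matrices from [discretizePath()] (a
#'   discretized [SolutionPath-class] is also accepted).
#' @param vdwFraction the collision fraction; contacts use this + 0.20.
#' @param perEpisode re-list re-formed contacts.
#' @return data.frame with columns frame, ligSerial, ligName, ligRes,
#'   envSerial, envName, envRes, envChain, envSeq, distance; sorted by
#'   frame then atom serials.
#' @export
buildContactsReport <- function(model, frames, vdwFraction = 0.75,
                                perEpisode = FALSE) {
  if (is(frames, "SolutionPath")) frames <- frames@frames
  a <- model@system@atoms
  lig <- model@system@ligand
  radii <- a$vdw
  seen <- character(0)
  active <- character(0)   # pairs in contact at the previous frame
  rows <- list()
  for (t in seq_along(frames)) {
    ct <- detectContacts(frames[[t]], radii, lig, vdwFraction)
    key <- paste(ct$i, ct$j)
    new <- if (perEpisode) !(key %in% active) else !(key %in% seen)
    if (any(new)) {
      ctn <- ct[new, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t - 1L,
        ligSerial = a$serial[ctn$i], ligName = a$name[ctn$i],
        ligRes = a$resname[ctn$i],
        envSerial = a$serial[ctn$j], envName = a$name[ctn$j],
        envRes = a$resname[ctn$j], envChain = a$chain[ctn$j],
        envSeq = a$resseq[ctn$j], distance = ctn$distance,
        stringsAsFactors = FALSE)
    }
    seen <- union(seen, key)
    active <- key
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), ligSerial = integer(0),
                      ligName = character(0), ligRes = character(0),
                      envSerial = integer(0), envName = character(0),
                      envRes = character(0), envChain = character(0),
                      envSeq = integer(0), distance = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$ligSerial, out$envSerial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname buildContactsReport
#' @param report a contacts data.frame.
#' @param file optional output path.
#' @return `formatContactsReport`: character lines, one per contact
#'   (frame index first, then ligand atom, environment atom, distance).
#' @export
formatContactsReport <- function(report, file = NULL) {
  lines <- sprintf("%d %d %s %s %d %s %s %s %d %.3f",
                   report$frame, report$ligSerial, report$ligName,
                   report$ligRes, report$envSerial, report$envName,
                   report$envRes, report$envChain, report$envSeq,
                   report$distance)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Execution report
#'
#' Human-readable summary of a planner run: outcome, seed, goal distance
#' achieved, iterations, node statistics, parse warnings, preprocessing
#' summary, and the failure reason when the search did not succeed.
#'
#' @param diag diagnostics list of a [SolutionPath-class] (see
#'   [diagnostics()]).
#' @param parseWarnings character vector of structure parse warnings.
#' @param resolutionSummary preprocessing summary string (attribute
#'   `"summary"` of [resolveInitialClashes()]'s result).
#' @param file optional output path.
#' @return character lines.
#' @export
writeExecutionReport <- function(diag, parseWarnings = character(0),
                                 resolutionSummary = NULL, file = NULL) {
  status <- if (isTRUE(diag$success)) "SUCCESS" else "FAILURE"
  lines <- c(
    "=== execution report ===",
    paste("status:", status),
    paste("seed:", diag$seed),
    paste("strategy:", diag$strategy),
    paste("vdW fraction:", diag$vdwFraction),
    sprintf("exit distance: %.3f A", diag$exitDistance),
    sprintf("final center-center distance: %.3f A", diag$finalDistance),
    paste("iterations used:", diag$iterations),
    paste("nodes created:", diag$nodesCreated),
    paste("nodes exhausted:", diag$nodesExhausted))
  if (!is.null(diag$nFrames))
    lines <- c(lines,
               paste("frames written:", diag$nFrames),
               sprintf("max ligand-atom step: %.3f A", diag$maxLigandStep),
               sprintf("max side-chain-atom step: %.3f A",
                       diag$maxSideChainStep))
  if (!isTRUE(diag$success))
    lines <- c(lines, paste("failure reason:", diag$reason))
  if (!is.null(resolutionSummary))
    lines <- c(lines, paste("preprocessing:", resolutionSummary))
  if (length(parseWarnings))
    lines <- c(lines, "parse warnings:", paste(" -", parseWarnings))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write a per-solution output archive
#'
#' One directory per solution: `frame_0000.pdb` ... `frame_NNNN.pdb`,
#' `contacts.txt` (first-occurrence ligand contacts) and `report.txt`
#' (execution report).
#'
#' @param model an [ArticulatedModel-class].
#' @param path a discretized [SolutionPath-class].
#' @param dir output directory (created if needed).
#' @param vdwFraction collision fraction used for the contact report.
#' @param parseWarnings,resolutionSummary forwarded to
#'   [writeExecutionReport()].
#' @return `dir`, invisibly.
#' @export
writeSolutionArchive <- function(model, path, dir, vdwFraction = 0.75,
                                 parseWarnings = character(0),
                                 resolutionSummary = NULL) {
  if (!length(path@frames))
    stop("path has no frames; run discretizePath() first")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(path@frames))
    writePDBFrame(model@system, path@frames[[t]], frameIndex = t - 1L,
                  file = file.path(dir, sprintf("frame_%04d.pdb", t - 1L)))
  # contacts from the coordinates as written (3 decimals), so the report
  # regenerates identically from the files
  rep <- buildContactsReport(model, lapply(path@frames, round, 3L),
                             vdwFraction)
  formatContactsReport(rep, file.path(dir, "contacts.txt"))
  writeExecutionReport(path@diagnostics, parseWarnings, resolutionSummary,
                       file = file.path(dir, "report.txt"))
  invisible(dir)
}

#' Re-validate a written solution archive
#'
#' Re-parses the PDB frames of an archive directory and re-checks, from
#' the files alone: the per-frame ligand displacement bound, clash
#' freedom of every frame at the given fraction, the exit-distance goal
#' on the last frame, and that the contacts file matches a regenerated
#' report.
#'
#' @param dir archive directory written by [writeSolutionArchive()].
#' @param model the [ArticulatedModel-class] the archive was produced
#'   from.
#' @param vdwFraction collision fraction.
#' @param maxDisp displacement bound (Angstrom); checked with a 2e-3
#'   Angstrom tolerance for the rounding of written coordinates.
#' @param exitDistance goal distance; `"auto"` recomputes it.
#' @param coordTol slack (Angstrom) subtracted from the clash thresholds
#'   to absorb the 1e-3 rounding of written coordinates.
#' @return named list of logicals: `displacementOk`, `clashFreeOk`,
#'   `exitOk`, `contactsOk`, plus measured `maxStep` and `finalDistance`.
#' @export
validateSolutionDir <- function(dir, model, vdwFraction = 0.75,
                                maxDisp = 0.5, exitDistance = "auto",
                                coordTol = 5e-3) {
  files <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.pdb$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame files in ", dir)
  sys <- model@system
  frames <- lapply(files, function(f) {
    p <- parsePDB(f, ligandSelector = "none")
    if (nAtoms(p) != nAtoms(sys)) stop("frame atom count mismatch in ", f)
    coords(p)
  })
  lig <- sys@ligand
  steps <- if (length(frames) > 1L)
    vapply(seq_len(length(frames) - 1L), function(t)
      sqrt(max(rowSums((frames[[t + 1L]][lig, , drop = FALSE] -
                          frames[[t]][lig, , drop = FALSE])^2))), 0)
  else 0
  settings <- collisionSettings(model, vdwFraction)
  settings@thresholds <- pmax(0, settings@thresholds - coordTol)
  clashFree <- all(vapply(frames, function(X) !anyClash(X, settings), TRUE))
  exitDist <- if (identical(exitDistance, "auto"))
    computeExitDistance(sys) else as.numeric(exitDistance)
  lastC <- colMeans(frames[[length(frames)]][lig, , drop = FALSE])
  finalDistance <- sqrt(sum((lastC - model@receptorCenter)^2))
  regen <- formatContactsReport(
    buildContactsReport(model, frames, vdwFraction))
  onDisk <- readLines(file.path(dir, "contacts.txt"), warn = FALSE)
  list(displacementOk = max(steps) <= maxDisp + 2e-3,
       clashFreeOk = clashFree,
       exitOk = finalDistance >= exitDist - 1e-9,
       contactsOk = identical(regen, onDisk),
       maxStep = max(steps), finalDistance = finalDistance)
}
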