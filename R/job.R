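#' Run a complete unbinding job
#'
#' The full pipeline: parse the PDB complex, perceive bonds, apply the
#' flexibility specification (an `.amc` file, or the default: all
#' side-chains free, all ligand rotatable bonds free), build the
#' articulated model, resolve initial clashes, and run `nPaths`
#' independent planner searches (seeds `rngSeed + 0 ... nPaths - 1`).
#' Each successful search is discretized and written as a per-solution
#' archive `solution_01/`, `solution_02/`, ... under `outputDir`,
#' together with a top-level `job_report.txt` and machine-readable
#' `job_summary.json`.
#'
#' @param pdb PDB input: path, text, or a parsed [MolecularSystem-class].
#' @param outputDir output directory (created if needed).
#' @param amc optional `.amc` input (path or text).
#' @param ligandSelector see [parsePDB()].
#' @param config a [plannerConfig()].
#' @return invisibly, the job summary list: per-run seed/success/
#'   diagnostics, and `nSolutions`.
#' @export
runJob <- function(pdb, outputDir, amc = NULL, ligandSelector = "auto",
                   config = plannerConfig()) {
  sys <- if (is(pdb, "MolecularSystem")) pdb
         else perceiveBonds(parsePDB(pdb, ligandSelector = ligandSelector))
  if (!nrow(sys@bonds) && nAtoms(sys) > 1L) sys <- perceiveBonds(sys)
  spec <- if (is.null(amc)) defaultFlexibilitySpec(sys)
          else parseAMC(amc, sys)
  model <- buildArticulatedModel(sys, spec)
  conf0 <- resolveInitialClashes(model, config = config)
  resolSummary <- attr(conf0, "summary")

  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  nSol <- 0L
  for (i in seq_len(config$nPaths)) {
    cfg <- config
    cfg$rngSeed <- config$rngSeed + i - 1L
    path <- planUnbinding(model, conf0, cfg)
    dg <- path@diagnostics
    if (isTRUE(dg$success)) {
      nSol <- nSol + 1L
      path <- discretizePath(model, path, cfg$edgeResolution)
      writeSolutionArchive(model, path,
                           file.path(outputDir, sprintf("solution_%02d", nSol)),
                           vdwFraction = cfg$vdwFraction,
                           parseWarnings = sys@warnings,
                           resolutionSummary = resolSummary)
      dg <- path@diagnostics
    }
    runs[[i]] <- dg
  }
  summary <- list(
    nRuns = config$nPaths, nSolutions = nSol,
    ligand = if (length(sys@ligand))
      paste(sys@atoms$resname[sys@ligand[1L]],
            sys@atoms$chain[sys@ligand[1L]],
            sys@atoms$resseq[sys@ligand[1L]]) else "none",
    activeDOFs = nActiveDOFs(model), passiveDOFs = nPassiveDOFs(model),
    vdwFraction = config$vdwFraction, strategy = config$strategy,
    preprocessing = resolSummary, parseWarnings = sys@warnings,
    runs = runs)
  jsonlite::write_json(summary, file.path(outputDir, "job_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(
    "=== job report ===",
    paste("ligand:", summary$ligand),
    paste("active DOFs:", summary$activeDOFs),
    paste("passive DOFs:", summary$passiveDOFs),
    paste("preprocessing:", resolSummary),
    paste("runs:", config$nPaths, "; solutions:", nSol),
    vapply(seq_along(runs), function(i)
      sprintf("run %d (seed %d): %s", i, runs[[i]]$seed,
              if (isTRUE(runs[[i]]$success)) "SUCCESS" else
                paste("FAILURE -", runs[[i]]$reason)), "")),
    file.path(outputDir, "job_report.txt"))
  invisible(summary)
}
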