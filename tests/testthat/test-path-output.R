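miniLigandModel <- function() {
  lines <- c(atomLine("ATOM", 1L, "C", "REC", "A", 1L, 0, 0, 0, "C"),
             atomLine("HETATM", 2L, "C1", "LIG", "L", 1L, 8, 0, 0, "C"))
  buildArticulatedModel(parseSystem(lines))
}

test_that("a pure 5 A translation discretizes into 11 frames of 0.5 A", {
  m <- miniLigandModel()
  a <- identityConformation(m)
  b <- newConformation(m, trans = c(5, 0, 0))
  p <- discretizePath(m, list(a, b))
  expect_equal(length(p@frames), 11L)
  steps <- vapply(1:10, function(t)
    p@frames[[t + 1L]][2L, 1L] - p@frames[[t]][2L, 1L], 0)
  expect_equal(steps, rep(0.5, 10L))
  expect_equal(p@diagnostics$maxLigandStep, 0.5, tolerance = 1e-12)
})

test_that("identical endpoints yield two identical frames", {
  m <- miniLigandModel()
  a <- identityConformation(m)
  p <- discretizePath(m, list(a, a))
  expect_equal(length(p@frames), 2L)
  expect_identical(p@frames[[1L]], p@frames[[2L]])
})

test_that("a half-turn ligand spin subdivides as the arc-length oracle predicts", {
  sys <- parseSystem(phenolPDB())
  m <- buildArticulatedModel(sys, defaultFlexibilitySpec(sys))
  a <- identityConformation(m)
  b <- newConformation(m, quat = c(cos(pi / 2), 0, 0, sin(pi / 2))) # 180 deg
  p <- discretizePath(m, list(a, b))
  # arc-length oracle: an atom at radius rho moves a chord
  # 2 rho sin(theta / 2) per uniform segment, so at least nMin segments
  # are needed; uniform refinement should not exceed twice that
  lig <- ligandAtoms(m)
  ctr <- m@ligandCenter
  rho <- sqrt(rowSums(sweep(m@refCoords[lig, ], 2L, ctr)^2))
  nMin <- 1L
  while (max(2 * rho * sin(pi / (2 * nMin))) > 0.5) nMin <- nMin + 1L
  nSeg <- length(p@frames) - 1L
  expect_gte(nSeg, nMin)
  expect_lte(nSeg, 2L * nMin)
  # the bound holds on true coordinates for every consecutive pair
  for (t in seq_len(length(p@frames) - 1L))
    expect_lte(maxDisp(p@frames[[t]], p@frames[[t + 1L]], lig), 0.5 + 1e-9)
})

twoAtomFrames <- function(dists) {
  lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
}

test_that("contacts are listed once at their first frame", {
  lines <- c(atomLine("ATOM", 1L, "C", "REC", "A", 1L, 0, 0, 0, "C"),
             atomLine("HETATM", 2L, "C1", "LIG", "L", 1L, 8, 0, 0, "C"))
  m <- buildArticulatedModel(parseSystem(lines))
  # receptor atom row 1, ligand row 2; contact threshold 0.95*3.4 = 3.23
  far <- 5; close <- 3.0
  rep1 <- buildContactsReport(m, twoAtomFrames(c(far, close, close)), 0.75)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$frame, 1L)
  expect_equal(rep1$distance, close)
  # re-formed contact: single absolute first occurrence by default,
  # per-episode listing behind the flag
  rep2 <- buildContactsReport(m, twoAtomFrames(c(close, far, close)), 0.75)
  expect_equal(rep2$frame, 0L)
  rep3 <- buildContactsReport(m, twoAtomFrames(c(close, far, close)), 0.75,
                              perEpisode = TRUE)
  expect_equal(rep3$frame, c(0L, 2L))
  # bound start: initial binding-site contacts carry frame 0
  rep4 <- buildContactsReport(m, twoAtomFrames(c(close, close, far)), 0.75)
  expect_equal(rep4$frame, 0L)
})

test_that("execution reports carry outcome, seed and distances", {
  diagOK <- list(success = TRUE, seed = 7L, strategy = "connect",
                 vdwFraction = 0.75, exitDistance = 13.6,
                 finalDistance = 14.2, iterations = 120L,
                 nodesCreated = 300L, nodesExhausted = 2L)
  txt <- writeExecutionReport(diagOK, parseWarnings = "odd element XX",
                              resolutionSummary = "input clash-free")
  expect_true(any(grepl("SUCCESS", txt)))
  expect_true(any(grepl("seed: 7", txt)))
  expect_true(any(grepl("14.200", txt)))
  expect_true(any(grepl("odd element", txt)))
  diagBudget <- modifyList(diagOK, list(success = FALSE,
                                        reason = "budget exhausted"))
  diagExh <- modifyList(diagOK, list(success = FALSE,
                                     reason = "all nodes exhausted"))
  expect_true(any(grepl("FAILURE", writeExecutionReport(diagBudget))))
  expect_true(any(grepl("budget exhausted", writeExecutionReport(diagBudget))))
  expect_true(any(grepl("all nodes exhausted", writeExecutionReport(diagExh))))
})

test_that("written archives re-validate from the files alone", {
  fx <- makeChannelFixture()
  m <- buildArticulatedModel(fx$system, fx$spec)
  p <- planUnbinding(m, config = plannerConfig(rngSeed = 9L))
  p <- discretizePath(m, p)
  dir <- file.path(tempdir(), "arch-test")
  unlink(dir, recursive = TRUE)
  writeSolutionArchive(m, p, dir)
  expect_true(file.exists(file.path(dir, "frame_0000.pdb")))
  expect_true(file.exists(file.path(dir, "contacts.txt")))
  expect_true(file.exists(file.path(dir, "report.txt")))
  chk <- validateSolutionDir(dir, m)
  expect_true(chk$displacementOk)
  expect_true(chk$clashFreeOk)
  expect_true(chk$exitOk)
  expect_true(chk$contactsOk)   # regenerated from re-parsed frames
})
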