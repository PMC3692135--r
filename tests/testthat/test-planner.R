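test_that("automatic exit distance follows the radius-sum formula", {
  mini <- function(xyzRec, xyzLig) {
    lines <- character(0); s <- 0L
    for (k in seq_len(nrow(xyzRec))) {
      s <- s + 1L
      lines <- c(lines, atomLine("ATOM", s, "C", "REC", "A", k,
                                 xyzRec[k, 1L], xyzRec[k, 2L], xyzRec[k, 3L], "C"))
    }
    for (k in seq_len(nrow(xyzLig))) {
      s <- s + 1L
      lines <- c(lines, atomLine("HETATM", s, paste0("C", k), "LIG", "L", 1L,
                                 xyzLig[k, 1L], xyzLig[k, 2L], xyzLig[k, 3L], "C"))
    }
    parsePDB(lines)
  }
  # single receptor atom (r = 1.7) + single ligand atom: 1.7 + 1.7 + 2.0
  expect_equal(computeExitDistance(mini(rbind(c(0, 0, 0)), rbind(c(9, 0, 0)))),
               5.4)
  # receptor of two atoms 10 A apart: R_receptor = 5 + 1.7
  expect_equal(computeExitDistance(mini(rbind(c(0, 0, 0), c(10, 0, 0)),
                                        rbind(c(0, 9, 0)))),
               6.7 + 1.7 + 2.0)
  # a user-supplied exit distance overrides the formula exactly
  fx <- makeFreeLigandFixture()
  m <- buildArticulatedModel(fx$system, fx$spec)
  p <- planUnbinding(m, config = plannerConfig(exitDistance = 7.5))
  expect_equal(diagnostics(p)$exitDistance, 7.5)
})

test_that("active sampling is uniform in the box, respects bounds, and is seeded", {
  fx <- makeChannelFixture()
  m <- buildArticulatedModel(fx$system, fx$spec)
  exitD <- computeExitDistance(fx$system)
  ctx <- LigandEgress:::samplingContext(m, exitD)
  set.seed(99)
  centers <- t(replicate(4000, sampleActive(m, ctx)@trans + m@ligandCenter))
  for (d in 1:3) {
    expect_true(all(centers[, d] >= ctx$boxLower[d] - 1e-12))
    expect_true(all(centers[, d] <= ctx$boxUpper[d] + 1e-12))
    mid <- (ctx$boxLower[d] + ctx$boxUpper[d]) / 2
    se <- (ctx$boxUpper[d] - ctx$boxLower[d]) / sqrt(12) / sqrt(4000)
    expect_lt(abs(mean(centers[, d]) - mid), 3 * se)
  }
  # fixed seed reproduces the sample stream
  set.seed(7); s1 <- replicate(5, sampleActive(m, ctx)@trans)
  set.seed(7); s2 <- replicate(5, sampleActive(m, ctx)@trans)
  expect_identical(s1, s2)
  # degenerate torsion bounds pin the torsion at the bound
  sysB <- parseSystem(c(residuesPDB("GLY"), butanePDB(50L, c(20, 0, 0))))
  tpl <- generateTemplateAMC(sysB)
  tok <- strsplit(grep("^[0-9]+ [0-9]+ [0-9]+", tpl$text, value = TRUE),
                  " ")[[1L]]
  specB <- parseAMC(c("molecule ligand BUT B:401",
                      paste(paste(tok[1:4], collapse = " "), "25 25")), sysB)
  mB <- buildArticulatedModel(sysB, specB)
  ref <- mB@ligandTorsions[[1L]]$ref
  set.seed(3)
  smp <- replicate(10, sampleActive(mB, exitDist = 5)@ligTorsions)
  expect_true(all(abs(smp - (25 * pi / 180 - ref)) < 1e-12))
})

test_that("clash-free inputs pass preprocessing unchanged", {
  fx <- makeChannelFixture(gate = TRUE)
  m <- buildArticulatedModel(fx$system, fx$spec)
  conf <- resolveInitialClashes(m)
  expect_equal(conf@passive, c(0, 0))
  expect_match(attr(conf, "summary"), "unchanged")
})

test_that("initial clashes are cleared by perturbing only the involved residues", {
  # phenol placed 2.35 A from lysine NZ: a clash at 75% (threshold 2.44)
  # that a small chi rotation clears
  lines <- c(residuesPDB(c("LYS", "PHE"), offsets = list(c(0, 0, 0), c(12, 0, 0))),
             phenolPDB(100L, c(-5.8, -4.75, 2.9)))
  sys <- parseSystem(lines)
  m <- buildArticulatedModel(sys, defaultFlexibilitySpec(sys))
  st <- collisionSettings(m, 0.75)
  cl0 <- detectClashes(coords(sys), st)
  expect_gt(nrow(cl0), 0L)
  a <- atoms(sys)
  expect_true(all(a$name[cl0$i] == "NZ" | a$name[cl0$j] == "NZ" |
                    a$resname[cl0$i] == "IPH" | a$resname[cl0$j] == "IPH"))
  conf <- resolveInitialClashes(m, config = plannerConfig(rngSeed = 2L))
  expect_equal(nrow(detectClashes(forwardKinematics(m, conf), st)), 0L)
  res <- vapply(m@passiveTorsions, `[[`, "", "residue")
  expect_true(any(conf@passive[res == "A:1"] != 0))  # LYS perturbed
  expect_true(all(conf@passive[res == "A:2"] == 0))  # PHE untouched
  expect_match(attr(conf, "summary"), "resolved")
})

test_that("clashes involving no flexible side-chain abort with vdW advice", {
  # ligand overlapping a rigid wall atom: nothing passive can fix it
  lines <- c(atomLine("ATOM", 1L, "C", "WAL", "Z", 1L, 0, 0, 0, "C"),
             atomLine("ATOM", 2L, "C", "WAL", "Z", 2L, 8, 0, 0, "C"),
             atomLine("HETATM", 3L, "C1", "LIG", "L", 1L, 2.3, 0, 0, "C"))
  m <- buildArticulatedModel(parseSystem(lines))
  expect_error(resolveInitialClashes(m), "reduced percentage of van der Waals")
})

test_that("flexible gate opens, rigid gate with negative clearance never passes", {
  flex <- makeChannelFixture(gate = TRUE)
  rigid <- makeChannelFixture(gate = TRUE, gateFlexible = FALSE)
  expect_lt(rigid$gateClearance, 0)
  mf <- buildArticulatedModel(flex$system, flex$spec)
  mr <- buildArticulatedModel(rigid$system, rigid$spec)
  okF <- okR <- 0L
  for (s in 1:3) {
    pf <- planUnbinding(mf, config = plannerConfig(rngSeed = s,
                                                   maxIterations = 6000L))
    okF <- okF + isTRUE(diagnostics(pf)$success)
    if (isTRUE(diagnostics(pf)$success)) {
      # the gate torsions actually moved somewhere along the path
      pas <- vapply(nodeConformations(pf), function(cf) max(abs(cf@passive)), 0)
      expect_gt(max(pas), 0.3)
    }
    pr <- planUnbinding(mr, config = plannerConfig(rngSeed = s,
                                                   maxIterations = 700L))
    okR <- okR + isTRUE(diagnostics(pr)$success)
    expect_false(diagnostics(pr)$success)
    expect_match(diagnostics(pr)$reason, "exhausted")
  }
  expect_gte(okF, 2L)
  expect_equal(okR, 0L)
})

test_that("systems without passive DOFs run as plain RRT", {
  fx <- makeChannelFixture()                 # no gate: zero passive DOFs
  m <- buildArticulatedModel(fx$system, fx$spec)
  expect_equal(nPassiveDOFs(m), 0L)
  p <- planUnbinding(m, config = plannerConfig(rngSeed = 5L))
  expect_true(diagnostics(p)$success)
  expect_true(all(lengths(lapply(nodeConformations(p),
                                 function(cf) cf@passive)) == 0L))
})

test_that("unrecruited side-chains keep zero passive values (parsimony)", {
  # open channel plus a flexible lysine tucked under the closed end:
  # never blocks the exit, so it must never move
  chan <- makeChannelFixture()$pdb
  rc <- residueCoords("LYS")
  lys <- character(0)
  for (k in seq_len(nrow(rc$xyz))) {
    p <- rc$xyz[k, ] + c(0, 0, -13)
    lys <- c(lys, atomLine("ATOM", 200L + k, rownames(rc$xyz)[k], "LYS",
                           "A", 1L, p[1L], p[2L], p[3L], rc$element[k]))
  }
  sys <- parseSystem(c(chan[-length(chan)], lys), selector = "LIG")
  m <- buildArticulatedModel(sys, defaultFlexibilitySpec(sys))
  expect_equal(nPassiveDOFs(m), 4L)
  p <- planUnbinding(m, config = plannerConfig(rngSeed = 4L))
  expect_true(diagnostics(p)$success)
  expect_true(all(vapply(nodeConformations(p),
                         function(cf) all(cf@passive == 0), TRUE)))
})

test_that("a caged ligand exhausts nodes and reports failure gracefully", {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(1 + phi^2) * 2.7
  lines <- character(0)
  for (k in seq_len(12L))
    lines <- c(lines, atomLine("ATOM", k, "C", "CAG", "Z", k,
                               v[k, 1L], v[k, 2L], v[k, 3L], "C"))
  lines <- c(lines, atomLine("HETATM", 13L, "C1", "LIG", "L", 1L, 0, 0, 0, "C"))
  m <- buildArticulatedModel(parseSystem(lines))
  p <- planUnbinding(m, config = plannerConfig(rngSeed = 1L, nFailMax = 5L,
                                               maxIterations = 2500L))
  d <- diagnostics(p)
  expect_false(d$success)
  expect_gte(d$nodesExhausted, 1L)
  expect_true(d$reason %in% c("all nodes exhausted", "budget exhausted"))
})

test_that("identical seeds reproduce the search bit-for-bit", {
  fx <- makeChannelFixture(gate = TRUE)
  m <- buildArticulatedModel(fx$system, fx$spec)
  cfg <- plannerConfig(rngSeed = 2L, maxIterations = 6000L)
  p1 <- planUnbinding(m, config = cfg)
  p2 <- planUnbinding(m, config = cfg)
  expect_identical(lapply(nodeConformations(p1), function(cf)
    list(cf@trans, cf@quat, cf@passive)),
    lapply(nodeConformations(p2), function(cf)
      list(cf@trans, cf@quat, cf@passive)))
  expect_identical(diagnostics(p1), diagnostics(p2))
})

test_that("success is monotone in corridor width (sanity trend)", {
  runs <- function(scale, seeds) {
    m <- tryCatch({
      fx <- makeChannelFixture(gate = TRUE, scale = scale)
      buildArticulatedModel(fx$system, fx$spec)
    }, error = function(e) NULL)
    if (is.null(m)) return(0L)
    sum(vapply(seeds, function(s) {
      p <- tryCatch(planUnbinding(m, config = plannerConfig(
        rngSeed = s, maxIterations = 2500L)), error = function(e) NULL)
      !is.null(p) && isTRUE(diagnostics(p)$success)
    }, TRUE))
  }
  wide <- runs(1.0, 1:6)
  narrow <- runs(0.9, 1:6)
  expect_gte(wide, narrow)
  expect_gte(wide, 4L)
})
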