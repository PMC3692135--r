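test_that("template generation: peptide flags and rotatable-bond lines", {
  # 5-residue peptide + rigid phenol: 5 protein lines "0 1", 0 ligand lines
  sys <- parseSystem(c(residuesPDB(rep("GLY", 5L)), phenolPDB(100L, c(45, 0, 0))))
  tpl <- generateTemplateAMC(sys)
  expect_equal(nrow(tpl$spec@protein), 5L)
  expect_true(all(tpl$spec@protein$backbone == 0L))
  expect_true(all(tpl$spec@protein$sidechain == 1L))
  expect_equal(nrow(tpl$spec@ligandDihedrals), 0L)
  # independent graph oracle: a rotatable bond is an acyclic heavy bond
  # whose endpoints both have >= 2 heavy neighbors
  b <- bonds(sys); lig <- ligandAtoms(sys)
  deg <- tabulate(b, nbins = nAtoms(sys))
  rot <- 0L
  for (k in seq_len(nrow(b))) {
    if (!(b[k, 1L] %in% lig)) next
    if (deg[b[k, 1L]] >= 2L && deg[b[k, 2L]] >= 2L &&
        oracleIsBridge(b, nAtoms(sys), k)) rot <- rot + 1L
  }
  expect_equal(rot, 0L)
})

test_that("butane-like ligand yields exactly one dihedral line", {
  sys <- parseSystem(c(residuesPDB("GLY"), butanePDB(50L, c(20, 0, 0))))
  tpl <- generateTemplateAMC(sys)
  d <- tpl$spec@ligandDihedrals
  expect_equal(nrow(d), 1L)
  # the middle bond is the central C2-C3 bond
  serials <- atoms(sys)$serial[c(d$a2, d$a3)]
  expect_setequal(serials, c(51L, 52L))
  expect_equal(d$lower, -pi)
  expect_equal(d$upper, pi)
})

test_that("glycine prints a side-chain flag but contributes zero DOFs", {
  sys <- parseSystem(c(residuesPDB("GLY"), phenolPDB(100L, c(30, 0, 0))))
  tpl <- generateTemplateAMC(sys)
  expect_equal(tpl$spec@protein$sidechain, 1L)
  model <- buildArticulatedModel(sys, tpl$spec)
  expect_equal(nPassiveDOFs(model), 0L)
})

test_that("generate -> write -> parse round-trips on varied fixtures", {
  for (lines in list(
    c(residuesPDB(c("GLY", "LYS", "PHE")), phenolPDB(100L, c(30, 0, 0))),
    c(residuesPDB("LYS"), butanePDB(60L, c(20, 0, 0))),
    makeChannelFixture(gate = TRUE)$pdb)) {
    sys <- parseSystem(lines)
    tpl <- generateTemplateAMC(sys)
    spec2 <- parseAMC(tpl$text, sys)
    expect_equal(spec2@protein, tpl$spec@protein)
    expect_equal(spec2@ligandDihedrals, tpl$spec@ligandDihedrals)
  }
})

test_that("blocking a residue removes its torsions from the passive set", {
  sys <- parseSystem(c(residuesPDB(c("LYS", "PHE")), phenolPDB(100L, c(30, 0, 0))))
  full <- buildArticulatedModel(sys, defaultFlexibilitySpec(sys))
  expect_equal(nPassiveDOFs(full), 6L)      # LYS 4 + PHE 2
  amc <- c("molecule protein A", "LYS A:1 0 0")
  spec <- parseAMC(amc, sys)
  expect_equal(spec@protein$sidechain, c(0L, 1L))   # absent rows keep defaults
  blocked <- buildArticulatedModel(sys, spec)
  expect_equal(nPassiveDOFs(blocked), 2L)   # only PHE remains
})

test_that("ligand dihedral lines can be removed and bounds restricted", {
  sys <- parseSystem(c(residuesPDB("GLY"), butanePDB(50L, c(20, 0, 0))))
  tpl <- generateTemplateAMC(sys)
  # ligand block present but empty: the torsion DOF is removed
  noLig <- parseAMC(grep("^[0-9]", tpl$text, invert = TRUE, value = TRUE),
                    sys)
  expect_equal(nrow(noLig@ligandDihedrals), 0L)
  # bounds [-30, 30] degrees are parsed to radians and drive sampling
  dihLine <- grep("^[0-9]+ [0-9]+ [0-9]+ [0-9]+", tpl$text, value = TRUE)
  tok <- strsplit(dihLine, " ")[[1L]]
  amc2 <- c("molecule ligand BUT B:401",
            paste(paste(tok[1:4], collapse = " "), "-30 30"))
  spec2 <- parseAMC(amc2, sys)
  expect_equal(spec2@ligandDihedrals$lower, -pi / 6)
  expect_equal(spec2@ligandDihedrals$upper, pi / 6)
  model <- buildArticulatedModel(sys, spec2)
  ref <- model@ligandTorsions[[1L]]$ref
  set.seed(1)
  for (k in 1:50) {
    smp <- sampleActive(model, exitDist = 5)
    expect_true(smp@ligTorsions >= -pi / 6 - ref - 1e-9)
    expect_true(smp@ligTorsions <= pi / 6 - ref + 1e-9)
  }
})

test_that("amc validation errors: backbone flag, bad serials, ring bonds", {
  sys <- parseSystem(c(residuesPDB("LYS"), phenolPDB(100L, c(30, 0, 0))))
  expect_error(parseAMC(c("molecule protein A", "LYS A:1 1 1"), sys),
               "only the side-chains")
  expect_error(parseAMC(c("molecule ligand IPH B:301",
                          "900 901 902 903 -180 180"), sys),
               "serial")
  # phenol ring bond as dihedral middle: rejected
  ser <- atoms(sys)$serial[ligandAtoms(sys)]
  expect_error(parseAMC(c("molecule ligand IPH B:301",
                          paste(ser[6L], ser[1L], ser[2L], ser[3L],
                                "-180 180")), sys),
               "not acyclic")
  expect_warning(parseAMC(c("molecule protein A", "HIS A:1 0 0"), sys),
                 "type mismatch")
})

test_that("all side-chain flags 0 gives a model with zero passive DOFs", {
  fx <- makeChannelFixture(gate = TRUE, gateFlexible = FALSE)
  model <- buildArticulatedModel(fx$system, fx$spec)
  expect_equal(nPassiveDOFs(model), 0L)
  expect_equal(nActiveDOFs(model), 6L)
})
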