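lysPhePhenol <- function() {
  sys <- parseSystem(c(residuesPDB(c("LYS", "PHE")), phenolPDB(100L, c(30, 0, 0))))
  list(sys = sys, model = buildArticulatedModel(sys, defaultFlexibilitySpec(sys)))
}

test_that("side-chain DOF enumeration: lysine 4, phenylalanine 2, rings none", {
  m <- lysPhePhenol()$model
  res <- vapply(m@passiveTorsions, `[[`, "", "residue")
  expect_equal(sum(res == "A:1"), 4L)       # LYS: CA-CB ... CD-CE
  expect_equal(sum(res == "A:2"), 2L)       # PHE: CA-CB, CB-CG only
  a <- atoms(m@system)
  axisNames <- t(vapply(m@passiveTorsions, function(t)
    a$name[t$axis], character(2)))
  expect_setequal(paste(axisNames[res == "A:1", 1L],
                        axisNames[res == "A:1", 2L]),
                  c("CA CB", "CB CG", "CG CD", "CD CE"))
  expect_setequal(paste(axisNames[res == "A:2", 1L],
                        axisNames[res == "A:2", 2L]),
                  c("CA CB", "CB CG"))
})

test_that("rigid ligand with all flags 0 leaves 6 active and 0 passive DOFs", {
  sys <- parseSystem(c(residuesPDB(c("LYS", "PHE")), phenolPDB(100L, c(30, 0, 0))))
  amc <- c("molecule protein A", "LYS A:1 0 0", "PHE A:2 0 0",
           "molecule ligand IPH B:301")
  model <- buildArticulatedModel(sys, parseAMC(amc, sys))
  expect_equal(nActiveDOFs(model), 6L)
  expect_equal(nPassiveDOFs(model), 0L)
})

test_that("identity conformation reproduces the input coordinates exactly", {
  m <- lysPhePhenol()$model
  expect_identical(forwardKinematics(m, identityConformation(m)), m@refCoords)
})

test_that("pure pose translation shifts every ligand atom, nothing else", {
  m <- lysPhePhenol()$model
  conf <- newConformation(m, trans = c(1, 0, 0))
  X <- forwardKinematics(m, conf)
  lig <- ligandAtoms(m)
  expect_equal(X[lig, ], m@refCoords[lig, ] + rep(c(1, 0, 0), each = length(lig)))
  rec <- setdiff(seq_len(nAtoms(m)), lig)
  expect_identical(X[rec, ], m@refCoords[rec, ])
})

test_that("a single torsion matches the rotation-matrix oracle and is local", {
  m <- lysPhePhenol()$model
  k <- which(vapply(m@passiveTorsions, `[[`, "", "residue") == "A:1")[2L]
  tor <- m@passiveTorsions[[k]]
  v <- pi
  pas <- numeric(nPassiveDOFs(m)); pas[k] <- v
  X <- forwardKinematics(m, newConformation(m, passive = pas))
  for (i in tor$distal)         # rotation by +v about proximal->distal
    expect_equal(X[i, ],
                 oracleRotate(m@refCoords[i, ], m@refCoords[tor$axis[1L], ],
                              m@refCoords[tor$axis[2L], ] -
                                m@refCoords[tor$axis[1L], ], v),
                 tolerance = 1e-9)
  untouched <- setdiff(seq_len(nAtoms(m)), tor$distal)
  expect_identical(X[untouched, ], m@refCoords[untouched, ])
})

test_that("rigid-group geometry and torsion values survive random conformations", {
  m <- lysPhePhenol()$model
  sys <- m@system
  pieceOf <- m@pieces
  lig <- ligandAtoms(m)
  set.seed(42)
  for (rep in 1:40) {
    conf <- newConformation(
      m, trans = stats::runif(3, -5, 5), quat = quatRandom(),
      ligTorsions = numeric(0),
      passive = stats::runif(nPassiveDOFs(m), -pi, pi))
    X <- forwardKinematics(m, conf)
    # intra-piece distances conserved (sampled pairs within each piece)
    for (p in unique(pieceOf)) {
      idx <- which(pieceOf == p)
      if (length(idx) < 2L) next
      i <- idx[1L]
      for (j in idx[-1L])
        expect_equal(sqrt(sum((X[i, ] - X[j, ])^2)),
                     sqrt(sum((m@refCoords[i, ] - m@refCoords[j, ])^2)),
                     tolerance = 1e-6)
    }
    # measured dihedral recovers input + offset (mod 2pi)
    for (k in seq_len(nPassiveDOFs(m))) {
      tor <- m@passiveTorsions[[k]]
      got <- measureDihedral(X[tor$atoms[1L], ], X[tor$atoms[2L], ],
                             X[tor$atoms[3L], ], X[tor$atoms[4L], ])
      expect_equal(wrapAngle(got - tor$ref - conf@passive[k]), 0,
                   tolerance = 1e-6)
    }
  }
})

test_that("interpolation: endpoints, wrapped torsions, antipodal quaternions", {
  m <- lysPhePhenol()$model
  a <- newConformation(m, trans = c(1, 2, 3), quat = quatRandomSeeded(1),
                       passive = rep(0.3, nPassiveDOFs(m)))
  b <- newConformation(m, trans = c(-2, 0, 1), quat = quatRandomSeeded(2),
                       passive = rep(-0.4, nPassiveDOFs(m)))
  expect_equal(interpolateConformations(m, a, b, 0)@trans, a@trans)
  # t = 1 recovers b's rotation (possibly as the sign-flipped
  # representative of the same rotation)
  expect_equal(quatAngle(interpolateConformations(m, a, b, 1)@quat, b@quat),
               0, tolerance = 1e-6)
  # shorter-arc wrap: 170 deg to -170 deg via 180
  a2 <- newConformation(m, passive = c(170 * pi / 180,
                                       rep(0, nPassiveDOFs(m) - 1L)))
  b2 <- newConformation(m, passive = c(-170 * pi / 180,
                                       rep(0, nPassiveDOFs(m) - 1L)))
  mid <- interpolateConformations(m, a2, b2, 0.5)
  expect_equal(abs(mid@passive[1L]), pi, tolerance = 1e-12)
  # antipodal representative: slerp(q, -q) stays put (angle 0)
  q <- quatRandomSeeded(3)
  s <- quatSlerp(q, -q, 0.5)
  expect_equal(quatAngle(q, s), 0, tolerance = 1e-9)
})

test_that("changing one side-chain DOF moves only that DOF's distal atoms", {
  m <- lysPhePhenol()$model
  for (k in seq_len(nPassiveDOFs(m))) {
    pas <- numeric(nPassiveDOFs(m)); pas[k] <- 0.7
    X <- forwardKinematics(m, newConformation(m, passive = pas))
    moved <- which(rowSums((X - m@refCoords)^2) > 1e-18)
    # on-axis distal atoms may not move numerically
    expect_true(all(moved %in% m@passiveTorsions[[k]]$distal))
    expect_true(length(moved) > 0L)
  }
})
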