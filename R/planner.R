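## ML-RRT unbinding planner. The tree grows over the active variables
## (ligand pose + ligand torsions); passive side-chain torsions are
## recruited only when a collision involving a flexible side-chain blocks
## an extension. Scaled vdW clash avoidance is the only feasibility
## condition; the goal is a ligand-center-to-receptor-center distance
## beyond the exit distance.

#' Planner configuration
#'
#' Defaults: 75% van der Waals radii, RRT-Connect expansion, automatic
#' exit distance, node exhaustion after 50 consecutive failures.
#'
#' @param vdwFraction collision threshold fraction in (0, 1].
#' @param nPaths number of independent solutions requested (runs use seeds
#'   `rngSeed + 0 ... nPaths - 1`). More than 20 triggers a warning.
#' @param strategy `"connect"` (repeat steps toward the sample until
#'   blocked or reached) or `"extend"` (a single step per iteration).
#' @param exitDistance goal center-center distance in Angstrom, or
#'   `"auto"` to use [computeExitDistance()].
#' @param nFailMax consecutive expansion failures after which a tree node
#'   is exhausted and no longer selected.
#' @param maxIterations iteration budget per run.
#' @param rngSeed integer seed; identical seed + config reproduces the run
#'   bit-for-bit.
#' @param stepSize cap on the ligand-displacement bound of one active
#'   step (Angstrom).
#' @param edgeResolution max atom-displacement bound between successive
#'   collision checks along an edge (Angstrom).
#' @param passiveTrials random perturbations attempted per blocking
#'   residue set.
#' @param passiveSigma std. dev. of Gaussian torsion perturbations (rad).
#' @param cascadeDepth how many times blocked side-chains may recruit
#'   further side-chains.
#' @param check14 whether 1-4 bonded pairs are collision-checked.
#' @param exitMargin margin added by the automatic exit distance (Angstrom).
#' @return a validated named list of class `plannerConfig`.
#' @export
plannerConfig <- function(vdwFraction = 0.75, nPaths = 1L,
                          strategy = c("connect", "extend"),
                          exitDistance = "auto", nFailMax = 50L,
                          maxIterations = 50000L, rngSeed = 1L,
                          stepSize = 1.0, edgeResolution = 0.5,
                          passiveTrials = 10L, passiveSigma = 0.4,
                          cascadeDepth = 3L, check14 = TRUE,
                          exitMargin = 2.0) {
  strategy <- match.arg(strategy)
  stopifnot(vdwFraction > 0, vdwFraction <= 1, nPaths >= 1L, nFailMax >= 1L,
            maxIterations >= 1L, stepSize > 0, edgeResolution > 0)
  if (nPaths > 20L)
    warning("more than 20 paths requested; expect long run times")
  structure(list(
    vdwFraction = vdwFraction, nPaths = as.integer(nPaths),
    strategy = strategy, exitDistance = exitDistance,
    nFailMax = as.integer(nFailMax),
    maxIterations = as.integer(maxIterations),
    rngSeed = as.integer(rngSeed), stepSize = stepSize,
    edgeResolution = edgeResolution,
    passiveTrials = as.integer(passiveTrials), passiveSigma = passiveSigma,
    cascadeDepth = as.integer(cascadeDepth), check14 = check14,
    exitMargin = exitMargin), class = "plannerConfig")
}

#' Automatic exit distance
#'
#' `R_receptor + R_ligand + margin`, where `R_X` is the maximum over X's
#' atoms of (distance from X's geometric center + the atom's vdW radius).
#' Beyond this center-center separation the two vdW envelopes cannot
#' overlap, with `margin` Angstrom to spare.
#'
#' @param system a [MolecularSystem-class] with a mobile ligand selected.
#' @param margin additional separation (Angstrom).
#' @return distance in Angstrom.
#' @export
computeExitDistance <- function(system, margin = 2.0) {
  xyz <- coords(system)
  lig <- system@ligand
  rec <- setdiff(seq_len(nAtoms(system)), lig)
  vdw <- system@atoms$vdw
  rOf <- function(idx) {
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    max(sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2L, ctr)^2)) + vdw[idx])
  }
  rOf(rec) + rOf(lig) + margin
}

## per-model sampling context: receptor bounding box inflated by the exit
## distance, ligand torsion offset bounds
samplingContext <- function(model, exitDist) {
  rec <- setdiff(seq_len(nAtoms(model@system)), model@system@ligand)
  xyz <- model@refCoords[rec, , drop = FALSE]
  lower <- apply(xyz, 2L, min) - exitDist
  upper <- apply(xyz, 2L, max) + exitDist
  lt <- model@ligandTorsions
  lo <- vapply(lt, `[[`, 0, "lower"); hi <- vapply(lt, `[[`, 0, "upper")
  ref <- vapply(lt, `[[`, 0, "ref")
  fc <- fullCircle(lo, hi)
  offLo <- ifelse(fc, -pi, lo - ref)
  offHi <- ifelse(fc, pi, hi - ref)
  list(boxLower = lower, boxUpper = upper, offLo = offLo, offHi = offHi,
       fullCircle = fc)
}

#' Sample random active variables
#'
#' Translation uniform over the receptor bounding box inflated by the exit
#' distance; orientation uniform over unit quaternions (Shoemake);
#' ligand torsions uniform within their bounds.
#'
#' @param model an [ArticulatedModel-class].
#' @param ctx sampling context from the planner (or `NULL` to build one
#'   from `exitDist`).
#' @param exitDist exit distance used to inflate the box when `ctx` is
#'   `NULL`.
#' @return a [Conformation-class] (passive values zero).
#' @export
sampleActive <- function(model, ctx = NULL, exitDist = NULL) {
  if (is.null(ctx)) {
    if (is.null(exitDist)) exitDist <- computeExitDistance(model@system)
    ctx <- samplingContext(model, exitDist)
  }
  target <- ctx$boxLower + stats::runif(3) * (ctx$boxUpper - ctx$boxLower)
  nlt <- length(model@ligandTorsions)
  tor <- if (nlt) ctx$offLo + stats::runif(nlt) * (ctx$offHi - ctx$offLo)
         else numeric(0)
  newConformation(model, trans = target - model@ligandCenter,
                  quat = quatRandom(), ligTorsions = tor)
}

## ---- internal planner machinery ------------------------------------

## residue key of the flexible side-chain owning each atom ("" if none)
flexResidueOfAtoms <- function(model) {
  out <- character(nAtoms(model@system))
  for (tor in model@passiveTorsions) out[tor$distal] <- tor$residue
  out
}

passiveDofsOfResidue <- function(model) {
  res <- vapply(model@passiveTorsions, `[[`, "", "residue")
  split(seq_along(res), res)
}

## flexible residues involved in a clash table; attr "hopeless" marks
## clash pairs that no side-chain can fix (neither atom flexible)
blockingResidues <- function(cl, flexOf) {
  ri <- flexOf[cl$i]; rj <- flexOf[cl$j]
  hopeless <- !nzchar(ri) & !nzchar(rj)
  res <- unique(c(ri[nzchar(ri)], rj[nzchar(rj)]))
  attr(res, "hopeless") <- any(hopeless)
  res
}

## active-space distance from one conformation to a matrix of node
## features (vectorized over nodes)
activeDistToNodes <- function(model, smp, TR, Q, LT, ctx) {
  dtr <- sqrt((TR[, 1L] - smp@trans[1L])^2 + (TR[, 2L] - smp@trans[2L])^2 +
                (TR[, 3L] - smp@trans[3L])^2)
  dq <- 2 * acos(pmin(1, abs(Q %*% smp@quat)))
  d <- dtr + dq * model@ligandCircumradius
  if (length(model@ligandTorsions)) {
    circ <- vapply(model@ligandTorsions, `[[`, 0, "circumradius")
    for (k in seq_along(circ)) {
      dk <- LT[, k] - smp@ligTorsions[k]
      if (ctx$fullCircle[k]) dk <- wrapAngle(dk)
      d <- d + abs(dk) * circ[k]
    }
  }
  as.numeric(d)
}

## interpolate only the active part from conf a toward sample s by
## fraction t, keeping a's passive values
stepActive <- function(model, a, s, t, ctx) {
  dl <- numeric(length(a@ligTorsions))
  if (length(dl)) {
    dl <- s@ligTorsions - a@ligTorsions
    dl[ctx$fullCircle] <- wrapAngle(dl[ctx$fullCircle])
  }
  ligv <- a@ligTorsions + t * dl
  ligv[ctx$fullCircle] <- wrapAngle(ligv[ctx$fullCircle])
  new("Conformation", trans = a@trans + t * (s@trans - a@trans),
      quat = quatSlerp(a@quat, s@quat, t),
      ligTorsions = ligv, passive = a@passive)
}

## collision-validate the straight edge a -> b at the same subdivision
## the output discretization will use, so every later frame is a checked
## conformation; returns list(ok, coords of b) or the blocking clashes
validateEdge <- function(model, a, b, settings, edgeResolution) {
  pts <- subdivideEdge(model, a, b, edgeResolution)
  lastCoords <- NULL
  for (k in seq_along(pts)) {
    X <- forwardKinematics(model, pts[[k]])
    cl <- detectClashes(X, settings)
    if (nrow(cl))
      return(list(ok = FALSE, clashes = cl, conf = pts[[k]]))
    lastCoords <- X
  }
  list(ok = TRUE, coords = lastCoords)
}

## try to clear the clashes of conformation (activeOf(cand), basePassive)
## by randomly perturbing the blocking residues' torsions; cascading
## recruitment up to cfg$cascadeDepth. Returns a clash-free Conformation
## (not yet edge-validated) or NULL.
tryPassiveResolution <- function(model, parent, cand, settings, cfg,
                                 flexOf, dofsOf) {
  X <- forwardKinematics(model, cand)
  cl <- detectClashes(X, settings)
  if (!nrow(cl)) return(cand)
  S <- blockingResidues(cl, flexOf)
  if (attr(S, "hopeless") || !length(S)) return(NULL)
  S <- as.character(S)
  depth <- 0L
  repeat {
    lastCl <- NULL
    for (trial in seq_len(cfg$passiveTrials)) {
      pass <- parent@passive
      for (r in S) {
        k <- dofsOf[[r]]
        pass[k] <- wrapAngle(pass[k] + stats::rnorm(length(k), 0,
                                                    cfg$passiveSigma))
      }
      confTry <- new("Conformation", trans = cand@trans, quat = cand@quat,
                     ligTorsions = cand@ligTorsions, passive = pass)
      cl2 <- detectClashes(forwardKinematics(model, confTry), settings)
      if (!nrow(cl2)) return(confTry)
      lastCl <- cl2
    }
    if (depth >= cfg$cascadeDepth || is.null(lastCl)) return(NULL)
    S2 <- blockingResidues(lastCl, flexOf)
    if (attr(S2, "hopeless")) return(NULL)
    newRes <- setdiff(as.character(S2), S)
    if (!length(newRes)) return(NULL)
    S <- c(S, newRes)
    depth <- depth + 1L
  }
}

#' Resolve clashes in the input conformation
#'
#' Input structures frequently contain scaled-vdW overlaps. This
#' preprocessing step perturbs only the side-chain torsions of residues
#' involved in the clashes (uniform steps of at most `maxStep` radians per
#' trial, hill-climbing on the clash count) until the conformation is
#' clash-free. Overlaps between two static atoms, or involving no
#' flexible side-chain, cannot be resolved this way and raise an error
#' suggesting a reduced van der Waals percentage.
#'
#' @param model an [ArticulatedModel-class].
#' @param conf0 starting [Conformation-class] (default identity).
#' @param config a [plannerConfig()].
#' @param maxTrials iteration budget.
#' @param maxStep largest single-trial perturbation (radians).
#' @return a clash-free [Conformation-class]; `conf0` itself when it has
#'   no clashes. The clash-resolution summary is attached as attribute
#'   `"summary"`.
#' @export
resolveInitialClashes <- function(model, conf0 = identityConformation(model),
                                  config = plannerConfig(),
                                  maxTrials = 200L, maxStep = 0.3) {
  so <- staticOverlaps(model, config$vdwFraction)
  if (nrow(so)) {
    ser <- model@system@atoms$serial
    stop("unresolvable error: overlapping static atoms in the input: ",
         paste(ser[so$i], "-", ser[so$j], collapse = ", "),
         "; no degree of freedom can separate them")
  }
  settings <- collisionSettings(model, config$vdwFraction, config$check14)
  cl <- detectClashes(forwardKinematics(model, conf0), settings)
  if (!nrow(cl)) {
    attr(conf0, "summary") <- "input conformation clash-free; unchanged"
    return(conf0)
  }
  flexOf <- flexResidueOfAtoms(model)
  dofsOf <- passiveDofsOfResidue(model)
  withSeed(config$rngSeed, {
    best <- conf0
    bestCl <- cl
    for (iter in seq_len(maxTrials)) {
      S <- blockingResidues(bestCl, flexOf)
      if (attr(S, "hopeless") || !length(S)) {
        ser <- model@system@atoms$serial
        bad <- bestCl[!nzchar(flexOf[bestCl$i]) & !nzchar(flexOf[bestCl$j]), ]
        stop("preprocessing-failure error: input clashes involve no ",
             "flexible side-chain (e.g. atoms ",
             if (nrow(bad)) paste(ser[bad$i[1L]], "-", ser[bad$j[1L]]) else "",
             "); resubmit the job with a reduced percentage of van der ",
             "Waals radii")
      }
      trial <- best
      for (r in as.character(S)) {
        k <- dofsOf[[r]]
        trial@passive[k] <- wrapAngle(trial@passive[k] +
                                        stats::runif(length(k), -maxStep,
                                                     maxStep))
      }
      cl2 <- detectClashes(forwardKinematics(model, trial), settings)
      if (nrow(cl2) < nrow(bestCl)) {
        best <- trial
        bestCl <- cl2
      }
      if (nrow(bestCl) == 0L) {
        attr(best, "summary") <- sprintf(
          "resolved %d initial clash(es) in %d trial(s)", nrow(cl), iter)
        return(best)
      }
    }
    stop("preprocessing-failure error: ", nrow(bestCl), " clash(es) remain ",
         "after ", maxTrials, " perturbation trials; resubmit the job with ",
         "a reduced percentage of van der Waals radii")
  })
}

#' Plan a ligand unbinding path
#'
#' Runs one ML-RRT search from `conf0` until some tree node's ligand
#' center lies at least the exit distance from the receptor center, the
#' iteration budget is exhausted, or every node is exhausted. Every tree
#' edge is collision-validated at the configured resolution, so a returned
#' path is collision-free throughout.
#'
#' @param model an [ArticulatedModel-class].
#' @param conf0 clash-free starting conformation (run
#'   [resolveInitialClashes()] first if unsure).
#' @param config a [plannerConfig()].
#' @return a [SolutionPath-class]; `diagnostics(x)$success` tells whether
#'   the goal was reached (a failed search returns the diagnostics, not an
#'   error). Frames are empty until [discretizePath()].
#' @export
planUnbinding <- function(model, conf0 = identityConformation(model),
                          config = plannerConfig()) {
  settings <- collisionSettings(model, config$vdwFraction, config$check14)
  X0 <- forwardKinematics(model, conf0)
  if (nrow(detectClashes(X0, settings)))
    stop("planUnbinding requires a clash-free start; run ",
         "resolveInitialClashes() first")
  exitDist <- if (identical(config$exitDistance, "auto"))
    computeExitDistance(model@system, config$exitMargin)
  else as.numeric(config$exitDistance)
  ctx <- samplingContext(model, exitDist)
  flexOf <- flexResidueOfAtoms(model)
  dofsOf <- passiveDofsOfResidue(model)
  nlt <- length(model@ligandTorsions)

  ## tree state (preallocated, grown geometrically)
  cap <- 256L
  confs <- vector("list", cap)
  parent <- integer(cap)
  fails <- integer(cap)
  exhausted <- logical(cap)
  TR <- matrix(0, cap, 3L); Q <- matrix(0, cap, 4L)
  LT <- matrix(0, cap, max(1L, nlt))
  centers <- matrix(0, cap, 3L)
  nNodes <- 0L
  addNode <- function(conf, par, center) {
    if (nNodes == cap) {
      cap <<- cap * 2L
      length(confs) <<- cap; length(parent) <<- cap
      length(fails) <<- cap; length(exhausted) <<- cap
      TR <<- rbind(TR, matrix(0, cap / 2L, 3L))
      Q <<- rbind(Q, matrix(0, cap / 2L, 4L))
      LT <<- rbind(LT, matrix(0, cap / 2L, ncol(LT)))
      centers <<- rbind(centers, matrix(0, cap / 2L, 3L))
    }
    nNodes <<- nNodes + 1L
    confs[[nNodes]] <<- conf
    parent[nNodes] <<- par
    fails[nNodes] <<- 0L
    exhausted[nNodes] <<- FALSE
    TR[nNodes, ] <<- conf@trans
    Q[nNodes, ] <<- conf@quat
    if (nlt) LT[nNodes, seq_len(nlt)] <<- conf@ligTorsions
    centers[nNodes, ] <<- center
    nNodes
  }

  recCenter <- model@receptorCenter
  goalReached <- function(center) sqrt(sum((center - recCenter)^2)) >= exitDist
  buildPath <- function(goalIdx, iter, reason) {
    idx <- goalIdx
    chain <- integer(0)
    while (idx != 0L) {
      chain <- c(idx, chain)
      idx <- parent[idx]
    }
    new("SolutionPath", nodeConfs = confs[chain],
        diagnostics = list(
          success = TRUE, reason = reason, seed = config$rngSeed,
          iterations = iter, nodesCreated = nNodes,
          nodesExhausted = sum(exhausted[seq_len(nNodes)]),
          finalDistance = sqrt(sum((centers[goalIdx, ] - recCenter)^2)),
          exitDistance = exitDist, strategy = config$strategy,
          vdwFraction = config$vdwFraction))
  }

  withSeed(config$rngSeed, {
    addNode(conf0, 0L, colMeans(X0[model@system@ligand, , drop = FALSE]))
    if (goalReached(centers[1L, ]))
      return(buildPath(1L, 0L, "start beyond exit distance"))

    for (iter in seq_len(config$maxIterations)) {
      live <- which(!exhausted[seq_len(nNodes)])
      if (!length(live)) {
        return(new("SolutionPath", nodeConfs = list(conf0),
                   diagnostics = list(
                     success = FALSE, reason = "all nodes exhausted",
                     seed = config$rngSeed, iterations = iter,
                     nodesCreated = nNodes,
                     nodesExhausted = sum(exhausted[seq_len(nNodes)]),
                     finalDistance = max(sqrt(rowSums(
                       sweep(centers[seq_len(nNodes), , drop = FALSE], 2L,
                             recCenter)^2))),
                     exitDistance = exitDist, strategy = config$strategy,
                     vdwFraction = config$vdwFraction)))
      }
      smp <- sampleActive(model, ctx)
      d <- activeDistToNodes(model, smp,
                             TR[live, , drop = FALSE],
                             Q[live, , drop = FALSE],
                             LT[live, , drop = FALSE], ctx)
      sel <- live[which.min(d)]
      cur <- sel
      advanced <- FALSE
      repeat {
        a <- confs[[cur]]
        D <- activeDisplacementBound(model, a, smp)
        if (D < 1e-8) break
        t <- min(1, config$stepSize / D)
        cand <- stepActive(model, a, smp, t, ctx)
        ev <- validateEdge(model, a, cand, settings, config$edgeResolution)
        if (!ev$ok) {
          resolved <- tryPassiveResolution(model, a, cand, settings, config,
                                           flexOf, dofsOf)
          ok2 <- FALSE
          if (!is.null(resolved)) {
            ev2 <- validateEdge(model, a, resolved, settings,
                                config$edgeResolution)
            if (ev2$ok) {
              cand <- resolved
              ev <- ev2
              ok2 <- TRUE
            }
          }
          if (!ok2) break
        }
        center <- colMeans(ev$coords[model@system@ligand, , drop = FALSE])
        cur <- addNode(cand, cur, center)
        advanced <- TRUE
        if (goalReached(center))
          return(buildPath(cur, iter, "exit distance reached"))
        if (t >= 1 || config$strategy == "extend") break
      }
      if (advanced) {
        fails[sel] <- 0L
      } else {
        fails[sel] <- fails[sel] + 1L
        if (fails[sel] >= config$nFailMax) exhausted[sel] <- TRUE
      }
    }
    new("SolutionPath", nodeConfs = list(conf0),
        diagnostics = list(
          success = FALSE, reason = "budget exhausted",
          seed = config$rngSeed, iterations = config$maxIterations,
          nodesCreated = nNodes,
          nodesExhausted = sum(exhausted[seq_len(nNodes)]),
          finalDistance = max(sqrt(rowSums(
            sweep(centers[seq_len(nNodes), , drop = FALSE], 2L,
                  recCenter)^2))),
          exitDistance = exitDist, strategy = config$strategy,
          vdwFraction = config$vdwFraction))
  })
}

#' @rdname planUnbinding
#' @param x a [SolutionPath-class].
#' @export
diagnostics <- function(x) x@diagnostics

#' @rdname planUnbinding
#' @export
nodeConformations <- function(x) x@nodeConfs
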