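# Independent brute-force oracles, deliberately written with plain loops
# so they share no code path with the implementation they check.

# O(n^2) distance-threshold bond oracle
oracleBonds <- function(xyz, covr, molecule, tolerance = 0.45) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (molecule[i] != molecule[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= covr[i] + covr[j] + tolerance && d > 0.4)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

# is bond k a bridge? BFS connectivity after deleting the edge
oracleIsBridge <- function(bondsMat, n, k) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bondsMat))) {
    if (r == k) next
    i <- bondsMat[r, 1L]; j <- bondsMat[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  from <- bondsMat[k, 1L]; to <- bondsMat[k, 2L]
  seen <- logical(n); seen[from] <- TRUE; queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  !seen[to]
}

# O(n^2) clash oracle over an explicit candidate-pair predicate
oracleClashes <- function(xyz, radii, fraction, isCandidate = NULL) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.null(isCandidate) && !isCandidate(i, j)) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < fraction * (radii[i] + radii[j])) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

# candidate-pair predicate matching the model's exclusion rules, derived
# independently from the bond list
modelPairPredicate <- function(model) {
  sys <- model@system
  n <- nAtoms(sys)
  b <- sys@bonds
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1L]]] <- c(adj[[b[r, 1L]]], b[r, 2L])
    adj[[b[r, 2L]]] <- c(adj[[b[r, 2L]]], b[r, 1L])
  }
  moving <- logical(n); moving[model@movingAtoms] <- TRUE
  function(i, j) {
    if (!moving[i] && !moving[j]) return(FALSE)
    if (model@pieces[i] == model@pieces[j]) return(FALSE)
    if (j %in% adj[[i]]) return(FALSE)                       # 1-2
    if (length(intersect(adj[[i]], adj[[j]]))) return(FALSE) # 1-3
    TRUE
  }
}

# Rodrigues rotation built from the explicit 3x3 matrix (independent of
# the vectorized implementation)
oracleRotate <- function(p, origin, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3L,
              byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  as.numeric(R %*% (p - origin) + origin)
}

sortPairs <- function(m) {
  m <- matrix(as.integer(m), ncol = 2L)
  unname(m[order(m[, 1L], m[, 2L]), , drop = FALSE])
}

quatRandomSeeded <- function(seed) {
  set.seed(seed)
  quatRandom()
}

# max ligand displacement between two coordinate sets
maxDisp <- function(X1, X2, idx) {
  m <- 0
  for (i in idx) m <- max(m, sqrt(sum((X1[i, ] - X2[i, ])^2)))
  m
}
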