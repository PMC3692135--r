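## Small geometric kernel: wrapped angles, quaternions, axis rotations,
## dihedrals. Conventions: quaternions are length-4 numeric (w, x, y, z),
## unit norm; angles in radians.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles (radians).
#' @return numeric vector with each value mapped into `(-pi, pi]`.
#' @export
wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi   # map -pi to +pi so the interval is half-open
  y
}

## shortest signed angular difference b - a, in (-pi, pi]
angleDiff <- function(a, b) wrapAngle(b - a)

#' Quaternion utilities
#'
#' `quatIdentity()` returns the identity rotation; `quatNormalize()` rescales
#' to unit norm; `quatMultiply()` composes rotations (Hamilton product);
#' `quatRotationMatrix()` converts to a 3x3 rotation matrix; `quatAngle()`
#' gives the geodesic angle between two unit quaternions (double cover
#' folded, so the result is in `[0, pi]`); `quatSlerp()` interpolates along
#' the shorter arc; `quatRandom()` draws a uniformly distributed rotation.
#'
#' @param q,q1,q2 length-4 numeric quaternions `(w, x, y, z)`.
#' @param t interpolation fraction in `[0, 1]`.
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quatIdentity <- function() c(1, 0, 0, 0)

#' @rdname quaternions
#' @export
quatNormalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize zero quaternion")
  q / n
}

#' @rdname quaternions
#' @export
quatMultiply <- function(q1, q2) {
  w1 <- q1[1L]; x1 <- q1[2L]; y1 <- q1[3L]; z1 <- q1[4L]
  w2 <- q2[1L]; x2 <- q2[2L]; y2 <- q2[3L]; z2 <- q2[4L]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' @rdname quaternions
#' @export
quatRotationMatrix <- function(q) {
  q <- quatNormalize(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
}

#' @rdname quaternions
#' @export
quatAngle <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

#' @rdname quaternions
#' @export
quatSlerp <- function(q1, q2, t) {
  d <- sum(q1 * q2)
  if (d < 0) {        # antipodal representative: take the shorter arc
    q2 <- -q2
    d <- -d
  }
  d <- min(1, d)
  theta <- acos(d)
  if (theta < 1e-9) return(quatNormalize(q1 + t * (q2 - q1)))
  s <- sin(theta)
  quatNormalize((sin((1 - t) * theta) / s) * q1 + (sin(t * theta) / s) * q2)
}

#' @rdname quaternions
#' @export
quatRandom <- function() {
  # Shoemake's subgroup algorithm: uniform over SO(3)
  u <- stats::runif(3)
  s1 <- sqrt(1 - u[1L]); s2 <- sqrt(u[1L])
  t1 <- 2 * pi * u[2L]; t2 <- 2 * pi * u[3L]
  c(s2 * cos(t2), s1 * sin(t1), s1 * cos(t1), s2 * sin(t2))
}

#' Rotate points about an axis
#'
#' Rodrigues rotation of a set of points about the axis through `origin`
#' with direction `axis`, by `theta` radians (right-handed).
#'
#' @param pts n x 3 numeric matrix of coordinates.
#' @param origin length-3 point on the axis.
#' @param axis length-3 direction vector (need not be unit).
#' @param theta rotation angle, radians.
#' @return n x 3 matrix of rotated coordinates.
#' @export
rotateAboutAxis <- function(pts, origin, axis, theta) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  k <- axis / n
  p <- sweep(pts, 2L, origin)
  ct <- cos(theta); st <- sin(theta)
  kx <- k[2L] * p[, 3L] - k[3L] * p[, 2L]
  ky <- k[3L] * p[, 1L] - k[1L] * p[, 3L]
  kz <- k[1L] * p[, 2L] - k[2L] * p[, 1L]
  kd <- p[, 1L] * k[1L] + p[, 2L] * k[2L] + p[, 3L] * k[3L]
  out <- cbind(
    p[, 1L] * ct + kx * st + k[1L] * kd * (1 - ct),
    p[, 2L] * ct + ky * st + k[2L] * kd * (1 - ct),
    p[, 3L] * ct + kz * st + k[3L] * kd * (1 - ct))
  sweep(out, 2L, origin, "+")
}

#' Measure a dihedral angle
#'
#' Signed torsion angle over four points, in `(-pi, pi]`, using the
#' standard atan2 formulation (IUPAC sign convention: looking from b to c,
#' positive is clockwise rotation of d relative to a).
#'
#' @param a,b,c,d length-3 coordinate vectors.
#' @return angle in radians.
#' @export
measureDihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  m1 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * m1
  wrapAngle(atan2(y, x))
}

## run expr with a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
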