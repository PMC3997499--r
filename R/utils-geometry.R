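## Small 3-d geometry helpers shared by the hydrogen builder and the
## synthetic-structure generators.  Everything works in Angstrom.

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rotation matrix for angle theta (radians) about unit axis k (Rodrigues)
.rotmat <- function(k, theta) {
  k <- .unit(k)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Place atom D given three reference positions A-B-C, bond |C-D|, angle
## B-C-D (deg) and dihedral A-B-C-D (deg).  Natural extension reference
## frame construction.
.placeInternal <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Optimal rotation (Kabsch) mapping coordinate set P onto Q (both n x 3,
## same correspondence).  Returns list(R, tP, tQ) with
## x_mapped = (x - tP) %*% R + tQ.
.kabsch <- function(P, Q) {
  tP <- colMeans(P)
  tQ <- colMeans(Q)
  Pc <- sweep(P, 2, tP)
  Qc <- sweep(Q, 2, tQ)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, tP = tP, tQ = tQ)
}

.applyKabsch <- function(X, k) {
  sweep(sweep(X, 2, k$tP) %*% k$R, 2, k$tQ, "+")
}

## Squared-distance matrix between two coordinate sets (n x 3, m x 3)
.dist2 <- function(X, Y) {
  outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
}

.distmat <- function(X, Y) sqrt(pmax(.dist2(X, Y), 0))

## Run an expression with a fixed RNG seed, restoring the caller's RNG
## state afterwards so generators never perturb user-level randomness.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
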