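## Solvent-accessible surface area by Shrake-Rupley sphere sampling with
## a deterministic generalized-spiral point set (no RNG involved).

#' Options for SASA computation
#'
#' @param probe_radius probe sphere radius in Angstrom (default 1.4).
#' @param n_sphere_points number of sample points per atom (default 960;
#'   at least 60).
#' @param surface_tension gamma, kcal/mol/A^2, for the nonpolar
#'   solvation term (default 0.0072).
#' @return a list of validated options.
#' @export
sasaOptions <- function(probe_radius = 1.4, n_sphere_points = 960,
                        surface_tension = 0.0072) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 60)
  list(probe_radius = probe_radius,
       n_sphere_points = as.integer(n_sphere_points),
       surface_tension = surface_tension)
}

## deterministic spiral points on the unit sphere
.spiralPoints <- function(n) {
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(pmax(h, -1), 1))
  phi <- (k - 1) * pi * (3 - sqrt(5))
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

## Point set invariant under 180-degree rotations about the coordinate
## axes (the proper part of the axis-flip group): a low-discrepancy seed
## on the quarter sphere {y > 0, z > 0} (uniform z, golden-ratio
## azimuth), orbited under {I, diag(1,-1,-1), diag(-1,1,-1),
## diag(-1,-1,1)}.
.symmetricSpiralPoints <- function(n) {
  m <- ceiling(n / 4)
  k <- seq_len(m)
  z <- (k - 0.5) / m
  phi <- pi * ((k * (sqrt(5) - 1) / 2) %% 1)
  r <- sqrt(pmax(0, 1 - z^2))
  q <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(q,
        q %*% diag(c(1, -1, -1)),
        q %*% diag(c(-1, 1, -1)),
        q %*% diag(c(-1, -1, 1)))
}

## Canonical molecular frame: covariance eigenvectors (descending
## eigenvalue order, right-handed).  Any remaining sign ambiguity is a
## 180-degree flip about a frame axis, under which the symmetric point
## set is invariant, so SASA is exactly invariant under rigid-body
## transforms of the input.
.canonicalFrame <- function(coords) {
  if (nrow(coords) < 3L) return(diag(3))
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  V <- ev$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley: each atom's accessible sphere (intrinsic radius +
#' probe) is sampled at `n_sphere_points` deterministic spiral points
#' (rounded up to a multiple of 4); a point is accessible when outside
#' every neighbour's accessible sphere.  The point set is oriented in a
#' canonical molecular frame (principal axes) and is invariant under
#' 180-degree flips about the frame axes, so the areas are exactly
#' invariant under rigid-body transforms of the input.  An isolated
#' atom's area is exact up to quadrature (4 pi (r + probe)^2).
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param radii per-atom intrinsic radii (A); the package convention is
#'   to use the intrinsic GB radii, hydrogens included.
#' @param options from [sasaOptions()].
#' @param frame optional 3 x 3 orientation matrix for the point set;
#'   defaults to the canonical frame of `coords`.  Complex-minus-monomer
#'   differences are computed with the complex's frame throughout so
#'   that quadrature cancels exactly for non-interacting partners.
#' @return numeric vector of per-atom areas in A^2.
#' @export
sasaAtoms <- function(coords, radii, options = sasaOptions(), frame = NULL) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1L) stop("need at least one atom")
  stopifnot(length(radii) == n, all(radii > 0))
  if (is.null(frame)) frame <- .canonicalFrame(coords)
  P0 <- .symmetricSpiralPoints(options$n_sphere_points) %*% t(frame)
  acc <- radii + options$probe_radius
  out <- numeric(n)
  ## neighbour lists from the squared-distance matrix
  d2 <- .dist2(coords, coords)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (acc[i] + acc)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * acc[i]^2
      next
    }
    pts <- sweep(P0 * acc[i], 2, coords[i, ], "+")
    D2 <- .dist2(pts, coords[nb, , drop = FALSE])
    lim <- matrix(acc[nb]^2, nrow(pts), length(nb), byrow = TRUE)
    free <- rowSums(D2 < lim) == 0L
    out[i] <- 4 * pi * acc[i]^2 * mean(free)
  }
  out
}
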