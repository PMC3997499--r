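## Independent brute-force oracles: scalar re-implementations of the
## energy terms, written as plain loops from the defining formulas.
## They share nothing with the package's vectorized code paths.

CE <- 332.0637

## HCT descreening integral of one neighbour, by numerical quadrature of
## the shell integral (not the analytic piecewise form the package uses)
oracleDescreenIntegral <- function(rho_i, s_rho_j, r) {
  a <- s_rho_j
  if (rho_i >= r + a) return(0)
  shell <- function(l) {
    ## fraction of the shell at radius l covered by the neighbour sphere
    mu <- (l^2 + r^2 - a^2) / (2 * l * r)
    0.5 / l^2 * (1 - mu)
  }
  I <- 0
  if (rho_i < a - r) {
    ## shells fully inside the neighbour sphere
    I <- I + integrate(function(l) 1 / l^2, rho_i, a - r,
                       rel.tol = 1e-12)$value
    lo <- a - r
  } else {
    lo <- max(rho_i, r - a)
  }
  I + integrate(Vectorize(shell), lo, r + a, rel.tol = 1e-12)$value
}

oracleBornRadii <- function(X, rad, scr, offset = 0.09, alpha = 1,
                            beta = 0.8, gamma = 4.85) {
  n <- nrow(X)
  rho <- rad - offset
  out <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      I <- I + oracleDescreenIntegral(rho[i], scr[j] * rho[j], r)
    }
    psi <- rho[i] * I
    out[i] <- 1 / (1 / rho[i] -
                   tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / rad[i])
  }
  out
}

oracleGBEnergy <- function(X, q, R, eps_in = 1, eps_out = 80, kappa = 0) {
  n <- nrow(X)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((X[i, ] - X[j, ])^2)
    f <- if (i == j) R[i] else
      sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    tau <- 1 / eps_in - exp(-kappa * f) / eps_out
    e <- e - 0.5 * CE * tau * q[i] * q[j] / f
  }
  e
}

## scalar Shrake-Rupley over an explicit point set
oracleSASA <- function(X, rad, probe, points) {
  n <- nrow(X)
  acc <- rad + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(points * acc[i], 2, X[i, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
        (pts[, 3] - X[j, 3])^2
      free <- free & d2 >= acc[j]^2
    }
    out[i] <- 4 * pi * acc[i]^2 * mean(free)
  }
  out
}

oracleInterNB <- function(X, q, rh, ep, ia, ib) {
  elec <- 0; vdw <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    elec <- elec + CE * q[i] * q[j] / r
    rmin <- rh[i] + rh[j]
    e <- sqrt(ep[i] * ep[j])
    vdw <- vdw + e * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  list(elec = elec, vdw = vdw)
}

## full effective binding energy of a toy system, assembled from the
## scalar pieces above (same deterministic SASA point set so quadrature
## cancels in the comparison)
oracleBindingEnergy <- function(sys, gb = gbOptions(), sasa = sasaOptions()) {
  X <- frameCoords(sys)
  p <- atomParams(sys)
  at <- atomData(sys)
  ia <- which(at$chain %in% sys@partition@partnerA)
  ib <- which(at$chain %in% sys@partition@partnerB)
  kappa <- gb$kappa_scale * sqrt(0.10806 * gb$ionic_strength)
  nb <- oracleInterNB(X, p$charge, p$rmin_half, p$eps, ia, ib)
  gbOf <- function(idx) {
    R <- oracleBornRadii(X[idx, , drop = FALSE], p$gb_radius[idx],
                         p$gb_screen[idx], gb$offset, gb$obc_alpha,
                         gb$obc_beta, gb$obc_gamma)
    oracleGBEnergy(X[idx, , drop = FALSE], p$charge[idx], R,
                   gb$eps_in, gb$eps_out, kappa)
  }
  ## complex-frame point set throughout (the package's convention)
  pts <- HotspotGBSA:::.symmetricSpiralPoints(sasa$n_sphere_points) %*%
    t(HotspotGBSA:::.canonicalFrame(X))
  saOf <- function(idx) sum(oracleSASA(X[idx, , drop = FALSE],
                                       p$gb_radius[idx],
                                       sasa$probe_radius, pts))
  all <- seq_len(nrow(X))
  nb$elec + nb$vdw +
    (gbOf(all) - gbOf(ia) - gbOf(ib)) +
    sasa$surface_tension * (saOf(all) - saOf(ia) - saOf(ib))
}
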