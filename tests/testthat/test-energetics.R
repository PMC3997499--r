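test_that("Born radii: isolated-atom limit and quadrature oracle", {
  ## zero descreening: R = rho - offset
  sys <- mkToySystem(matrix(0, 1, 3), charge = 1, gb_radius = 1.5)
  expect_equal(bornRadii(sys), 1.41, tolerance = 1e-9)

  ## two heterogeneous atoms vs numeric evaluation of the descreening
  ## integral
  X <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  rad <- c(1.59, 1.79); scr <- c(0.72, 0.96)
  sys2 <- mkToySystem(X, charge = c(0.3, -0.4), gb_radius = rad,
                      gb_screen = scr)
  expect_equal(bornRadii(sys2), oracleBornRadii(X, rad, scr),
               tolerance = 1e-8)

  ## overlapping spheres (r < s_j rho_j) exercise the deep-burial branch
  X3 <- rbind(c(0, 0, 0), c(0.9, 0, 0))
  sys3 <- mkToySystem(X3, charge = c(0, 0), gb_radius = c(1.2, 2.2),
                      gb_screen = c(0.85, 0.96))
  expect_equal(bornRadii(sys3),
               oracleBornRadii(X3, c(1.2, 2.2), c(0.85, 0.96)),
               tolerance = 1e-8)
})

test_that("burying an atom never shrinks its Born radius", {
  set.seed(42)
  centre <- matrix(0, 1, 3)
  shell <- matrix(rnorm(30 * 3), 30, 3)
  shell <- 3.5 * shell / sqrt(rowSums(shell^2))
  prev <- -Inf
  for (k in c(0, 5, 10, 20, 30)) {
    X <- rbind(centre, shell[seq_len(k), , drop = FALSE])
    sys <- mkToySystem(X, charge = rep(0, k + 1))
    R1 <- bornRadii(sys)[1]
    expect_gte(R1, prev - 1e-12)
    prev <- R1
  }
})

test_that("GB polar energy: analytic Born ion, null charges, share conservation", {
  opt <- gbOptions(ionic_strength = 0)
  ion <- mkToySystem(matrix(0, 1, 3), charge = 1, gb_radius = 2.09)
  expect_equal(gbPolarEnergy(ion, options = opt)$total,
               -0.5 * 332.0637 * (1 - 1 / 80) / 2,
               tolerance = 1e-6)

  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3.5, 0))
  zero <- mkToySystem(X, charge = c(0, 0, 0))
  expect_equal(gbPolarEnergy(zero, options = opt)$total, 0)

  chg <- mkToySystem(X, charge = c(0.5, -0.3, 0.8))
  g <- gbPolarEnergy(chg, options = opt)
  expect_equal(sum(g$atom), g$total, tolerance = 1e-12)
  ## and against the scalar oracle
  R <- oracleBornRadii(X, rep(1.7, 3), rep(0.8, 3))
  expect_equal(g$total, oracleGBEnergy(X, c(0.5, -0.3, 0.8), R),
               tolerance = 1e-8)
})

test_that("salt screening stabilizes a net-charged system monotonically", {
  X <- rbind(c(0, 0, 0), c(3, 0, 0))
  sys <- mkToySystem(X, charge = c(1, 1))
  e <- vapply(c(0, 0.05, 0.1, 0.3),
              function(I) gbPolarEnergy(sys, options = gbOptions(
                ionic_strength = I))$total, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("SASA: analytic sphere, pair symmetry, dense-sampling oracle", {
  ## isolated atom: 4 pi (1.6 + 1.4)^2
  a1 <- sasaAtoms(matrix(0, 1, 3), 1.6)
  expect_lt(abs(a1 - 4 * pi * 9) / (4 * pi * 9), 0.01)

  ## two identical overlapping spheres: equal areas by symmetry
  X2 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  a2 <- sasaAtoms(X2, c(1.7, 1.7))
  expect_equal(a2[1], a2[2], tolerance = 1e-9)

  ## 5-atom cluster vs high-density oracle, per atom within 0.5 A^2
  set.seed(7)
  X5 <- matrix(rnorm(15, sd = 1.4), 5, 3)
  rad5 <- c(1.5, 1.7, 1.2, 1.8, 1.55)
  got <- sasaAtoms(X5, rad5)
  dense <- HotspotGBSA:::.symmetricSpiralPoints(10000) %*%
    t(HotspotGBSA:::.canonicalFrame(X5))
  want <- oracleSASA(X5, rad5, 1.4, dense)
  expect_lt(max(abs(got - want)), 0.5)

  expect_error(sasaAtoms(matrix(0, 0, 3), numeric(0)), "at least one atom")
})

test_that("inter-partner nonbonded terms match closed forms", {
  X <- rbind(c(0, 0, 0), c(10, 0, 0))
  qq <- mkToySystem(X, charge = c(1, -1), rmin_half = 0, eps = 0,
                    chain = c("A", "B"))
  nb <- interNonbonded(qq)
  expect_equal(nb$e_elec, -332.0637 / 10, tolerance = 1e-9)
  expect_equal(nb$e_vdw, 0)

  lj <- mkToySystem(rbind(c(0, 0, 0), c(3.4, 0, 0)), charge = c(0, 0),
                    rmin_half = 1.7, eps = 0.2, chain = c("A", "B"))
  expect_equal(interNonbonded(lj)$e_vdw, -0.2, tolerance = 1e-12)

  far <- mkToySystem(rbind(c(0, 0, 0), c(500, 0, 0)), charge = c(1, -1),
                     rmin_half = 1.7, eps = 0.2, chain = c("A", "B"))
  nbf <- interNonbonded(far)
  expect_lt(abs(nbf$e_elec), 1e-3 + 332.0637 / 500)  # pure Coulomb decay
  expect_lt(abs(nbf$e_vdw), 1e-3)

  clash <- mkToySystem(rbind(c(0, 0, 0), c(0, 0, 0)), charge = c(1, 1),
                       chain = c("A", "B"))
  expect_error(interNonbonded(clash), "zero interatomic distance")

  ## per-atom half shares re-sum to the totals
  set.seed(3)
  Xr <- matrix(rnorm(24, sd = 4), 8, 3)
  sys <- mkToySystem(Xr, charge = runif(8, -1, 1),
                     chain = rep(c("A", "B"), each = 4))
  nbr <- interNonbonded(sys, ledger = TRUE)
  expect_equal(sum(nbr$atom_elec), nbr$e_elec, tolerance = 1e-12)
  expect_equal(sum(nbr$atom_vdw), nbr$e_vdw, tolerance = 1e-12)
  expect_equal(sum(nbr$pair_elec), nbr$e_elec, tolerance = 1e-12)
})

test_that("effective binding energy matches a brute-force oracle on toys", {
  ## two-residue toy dimer: 4 charged LJ atoms
  X <- rbind(c(0, 0, 0), c(3.6, 0, 0), c(1.8, 3.4, 0), c(1.8, 3.4, 3.6))
  sys <- mkToySystem(X, charge = c(0.4, -0.4, 0.5, -0.5),
                     rmin_half = c(1.9, 1.8, 1.7, 1.8),
                     eps = c(0.1, 0.12, 0.2, 0.09),
                     gb_radius = c(1.7, 1.6, 1.5, 1.8),
                     gb_screen = c(0.72, 0.85, 0.79, 0.96),
                     chain = c("A", "A", "B", "B"))
  got <- effectiveBindingEnergy(sys)
  expect_equal(got$total, got$e_elec + got$e_vdw + got$g_gb + got$g_sa,
               tolerance = 1e-12)
  expect_equal(got$total, oracleBindingEnergy(sys), tolerance = 1e-6)
})

test_that("non-interacting partners have vanishing binding energy", {
  d <- buildHelixDimer("AAALAAAA", separation = 500)
  sys <- assignParameters(buildHydrogens(d$ensemble), part = d$partition)
  expect_lt(abs(effectiveBindingEnergy(sys)$total), 0.01)
})

test_that("decomposition conserves the total on every frame", {
  fx <- fixtureC2Dimer()
  je <- jitterEnsemble(ensemble(fx$sys), 0.25, 3, seed = 5)
  sys <- new("ParameterizedSystem", ensemble = je,
             params = atomParams(fx$sys), partition = partition(fx$sys))
  rt <- decomposeResidues(sys)
  totals <- residueFrameTotals(rt)
  for (f in 1:3) {
    direct <- effectiveBindingEnergy(sys, f)$total
    expect_lt(abs(sum(totals[, f]) - direct), 1e-6)
  }
})

test_that("exact C2 symmetry gives identical per-chain profiles", {
  fx <- fixtureC2Dimer()
  s <- summarizeEnergies(decomposeResidues(fx$sys))
  a <- s[s$chain == "A", ]
  b <- s[s$chain == "B", ]
  expect_lt(max(abs(a$total - b$total)), 1e-6)
  for (cmp in c("e_elec", "e_vdw", "g_gb", "g_sa"))
    expect_lt(max(abs(a[[cmp]] - b[[cmp]])), 1e-6)
})

test_that("rigid transforms leave all energy terms unchanged", {
  fx <- fixtureC2Dimer()
  sys <- fx$sys
  e0 <- effectiveBindingEnergy(sys)
  X <- frameCoords(sys)
  R <- HotspotGBSA:::.rotmat(c(1, 2, 3), 0.83)
  X2 <- sweep(X %*% t(R), 2, c(7, -4, 2.5), "+")
  sys2 <- new("ParameterizedSystem",
              ensemble = new("Ensemble", atoms = atomData(sys),
                             frames = list(X2)),
              params = atomParams(sys), partition = partition(sys))
  e1 <- effectiveBindingEnergy(sys2)
  expect_lt(max(abs(unlist(e0) - unlist(e1))), 1e-6)
})

test_that("per-residue rows re-sum from the pair ledger on a 3-residue toy", {
  ## residues: two atoms on A (res 1), one on B (res 2), one on B (res 3)
  a <- data.frame(serial = 1:4, name = paste0("X", 1:4), element = "C",
                  chain = c("A", "A", "B", "B"), resno = c(1L, 1L, 2L, 3L),
                  icode = "", resname = "ALA", is_h = FALSE, added_h = FALSE)
  X <- rbind(c(0, 0, 0), c(3.3, 0.5, 0), c(1.5, 3.6, 0), c(1.5, 3.3, 3.4))
  ens <- new("Ensemble", atoms = a, frames = list(X))
  prm <- data.frame(charge = c(0.4, -0.2, 0.3, -0.6), rmin_half = 1.8,
                    eps = 0.11, gb_radius = 1.65, gb_screen = 0.8)
  sys <- new("ParameterizedSystem", ensemble = ens, params = prm,
             partition = new("DimerPartition", partnerA = "A",
                             partnerB = "B"))
  rt <- decomposeResidues(sys)
  s <- summarizeEnergies(rt)

  nb <- interNonbonded(sys, ledger = TRUE)
  ## half/half split re-summed per residue from the dense pair matrices
  elecA1 <- 0.5 * sum(nb$pair_elec[1:2, ])
  elecB2 <- 0.5 * sum(nb$pair_elec[, 1])
  elecB3 <- 0.5 * sum(nb$pair_elec[, 2])
  expect_equal(s$e_elec, c(elecA1, elecB2, elecB3), tolerance = 1e-9)
  vdwA1 <- 0.5 * sum(nb$pair_vdw[1:2, ])
  expect_equal(s$e_vdw[1], vdwA1, tolerance = 1e-9)

  ## solvation columns re-sum from per-atom complex-minus-monomer calls
  gbC <- gbPolarEnergy(sys)$atom
  gbA <- gbPolarEnergy(sys, subset = 1:2)$atom
  gbB <- gbPolarEnergy(sys, subset = 3:4)$atom
  expect_equal(s$g_gb,
               c(sum(gbC[1:2]) - sum(gbA), gbC[3] - gbB[1], gbC[4] - gbB[2]),
               tolerance = 1e-9)
})
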