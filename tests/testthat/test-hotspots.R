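## a minimal ResidueEnergyTable built by hand: values per frame chosen
## so the ensemble statistics are known exactly
mkTable <- function(perFrameTotals, chain = "A") {
  nres <- nrow(perFrameTotals)
  comp <- array(0, dim = c(nres, 4, ncol(perFrameTotals)),
                dimnames = list(NULL, c("e_elec", "e_vdw", "g_gb", "g_sa"),
                                NULL))
  comp[, 1, ] <- perFrameTotals
  new("ResidueEnergyTable",
      residues = data.frame(chain = chain, resno = seq_len(nres),
                            icode = "", resname = "ALA",
                            stringsAsFactors = FALSE),
      components = comp)
}

test_that("ensemble aggregation: mean and SEM follow hand arithmetic", {
  ## constant value: SEM 0; frames {-1,-3}: mean -2, SEM 1
  tab <- mkTable(rbind(rep(-4, 5), matrix(0, 0, 5)))
  s <- summarizeEnergies(tab)
  expect_equal(s$total, -4)
  expect_equal(s$sem, 0)

  tab2 <- mkTable(matrix(c(-1, -3), 1, 2))
  s2 <- summarizeEnergies(tab2)
  expect_equal(s2$total, -2)
  expect_equal(s2$sem, 1)

  ## single frame: SEM undefined
  s3 <- summarizeEnergies(mkTable(matrix(-2.5, 1, 1)))
  expect_true(is.na(s3$sem))
})

test_that("spot classification uses a strict hot cutoff and an interface cold band", {
  agg <- data.frame(chain = "A", resno = 1:5, icode = "", resname = "ALA",
                    total = c(0.06, -0.67, -2.0, -2.5, -0.3),
                    sem = 0.01)
  burial <- data.frame(chain = "A", resno = 1:5, icode = "",
                       resname = "ALA",
                       rel_burial = c(0.4, 0.3, 0.5, 0.6, 0.01))
  rep <- classifySpots(agg, spotThresholds(), burial)
  cls <- rep@table$class
  expect_equal(cls[1], "cold")     # dG = 0.06, interface
  expect_equal(cls[2], "cold")     # dG = -0.67, interface
  expect_equal(cls[3], "neutral")  # dG = -2.0 exactly: not hot (strict <)
  expect_equal(cls[4], "hot")      # dG = -2.5
  expect_equal(cls[5], "neutral")  # |dG| small but not interface

  ## row-local: dropping rows never changes the remaining classes
  rep2 <- classifySpots(agg[-3, ], spotThresholds(), burial)
  expect_equal(rep2@table$class, cls[-3])

  expect_error(classifySpots(agg, spotThresholds(), NULL), "burial")
})

test_that("relative burial matches per-atom SASA recomputation and bounds", {
  fx <- fixtureC2Dimer()
  bur <- relativeBurial(fx$sys)
  ok <- !is.na(bur$rel_burial)
  expect_true(all(bur$rel_burial[ok] > -0.02 & bur$rel_burial[ok] <= 1.001))

  ## direct re-summation from sasaAtoms output
  sys <- fx$sys
  idx <- partitionIndices(ensemble(sys), partition(sys))
  X <- frameCoords(sys)
  rad <- atomParams(sys)$gb_radius
  orient <- HotspotGBSA:::.canonicalFrame(X)
  saC <- sasaAtoms(X, rad, frame = orient)
  saA <- sasaAtoms(X[idx$a, ], rad[idx$a], frame = orient)
  at <- atomData(sys)
  r1 <- which(at$chain == "A" & at$resno == 4)
  mono <- sum(saA[match(r1, idx$a)])
  comp <- sum(saC[r1])
  want <- (mono - comp) / mono
  expect_equal(bur$rel_burial[bur$chain == "A" & bur$resno == 4], want,
               tolerance = 1e-9)
})

test_that("fully occluded and fully exposed toy residues hit the burial limits", {
  ## one atom caged inside a partner shell: rb ~ 1
  set.seed(9)
  shell <- matrix(rnorm(60 * 3), 60, 3)
  shell <- 3.1 * shell / sqrt(rowSums(shell^2))
  X <- rbind(c(0, 0, 0), shell)
  sys <- mkToySystem(X, charge = rep(0, 61),
                     chain = c("A", rep("B", 60)))
  bur <- relativeBurial(sys)
  expect_gt(bur$rel_burial[1], 0.98)

  ## a far-away residue: rb ~ 0
  X2 <- rbind(c(0, 0, 0), c(40, 0, 0))
  sys2 <- mkToySystem(X2, charge = c(0, 0), chain = c("A", "B"))
  bur2 <- relativeBurial(sys2)
  expect_lt(abs(bur2$rel_burial[1]), 1e-9)
})

test_that("alanine scan: identity mutation is exactly zero, distant residues are silent", {
  d <- buildHelixDimer("AAALAAAA", separation = 30, c2_symmetric = FALSE)
  sys <- assignParameters(buildHydrogens(d$ensemble), part = d$partition)
  sc <- alanineScan(sys, data.frame(chain = c("A", "A"), resno = c(2, 4)))
  expect_equal(sc@table$ddg_mean[1], 0)          # ALA -> ALA
  expect_lt(abs(sc@table$ddg_mean[2]), 0.05)     # no partner atom near

  expect_error(alanineScan(sys, data.frame(chain = "A", resno = 99)),
               "unknown position")
  dg <- buildHelixDimer("AAGA", separation = 30, c2_symmetric = FALSE)
  sysg <- assignParameters(buildHydrogens(dg$ensemble), part = dg$partition)
  expect_error(alanineScan(sysg, data.frame(chain = "A", resno = 3)), "GLY")
})

test_that("alanine scan equals the two-evaluation brute force", {
  fx <- fixtureStickyDimer()
  sys <- fx$sys
  pos <- data.frame(chain = "B", resno = 10)   # an interface leucine
  sc <- alanineScan(sys, pos)

  wt <- effectiveBindingEnergy(sys)$total
  mut <- mutateToAlanine(ensemble(sys), "B", 10)
  msys <- assignParameters(buildHydrogens(mut), part = partition(sys))
  want <- effectiveBindingEnergy(msys)$total - wt
  expect_equal(sc@table$ddg_mean, want, tolerance = 1e-9)
  ## removing a packed leucine costs binding energy
  expect_gt(sc@table$ddg_mean, 0)
})

test_that("the engineered sticky residue is recovered as the rank-1 hot spot", {
  fx <- fixtureStickyDimer()
  rt <- decomposeResidues(fx$sys)
  s <- summarizeEnergies(rt)
  rep <- classifySpots(rt, burial = relativeBurial(fx$sys))
  tab <- rep@table
  sticky <- fx$d$sticky[1, ]
  i <- which(tab$chain == sticky$chain & tab$resno == sticky$resno)
  expect_equal(tab$class[i], "hot")
  expect_lt(tab$dg_mean[i], -2)
  expect_equal(which.min(s$total), i)
})

test_that("the charged-pair variant dominates the electrostatic pair ledger", {
  d <- buildStickyDimer(core_a = "R")
  sys <- assignParameters(buildHydrogens(d$ensemble), part = d$partition)
  nb <- interNonbonded(sys, ledger = TRUE)
  at <- atomData(sys)
  ia <- nb$idx$a; ib <- nb$idx$b
  resPair <- abs(rowsum(t(rowsum(nb$pair_elec, at$resno[ia])),
                        at$resno[ib]))
  ## strongest |elec| residue pair is the engineered Arg-Glu contact
  w <- which(resPair == max(resPair), arr.ind = TRUE)
  expect_equal(unname(as.integer(rownames(resPair)[w[1]])),
               d$sticky$resno[2])
  expect_equal(unname(as.integer(colnames(resPair)[w[2]])),
               d$sticky$resno[1])
})

test_that("hotspot reports export and re-import losslessly", {
  agg <- data.frame(chain = "A", resno = 1:3, icode = "", resname = "ALA",
                    total = c(-2.5, 0.2, -0.9), sem = 0.02)
  burial <- data.frame(chain = "A", resno = 1:3, icode = "",
                       rel_burial = c(0.5, 0.01, 0.3))
  rep <- classifySpots(agg, spotThresholds(), burial)
  f <- tempfile(fileext = ".tsv")
  exportReport(rep, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$class, rep@table$class)

  ## empty report: header only
  rep0 <- new("HotspotReport", table = rep@table[0, ],
              thresholds = spotThresholds())
  f0 <- tempfile(fileext = ".tsv")
  exportReport(rep0, f0)
  expect_length(readLines(f0), 1L)
})
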