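test_that("multi-MODEL PDB reading preserves frames and atoms", {
  pdb <- tempfile(fileext = ".pdb")
  atomLine <- function(serial, name, res, chain, resno, x, model = NULL) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, res, chain, resno, x, 0, 0, substr(name, 1, 1))
  }
  writeLines(c(
    "MODEL        1",
    atomLine(1, "N", "GLY", "A", 1, 0), atomLine(2, "CA", "GLY", "A", 1, 1.4),
    atomLine(3, "C", "GLY", "A", 1, 2.4), "ENDMDL",
    "MODEL        2",
    atomLine(1, "N", "GLY", "A", 1, 0.1), atomLine(2, "CA", "GLY", "A", 1, 1.5),
    atomLine(3, "C", "GLY", "A", 1, 2.5), "ENDMDL", "END"), pdb)
  ens <- readStructure(pdb)
  expect_equal(nFrames(ens), 2L)
  expect_equal(nAtoms(ens), 3L)
  expect_equal(frameCoords(ens, 2)[2, 1], 1.5)
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.60  0.00           C",
    "ATOM      3  CA BALA A   1      99.000  99.000  99.000  0.40  0.00           C",
    "END"), pdb)
  ens <- readStructure(pdb)
  expect_equal(nAtoms(ens), 2L)
  expect_equal(frameCoords(ens)[2, ], c(11.639, 6.071, -5.147))
})

test_that("waters and counterions are always stripped; HETATM is optional", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 NA    NA A   3       6.000   0.000   0.000  1.00  0.00          NA",
    "HETATM    4  C1  LIG A   4       7.000   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  expect_equal(nAtoms(readStructure(pdb)), 1L)
  expect_equal(nAtoms(readStructure(pdb, keepHet = TRUE)), 2L)

  onlyWater <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), onlyWater)
  expect_error(readStructure(onlyWater), "zero atoms")
})

test_that("write/read round-trip preserves topology and coordinates to 1e-3 A", {
  d <- buildHelixDimer("AALA", "ALAA", separation = 12, c2_symmetric = FALSE)
  je <- jitterEnsemble(d$ensemble, 0.15, 3, seed = 11)
  out <- tempfile(fileext = ".pdb")
  writeStructure(je, out)
  back <- readStructure(out)
  expect_equal(nFrames(back), 3L)
  expect_equal(atomData(back)$name, atomData(je)$name)
  expect_equal(atomData(back)$resno, atomData(je)$resno)
  expect_equal(atomData(back)$resname, atomData(je)$resname)
  for (f in 1:3)
    expect_lt(max(abs(frameCoords(back, f) - frameCoords(je, f))), 1e-3)

  ## single frame: no MODEL records, still re-readable
  one <- tempfile(fileext = ".pdb")
  writeStructure(new("Ensemble", atoms = atomData(je),
                     frames = je@frames[1]), one)
  expect_length(grep("^MODEL", readLines(one)), 0L)
  expect_equal(nFrames(readStructure(one)), 1L)
})

test_that("atom serials beyond the PDB field wrap but stay re-readable", {
  n <- 100005L
  a <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                  chain = LETTERS[(seq_len(n) - 1L) %/% 9999L + 1L],
                  resno = (seq_len(n) - 1L) %% 9999L + 1L, icode = "",
                  resname = "GLY", is_h = FALSE, added_h = FALSE)
  X <- cbind(seq_len(n) %% 500, (seq_len(n) %/% 500) %% 500, 0)
  ens <- new("Ensemble", atoms = a, frames = list(X))
  out <- tempfile(fileext = ".pdb")
  writeStructure(ens, out)
  back <- readStructure(out)
  expect_equal(nAtoms(back), n)
  expect_lt(max(abs(frameCoords(back) - X)), 1e-3)
})

test_that("ensembles reject inconsistent frames and invalid atoms", {
  a <- data.frame(serial = 1:2, name = c("N", "CA"), element = c("N", "C"),
                  chain = "A", resno = 1L, icode = "", resname = "GLY",
                  is_h = FALSE, added_h = FALSE)
  expect_error(new("Ensemble", atoms = a,
                   frames = list(matrix(0, 3, 3))), "atom count")
  expect_error(new("Ensemble", atoms = a, frames = list()), "frame")
  expect_error(new("Ensemble", atoms = a,
                   frames = list(matrix(c(0, NA, 1, 1, 1, 1), 2, 3))),
               "finite")
})

test_that("dimer partitions validate chains and cover all atoms", {
  d <- buildHelixDimer("AAAA", separation = 12)
  ens <- d$ensemble
  expect_error(partitionDimer(ens, "A", "A"), "overlap")
  expect_error(partitionDimer(ens, "A", "C"), "unknown chain C")
  part <- partitionDimer(ens, "A", "B")
  idx <- partitionIndices(ens, part)
  expect_length(intersect(idx$a, idx$b), 0L)
  expect_setequal(c(idx$a, idx$b), seq_len(nAtoms(ens)))
})

test_that("renumbering shifts one chain and rejects collisions", {
  d <- buildHelixDimer("AAAA", separation = 12)
  r <- renumberChain(d$ensemble, "A", 560L)
  expect_equal(sort(unique(atomData(r)$resno[atomData(r)$chain == "A"])),
               561:564)
  expect_equal(atomData(renumberChain(d$ensemble, "A", 0L)),
               atomData(d$ensemble))

  ## insertion codes move with their numbers and never collide
  a <- data.frame(serial = 1:2, name = "CA", element = "C", chain = "A",
                  resno = c(5L, 5L), icode = c("", "A"), resname = "GLY",
                  is_h = FALSE, added_h = FALSE)
  ens <- new("Ensemble", atoms = a, frames = list(matrix(c(0, 0, 0, 4, 0, 0),
                                                         2, 3, byrow = TRUE)))
  r2 <- renumberChain(ens, "A", 10L)
  expect_equal(atomData(r2)$resno, c(15L, 15L))
  expect_equal(atomData(r2)$icode, c("", "A"))
})
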