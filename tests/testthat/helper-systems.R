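## Constructors for small hand-made systems and cached fixtures.

## Build a ParameterizedSystem directly from coordinates and parameters
## (one atom per residue), bypassing templates.  `chain` assigns atoms
## to chains; the partition is A vs B (chain "B" may be absent for
## single-molecule toys).
mkToySystem <- function(X, charge, rmin_half = 1.9, eps = 0.1,
                        gb_radius = 1.7, gb_screen = 0.8,
                        chain = rep("A", nrow(X))) {
  n <- nrow(X)
  a <- data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
                  element = "C", chain = chain, resno = seq_len(n),
                  icode = "", resname = "ALA", is_h = FALSE,
                  added_h = FALSE, stringsAsFactors = FALSE)
  ens <- new("Ensemble", atoms = a, frames = list(X))
  prm <- data.frame(charge = charge,
                    rmin_half = rep_len(rmin_half, n),
                    eps = rep_len(eps, n),
                    gb_radius = rep_len(gb_radius, n),
                    gb_screen = rep_len(gb_screen, n))
  new("ParameterizedSystem", ensemble = ens, params = prm,
      partition = new("DimerPartition", partnerA = "A", partnerB = "B"))
}

## lazily built shared fixtures (helpers are sourced once per run)
.fixtures <- new.env()

fixtureStickyDimer <- function() {
  if (is.null(.fixtures$sticky)) {
    d <- buildStickyDimer()
    ens <- buildHydrogens(d$ensemble)
    sys <- assignParameters(ens, part = d$partition)
    .fixtures$sticky <- list(d = d, sys = sys)
  }
  .fixtures$sticky
}

fixtureC2Dimer <- function() {
  if (is.null(.fixtures$c2)) {
    d <- buildHelixDimer("AAALAAAA", separation = 10, c2_symmetric = TRUE)
    ens <- buildHydrogens(d$ensemble)
    .fixtures$c2 <- list(d = d,
                         sys = assignParameters(ens, part = d$partition))
  }
  .fixtures$c2
}
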