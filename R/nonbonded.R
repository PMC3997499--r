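## Gas-phase inter-partner nonbonded terms: Coulomb and Lennard-Jones
## over all cross-partner atom pairs, no cutoff, no scaling (the pairs
## are strictly inter-molecular).

#' Inter-partner Coulomb and Lennard-Jones energies
#'
#' Sums `Ce * q_i q_j / r_ij` (solute dielectric 1) and 12-6
#' Lennard-Jones with Lorentz-Berthelot combination
#' (`rmin = rmin_half_i + rmin_half_j`, `eps = sqrt(eps_i eps_j)`) over
#' every atom pair with one atom in each partner, without cutoff.
#'
#' @param sys a [ParameterizedSystem-class].
#' @param frame frame index.
#' @param ledger also return the dense per-pair matrices (rows: partner
#'   A atoms, columns: partner B atoms)?  Intended for small systems.
#' @return list with totals `e_elec`, `e_vdw` (kcal/mol), per-atom
#'   half-share vectors `atom_elec`, `atom_vdw` (full topology length),
#'   and, if requested, matrices `pair_elec`, `pair_vdw`.
#' @export
interNonbonded <- function(sys, frame = 1L, ledger = FALSE) {
  stopifnot(is(sys, "ParameterizedSystem"))
  idx <- partitionIndices(sys@ensemble, sys@partition)
  X <- sys@ensemble@frames[[frame]]
  p <- sys@params
  r <- .distmat(X[idx$a, , drop = FALSE], X[idx$b, , drop = FALSE])
  if (any(r < 1e-9)) stop("zero interatomic distance between partners")
  Eel <- .COULOMB * outer(p$charge[idx$a], p$charge[idx$b]) / r
  rmin <- outer(p$rmin_half[idx$a], p$rmin_half[idx$b], "+")
  epsm <- sqrt(outer(p$eps[idx$a], p$eps[idx$b]))
  sr6 <- (rmin / r)^6
  Evdw <- epsm * (sr6^2 - 2 * sr6)
  atom_elec <- numeric(nAtoms(sys))
  atom_vdw <- numeric(nAtoms(sys))
  atom_elec[idx$a] <- 0.5 * rowSums(Eel)
  atom_elec[idx$b] <- 0.5 * colSums(Eel)
  atom_vdw[idx$a] <- 0.5 * rowSums(Evdw)
  atom_vdw[idx$b] <- 0.5 * colSums(Evdw)
  out <- list(e_elec = sum(Eel), e_vdw = sum(Evdw),
              atom_elec = atom_elec, atom_vdw = atom_vdw)
  if (ledger) {
    out$pair_elec <- Eel
    out$pair_vdw <- Evdw
    out$idx <- idx
  }
  out
}
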