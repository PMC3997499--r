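## Effective binding energy (single-trajectory end-point scheme) and its
## per-residue decomposition.  Complex and both monomers are evaluated on
## identical complex-frame coordinates, so all intramolecular gas-phase
## terms cancel exactly and only the inter-partner nonbonded terms plus
## the solvation differences remain.

#' Effective binding energy of one frame
#'
#' `dG_eff = E_elec(inter) + E_vdw(inter) + [G_GB(AB) - G_GB(A) -
#' G_GB(B)] + gamma [SASA(AB) - SASA(A) - SASA(B)]`, all on the same
#' frame coordinates.  Configurational entropy is not part of the
#' effective energy.
#'
#' @param sys a [ParameterizedSystem-class].
#' @param frame frame index.
#' @param gb from [gbOptions()].
#' @param sasa from [sasaOptions()].
#' @return list with components `e_elec`, `e_vdw`, `g_gb`, `g_sa` and
#'   their sum `total` (kcal/mol).
#' @export
effectiveBindingEnergy <- function(sys, frame = 1L, gb = gbOptions(),
                                   sasa = sasaOptions()) {
  dec <- .frameDecomposition(sys, frame, gb, sasa)
  comp <- c(e_elec = sum(dec$atom_elec), e_vdw = sum(dec$atom_vdw),
            g_gb = sum(dec$atom_gb), g_sa = sum(dec$atom_sa))
  c(as.list(comp), list(total = sum(comp)))
}

## Per-atom decomposition of one frame's binding energy; everything else
## (totals, residue tables) is aggregation of this.
.frameDecomposition <- function(sys, frame, gb, sasa) {
  idx <- partitionIndices(sys@ensemble, sys@partition)
  nb <- interNonbonded(sys, frame)

  gbC <- gbPolarEnergy(sys, frame, gb)
  gbA <- gbPolarEnergy(sys, frame, gb, subset = idx$a)
  gbB <- gbPolarEnergy(sys, frame, gb, subset = idx$b)
  atom_gb <- gbC$atom
  atom_gb[idx$a] <- atom_gb[idx$a] - gbA$atom
  atom_gb[idx$b] <- atom_gb[idx$b] - gbB$atom

  X <- sys@ensemble@frames[[frame]]
  rad <- sys@params$gb_radius
  orient <- .canonicalFrame(X)
  saC <- sasaAtoms(X, rad, sasa, frame = orient)
  saA <- sasaAtoms(X[idx$a, , drop = FALSE], rad[idx$a], sasa, frame = orient)
  saB <- sasaAtoms(X[idx$b, , drop = FALSE], rad[idx$b], sasa, frame = orient)
  atom_sa <- saC
  atom_sa[idx$a] <- atom_sa[idx$a] - saA
  atom_sa[idx$b] <- atom_sa[idx$b] - saB
  atom_sa <- sasa$surface_tension * atom_sa

  list(atom_elec = nb$atom_elec, atom_vdw = nb$atom_vdw,
       atom_gb = atom_gb, atom_sa = atom_sa,
       sasa_complex = saC, sasa_monomer = c(saA, saB)[order(c(idx$a, idx$b))])
}

#' Per-residue decomposition of the effective binding energy
#'
#' Attributes every energy term to residues: cross-partner pair terms
#' are split half/half between the two residues they touch, GB self
#' terms belong to their atom, and the GB/SASA contributions are
#' complex-minus-monomer differences on identical coordinates.  By
#' construction the residue contributions of each frame sum exactly to
#' that frame's effective binding energy.
#'
#' @param sys a [ParameterizedSystem-class].
#' @param frames frame indices (default: all).
#' @param gb from [gbOptions()].
#' @param sasa from [sasaOptions()].
#' @return a [ResidueEnergyTable-class].
#' @seealso [summarizeEnergies()], [classifySpots()]
#' @export
decomposeResidues <- function(sys, frames = NULL, gb = gbOptions(),
                              sasa = sasaOptions()) {
  stopifnot(is(sys, "ParameterizedSystem"))
  if (is.null(frames)) frames <- seq_len(nFrames(sys))
  if (length(frames) == 0L) stop("empty frame range")
  ridx <- residueIndex(sys)
  nres <- nrow(ridx)
  grp <- integer(nAtoms(sys))
  for (i in seq_len(nres)) grp[ridx$atoms[[i]]] <- i

  comp <- array(0, dim = c(nres, 4L, length(frames)),
                dimnames = list(NULL, c("e_elec", "e_vdw", "g_gb", "g_sa"),
                                NULL))
  for (k in seq_along(frames)) {
    dec <- .frameDecomposition(sys, frames[k], gb, sasa)
    comp[, 1, k] <- rowsum(dec$atom_elec, grp)[, 1]
    comp[, 2, k] <- rowsum(dec$atom_vdw, grp)[, 1]
    comp[, 3, k] <- rowsum(dec$atom_gb, grp)[, 1]
    comp[, 4, k] <- rowsum(dec$atom_sa, grp)[, 1]
  }
  new("ResidueEnergyTable",
      residues = ridx[, c("chain", "resno", "icode", "resname")],
      components = comp)
}

#' Ensemble aggregation of a residue energy table
#'
#' Arithmetic mean over frames per residue and component, plus the
#' standard error of the mean of the per-residue totals
#' (`sd / sqrt(n)`).  With a single frame the SEM is undefined and
#' reported as `NA`.
#'
#' @param rtab a [ResidueEnergyTable-class].
#' @return data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `e_elec`, `e_vdw`, `g_gb`, `g_sa`, `total`, `sem`, `n_frames`.
#' @export
summarizeEnergies <- function(rtab) {
  stopifnot(is(rtab, "ResidueEnergyTable"))
  comp <- rtab@components
  nfr <- dim(comp)[3]
  if (nfr == 0L) stop("empty table")
  means <- apply(comp, c(1, 2), mean)
  totals <- apply(comp, c(1, 3), sum)   # residue x frame
  if (is.null(dim(totals))) totals <- matrix(totals, ncol = nfr)
  tot_mean <- rowMeans(totals)
  sem <- if (nfr >= 2L) apply(totals, 1, sd) / sqrt(nfr) else NA_real_
  out <- cbind(rtab@residues,
               as.data.frame(means),
               total = tot_mean, sem = sem, n_frames = nfr)
  rownames(out) <- NULL
  out
}

#' Per-frame residue totals of a residue energy table
#'
#' @param rtab a [ResidueEnergyTable-class].
#' @return matrix (residue x frame) of total contributions in kcal/mol.
#' @export
residueFrameTotals <- function(rtab) {
  stopifnot(is(rtab, "ResidueEnergyTable"))
  out <- apply(rtab@components, c(1, 3), sum)
  if (is.null(dim(out))) out <- matrix(out, ncol = dim(rtab@components)[3])
  out
}

#' Export a residue energy table as TSV
#'
#' Fixed column order: chain, resnum, resname, e_elec, e_vdw, g_gb,
#' g_sa, total, sem, n_frames.
#'
#' @param rtab a [ResidueEnergyTable-class].
#' @param path output file.
#' @export
exportEnergyTable <- function(rtab, path) {
  s <- summarizeEnergies(rtab)
  out <- data.frame(chain = s$chain, resnum = paste0(s$resno, s$icode),
                    resname = s$resname, e_elec = s$e_elec, e_vdw = s$e_vdw,
                    g_gb = s$g_gb, g_sa = s$g_sa, total = s$total,
                    sem = s$sem, n_frames = s$n_frames)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
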