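## Hot-spot analytics: classification thresholds, relative burial,
## hot/cold/neutral classification, and MM-GB/SA alanine scanning.

#' Classification thresholds for interface spots
#'
#' Hot spots are residues whose mean contribution to the effective
#' binding energy is strictly below `hot_cutoff` (default -2 kcal/mol).
#' Cold spots are interface residues (mean relative burial at least
#' `interface_burial`) whose |mean dG| is at most `cold_band`
#' (default 1 kcal/mol); they serve as negative controls.  Everything
#' else is neutral.
#'
#' @param hot_cutoff negative kcal/mol cutoff, strict "<".
#' @param cold_band kcal/mol half-width of the cold band.
#' @param interface_burial minimum relative burial for interface
#'   membership (default 0.05).
#' @return a [SpotThresholds-class].
#' @export
spotThresholds <- function(hot_cutoff = -2, cold_band = 1,
                           interface_burial = 0.05) {
  new("SpotThresholds", hot_cutoff = hot_cutoff, cold_band = cold_band,
      interface_burial = interface_burial)
}

#' Residue-wise relative burial upon complex formation
#'
#' For each residue, `rb = (SASA_monomer - SASA_complex) /
#' SASA_monomer`, with the monomer computed on the same frame
#' coordinates, averaged over frames.  Residues whose mean monomer area
#' is below 1 A^2 are flagged undefined (`NA`).  Up to quadrature
#' tolerance, rb lies between 0 and 1.
#'
#' @param sys a [ParameterizedSystem-class].
#' @param frames frame indices (default all).
#' @param sasa from [sasaOptions()].
#' @return data.frame with `chain`, `resno`, `icode`, `resname`,
#'   `rel_burial`, `sasa_monomer`, `sasa_complex` (frame means).
#' @export
relativeBurial <- function(sys, frames = NULL, sasa = sasaOptions()) {
  stopifnot(is(sys, "ParameterizedSystem"))
  if (is.null(frames)) frames <- seq_len(nFrames(sys))
  idx <- partitionIndices(sys@ensemble, sys@partition)
  ridx <- residueIndex(sys)
  grp <- integer(nAtoms(sys))
  for (i in seq_len(nrow(ridx))) grp[ridx$atoms[[i]]] <- i
  rad <- sys@params$gb_radius
  accC <- accM <- matrix(0, nrow(ridx), length(frames))
  for (k in seq_along(frames)) {
    X <- sys@ensemble@frames[[frames[k]]]
    orient <- .canonicalFrame(X)
    saC <- sasaAtoms(X, rad, sasa, frame = orient)
    saM <- numeric(nAtoms(sys))
    saM[idx$a] <- sasaAtoms(X[idx$a, , drop = FALSE], rad[idx$a], sasa,
                            frame = orient)
    saM[idx$b] <- sasaAtoms(X[idx$b, , drop = FALSE], rad[idx$b], sasa,
                            frame = orient)
    accC[, k] <- rowsum(saC, grp)[, 1]
    accM[, k] <- rowsum(saM, grp)[, 1]
  }
  monoMean <- rowMeans(accM)
  compMean <- rowMeans(accC)
  rb <- rowMeans((accM - accC) / accM)
  rb[monoMean < 1] <- NA_real_
  data.frame(chain = ridx$chain, resno = ridx$resno, icode = ridx$icode,
             resname = ridx$resname, rel_burial = rb,
             sasa_monomer = monoMean, sasa_complex = compMean,
             stringsAsFactors = FALSE)
}

#' Classify interface residues into hot, cold and neutral spots
#'
#' Hot iff mean dG < `hot_cutoff` (strict); cold iff interface-flagged
#' (relative burial >= `interface_burial`) and |mean dG| <= `cold_band`;
#' neutral otherwise.  Classes are mutually exclusive and row-local:
#' adding or removing residues never changes another residue's class.
#'
#' @param x a [ResidueEnergyTable-class] or the data.frame from
#'   [summarizeEnergies()].
#' @param thresholds a [SpotThresholds-class].
#' @param burial data.frame from [relativeBurial()] (required: cold
#'   classification depends on interface membership).
#' @return a [HotspotReport-class].
#' @export
classifySpots <- function(x, thresholds = spotThresholds(), burial) {
  agg <- if (is(x, "ResidueEnergyTable")) summarizeEnergies(x) else x
  if (missing(burial) || is.null(burial))
    stop("burial data required for cold-spot classification")
  key <- paste(agg$chain, agg$resno, agg$icode)
  bkey <- paste(burial$chain, burial$resno, burial$icode)
  m <- match(key, bkey)
  if (anyNA(m)) stop("burial table does not cover all residues")
  rb <- burial$rel_burial[m]
  interface <- !is.na(rb) & rb >= thresholds@interface_burial
  cls <- rep("neutral", nrow(agg))
  cls[interface & abs(agg$total) <= thresholds@cold_band] <- "cold"
  cls[agg$total < thresholds@hot_cutoff] <- "hot"
  tab <- data.frame(chain = agg$chain, resno = agg$resno, icode = agg$icode,
                    resname = agg$resname, dg_mean = agg$total,
                    dg_sem = agg$sem, rel_burial = rb,
                    interface = interface, class = cls,
                    stringsAsFactors = FALSE)
  new("HotspotReport", table = tab, thresholds = thresholds)
}

#' In-silico alanine scanning over an ensemble
#'
#' For every requested position and frame, the side chain is truncated
#' to alanine on the fixed complex coordinates (single-trajectory
#' philosophy: no re-minimization), the mutant is re-protonated and
#' re-parameterized, and the full effective binding energy is
#' recomputed.  `ddG = dG_eff(mutant) - dG_eff(wild type)`; positive
#' values mean the mutation destabilizes binding.  Mutating an alanine
#' gives exactly 0.  Glycine and proline positions are rejected.
#'
#' @param sys a [ParameterizedSystem-class] of the wild-type complex.
#' @param positions data.frame with columns `chain` and `resno` (and
#'   optionally `icode`).
#' @param frames frame indices (default all).
#' @param gb,sasa energy options.
#' @param pset parameter set used for re-parameterization.
#' @return an [AlaScanResult-class].
#' @export
alanineScan <- function(sys, positions, frames = NULL, gb = gbOptions(),
                        sasa = sasaOptions(), pset = loadParameterSet()) {
  stopifnot(is(sys, "ParameterizedSystem"))
  positions <- as.data.frame(positions)
  if (is.null(positions$icode)) positions$icode <- ""
  if (is.null(frames)) frames <- seq_len(nFrames(sys))
  a <- sys@ensemble@atoms
  resn <- character(nrow(positions))
  for (p in seq_len(nrow(positions))) {
    hit <- which(a$chain == positions$chain[p] &
                 a$resno == positions$resno[p] &
                 a$icode == positions$icode[p])
    if (length(hit) == 0L)
      stop("unknown position ", positions$chain[p], "/", positions$resno[p])
    resn[p] <- a$resname[hit[1]]
    if (resn[p] %in% c("GLY", "PRO"))
      stop(resn[p], " at ", positions$chain[p], "/", positions$resno[p],
           " cannot be scanned")
  }

  ddg <- matrix(0, nrow(positions), length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    wt <- effectiveBindingEnergy(sys, f, gb, sasa)$total
    single <- new("Ensemble", atoms = a,
                  frames = sys@ensemble@frames[f])
    for (p in seq_len(nrow(positions))) {
      if (resn[p] == "ALA") { ddg[p, k] <- 0; next }
      mut <- mutateToAlanine(single, positions$chain[p], positions$resno[p],
                             positions$icode[p])
      mut <- buildHydrogens(mut, pset)
      msys <- assignParameters(mut, pset, sys@partition)
      ddg[p, k] <- effectiveBindingEnergy(msys, 1L, gb, sasa)$total - wt
    }
  }
  nfr <- length(frames)
  tab <- data.frame(chain = positions$chain, resno = positions$resno,
                    icode = positions$icode, resname = resn,
                    ddg_mean = rowMeans(ddg),
                    ddg_sem = if (nfr >= 2L) apply(ddg, 1, sd) / sqrt(nfr)
                              else NA_real_,
                    n_frames = nfr, stringsAsFactors = FALSE)
  new("AlaScanResult", table = tab, perFrame = ddg)
}

#' Export a hotspot report as TSV
#'
#' Columns: chain, resnum, resname, dg_mean, dg_sem, rel_burial,
#' interface, class.  Re-importing the file reproduces the classes.
#'
#' @param report a [HotspotReport-class].
#' @param path output file.
#' @export
exportReport <- function(report, path) {
  stopifnot(is(report, "HotspotReport"))
  tab <- report@table
  out <- data.frame(chain = tab$chain, resnum = paste0(tab$resno, tab$icode),
                    resname = tab$resname, dg_mean = tab$dg_mean,
                    dg_sem = tab$dg_sem, rel_burial = tab$rel_burial,
                    interface = tab$interface, class = tab$class)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
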