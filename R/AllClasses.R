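## Central S4 containers.
##
## An Ensemble stores one canonical atom table (the topology) plus one or
## more coordinate frames over that topology; a single-conformation
## structure is simply a one-frame Ensemble.  All energetic machinery runs
## over Ensembles partitioned into two binding partners.

#' Ensemble: an atom topology with one or more coordinate frames
#'
#' The atom table (`atoms`) is a data.frame with one row per atom and
#' columns `serial`, `name`, `element`, `chain`, `resno`, `icode`,
#' `resname`, `is_h` and `added_h`.  Each frame is an N x 3 matrix of
#' coordinates in Angstrom, in topology order.  A conventional
#' single-conformation structure is represented as a one-frame ensemble.
#'
#' @slot atoms data.frame, one row per atom (topology order).
#' @slot frames list of N x 3 numeric matrices, one per frame.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(atoms = "data.frame", frames = "list"))

setValidity("Ensemble", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "chain", "resno", "icode",
            "resname", "is_h", "added_h")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("ensemble has zero atoms")
  if (length(object@frames) < 1L) return("ensemble needs at least one frame")
  for (f in object@frames) {
    if (!is.matrix(f) || ncol(f) != 3L)
      return("each frame must be an N x 3 matrix")
    if (nrow(f) != nrow(a))
      return("frame atom count differs from topology")
    if (!all(is.finite(f))) return("non-finite coordinates")
  }
  if (any(!nzchar(a$element))) return("empty element symbol")
  key <- paste(a$chain, a$resno, a$icode)
  ## (number, icode) pairs must be unique per chain at the residue level
  res <- unique(data.frame(chain = a$chain, resno = a$resno, icode = a$icode,
                           resname = a$resname))
  if (anyDuplicated(paste(res$chain, res$resno, res$icode)))
    return("duplicate (residue number, insertion code) within a chain")
  TRUE
})

#' DimerPartition: the two binding partners of a complex
#'
#' @slot partnerA character vector of chain ids forming partner A.
#' @slot partnerB character vector of chain ids forming partner B.
#' @exportClass DimerPartition
setClass("DimerPartition",
  representation(partnerA = "character", partnerB = "character"))

setValidity("DimerPartition", function(object) {
  if (length(object@partnerA) == 0L || length(object@partnerB) == 0L)
    return("both partners need at least one chain")
  if (length(intersect(object@partnerA, object@partnerB)) > 0L)
    return("partners overlap")
  TRUE
})

#' ParameterizedSystem: ensemble plus per-atom force-field parameters
#'
#' Produced by [assignParameters()].  `params` has one row per atom
#' (topology order) with columns `charge` (e), `rmin_half` (A), `eps`
#' (kcal/mol), `gb_radius` (A, intrinsic Born radius), `gb_screen`
#' (dimensionless descreening scale).
#'
#' @slot ensemble an [Ensemble-class].
#' @slot params data.frame of per-atom parameters.
#' @slot partition a [DimerPartition-class].
#' @exportClass ParameterizedSystem
setClass("ParameterizedSystem",
  representation(ensemble = "Ensemble", params = "data.frame",
                 partition = "DimerPartition"))

setValidity("ParameterizedSystem", function(object) {
  if (nrow(object@params) != nrow(object@ensemble@atoms))
    return("one parameter row per atom required")
  need <- c("charge", "rmin_half", "eps", "gb_radius", "gb_screen")
  if (!all(need %in% names(object@params)))
    return(paste("params must have columns:", paste(need, collapse = ", ")))
  if (any(object@params$gb_radius <= 0)) return("non-positive intrinsic GB radius")
  if (any(object@params$eps < 0)) return("negative LJ epsilon")
  ch <- unique(object@ensemble@atoms$chain)
  if (!all(ch %in% c(object@partition@partnerA, object@partition@partnerB)))
    return("every chain must be assigned to a partner")
  TRUE
})

#' ResidueEnergyTable: per-residue effective-energy contributions
#'
#' `residues` identifies the rows (chain, resno, icode, resname);
#' `components` is an nres x 4 x nframes array with component slices
#' `e_elec`, `e_vdw`, `g_gb`, `g_sa` in kcal/mol.
#'
#' @slot residues data.frame keying the rows.
#' @slot components 3-d numeric array (residue x component x frame).
#' @exportClass ResidueEnergyTable
setClass("ResidueEnergyTable",
  representation(residues = "data.frame", components = "array"))

setValidity("ResidueEnergyTable", function(object) {
  d <- dim(object@components)
  if (length(d) != 3L) return("components must be a 3-d array")
  if (d[1] != nrow(object@residues)) return("row mismatch")
  if (d[2] != 4L || !identical(dimnames(object@components)[[2]],
                               c("e_elec", "e_vdw", "g_gb", "g_sa")))
    return("component slices must be e_elec, e_vdw, g_gb, g_sa")
  TRUE
})

#' HotspotReport: per-residue classification into hot/cold/neutral
#'
#' @slot table data.frame with columns `chain`, `resno`, `resname`,
#'   `dg_mean`, `dg_sem`, `rel_burial`, `interface`, `class`.
#' @slot thresholds the [SpotThresholds-class] used.
#' @exportClass HotspotReport
setClass("HotspotReport",
  representation(table = "data.frame", thresholds = "ANY"))

#' SpotThresholds: hot/cold classification cutoffs
#'
#' @slot hot_cutoff kcal/mol; residues with mean dG strictly below this
#'   are hot spots (default -2).
#' @slot cold_band kcal/mol; interface residues with |mean dG| at or
#'   below this are cold spots (default 1).
#' @slot interface_burial minimum mean relative burial for a residue to
#'   count as interface (default 0.05).
#' @exportClass SpotThresholds
setClass("SpotThresholds",
  representation(hot_cutoff = "numeric", cold_band = "numeric",
                 interface_burial = "numeric"))

setValidity("SpotThresholds", function(object) {
  if (object@hot_cutoff >= 0) return("hot_cutoff must be negative")
  if (object@cold_band < 0) return("cold_band must be non-negative")
  TRUE
})

#' AlaScanResult: alanine-scanning ddG per mutated position
#'
#' Sign convention: positive ddG means the mutation destabilizes binding
#' (ddG = dG_eff(mutant) - dG_eff(wild type)).
#'
#' @slot table data.frame with `chain`, `resno`, `resname`, `ddg_mean`,
#'   `ddg_sem`, `n_frames`.
#' @slot perFrame matrix (position x frame) of per-frame ddG.
#' @exportClass AlaScanResult
setClass("AlaScanResult",
  representation(table = "data.frame", perFrame = "matrix"))

#' TmResult: melting temperature estimate
#'
#' @slot tm melting temperature, degrees C.
#' @slot method "derivative" or "sigmoid-fit".
#' @slot diagnostics named list (slope, residual norm, ... when fitted;
#'   `sem_defined` flag for ensemble aggregation).
#' @exportClass TmResult
setClass("TmResult",
  representation(tm = "numeric", method = "character", diagnostics = "list"))

#' CalibrationCurve: log-linear SEC calibration
#'
#' log10(MW in Da) = slope * Ve + intercept, fitted over the elution
#' volumes of the standards.
#'
#' @slot slope,intercept fitted line coefficients.
#' @slot r2 coefficient of determination.
#' @slot ve_range min/max elution volume of the standards (mL).
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 ve_range = "numeric"))
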