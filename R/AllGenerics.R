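#' Number of atoms / frames in an object
#'
#' @param x an [Ensemble-class] or [ParameterizedSystem-class].
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Accessors for ensembles and systems
#'
#' `atomData` returns the atom table, `frameCoords` one coordinate frame,
#' `ensemble` / `partition` / `atomParams` the corresponding slots of a
#' [ParameterizedSystem-class].
#'
#' @param x the object.
#' @param i frame index (1-based).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname accessors
#' @export
setGeneric("ensemble", function(x) standardGeneric("ensemble"))

#' @rdname accessors
#' @export
setGeneric("partition", function(x) standardGeneric("partition"))

#' @rdname accessors
#' @export
setGeneric("atomParams", function(x) standardGeneric("atomParams"))

setMethod("nAtoms", "Ensemble", function(x) nrow(x@atoms))
setMethod("nFrames", "Ensemble", function(x) length(x@frames))
setMethod("atomData", "Ensemble", function(x) x@atoms)
setMethod("frameCoords", "Ensemble", function(x, i = 1L) x@frames[[i]])

setMethod("nAtoms", "ParameterizedSystem", function(x) nrow(x@ensemble@atoms))
setMethod("nFrames", "ParameterizedSystem", function(x) length(x@ensemble@frames))
setMethod("atomData", "ParameterizedSystem", function(x) x@ensemble@atoms)
setMethod("frameCoords", "ParameterizedSystem", function(x, i = 1L) x@ensemble@frames[[i]])
setMethod("ensemble", "ParameterizedSystem", function(x) x@ensemble)
setMethod("partition", "ParameterizedSystem", function(x) x@partition)
setMethod("atomParams", "ParameterizedSystem", function(x) x@params)

setMethod("show", "Ensemble", function(object) {
  a <- object@atoms
  cat("Ensemble:", nrow(a), "atoms,", length(object@frames), "frame(s)\n")
  for (ch in unique(a$chain)) {
    r <- a[a$chain == ch, ]
    cat("  chain", ch, ":", length(unique(paste(r$resno, r$icode))),
        "residues,", nrow(r), "atoms\n")
  }
})

setMethod("show", "DimerPartition", function(object) {
  cat("DimerPartition: A = {", paste(object@partnerA, collapse = ","),
      "}  B = {", paste(object@partnerB, collapse = ","), "}\n")
})

setMethod("show", "ParameterizedSystem", function(object) {
  cat("ParameterizedSystem:", nrow(object@params), "parameterized atoms,",
      length(object@ensemble@frames), "frame(s)\n")
  cat("  total charge:", sprintf("%+.3f e", sum(object@params$charge)), "\n")
  show(object@partition)
})

setMethod("show", "ResidueEnergyTable", function(object) {
  cat("ResidueEnergyTable:", nrow(object@residues), "residues x",
      dim(object@components)[3], "frame(s)\n")
  s <- summarizeEnergies(object)
  cat("  ensemble-mean total over residues:",
      sprintf("%.3f kcal/mol", sum(s$total)), "\n")
})

setMethod("show", "HotspotReport", function(object) {
  tab <- object@table
  cat("HotspotReport:", nrow(tab), "residues |",
      sum(tab$class == "hot"), "hot,",
      sum(tab$class == "cold"), "cold,",
      sum(tab$class == "neutral"), "neutral\n")
})

setMethod("show", "AlaScanResult", function(object) {
  cat("AlaScanResult:", nrow(object@table), "position(s),",
      ncol(object@perFrame), "frame(s); positive ddG = destabilizing\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "TmResult", function(object) {
  cat(sprintf("Tm = %.2f C (%s)\n", object@tm, object@method))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("SEC calibration: log10(MW) = %.4f * Ve + %.4f (r2 = %.4f)\n",
              object@slope, object@intercept, object@r2))
})
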