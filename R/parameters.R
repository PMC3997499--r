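## Residue templates: fixed-charge force-field parameters (charges in e,
## Lennard-Jones rmin/2 and epsilon, atom type classes) for the 20
## standard amino acids, plus ideal-geometry coordinates and connectivity
## used for hydrogen building and side-chain placement.  Protonation
## defaults: His neutral (N-epsilon tautomer), Asp/Glu deprotonated,
## Lys/Arg protonated, Cys reduced.

.GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96)

## element radii of the mbondi2 intrinsic Born set; hydrogens default to
## 1.2 A but take 1.3 A when bonded to nitrogen
.GB_RADIUS <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8)

.FORMAL_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)

## amber-style type classes treated as sp2 when placing hydrogens
.SP2_TYPES <- c("C", "CA", "CB", "CC", "CN", "CR", "CW", "C*",
                "N", "NA", "NB", "N2")

.paramCache <- new.env(parent = emptyenv())

#' Load the bundled residue parameter set
#'
#' Reads the packaged residue templates: per-atom partial charges and
#' Lennard-Jones types of a fixed-charge all-atom protein force field,
#' intrinsic Born radii (mbondi2 convention, assigned from the element
#' with the H-on-N exception) with their descreening scale factors, ideal
#' residue geometry and covalent connectivity.  The set covers the 20
#' standard amino acids; terminal variants are derived as charge patches
#' (see [assignParameters()]).
#'
#' @param dir directory holding the parameter tables; defaults to the
#'   tables shipped with the package.
#' @return a named list (one element per residue) with components
#'   `atoms` (data.frame: name, element, charge, type, rmin_half, eps,
#'   gb_radius, gb_screen, is_h), `bonds` (data.frame: atom1, atom2),
#'   `coords` (matrix of ideal coordinates, rownames = atom names) and
#'   `formal` (integer formal charge); the whole list carries the
#'   attribute `lj_types`.
#' @examples
#' pset <- loadParameterSet()
#' names(pset)
#' sum(pset$ALA$atoms$charge)   # neutral residue: 0
#' @export
loadParameterSet <- function(dir = system.file("extdata", package = "HotspotGBSA")) {
  key <- normalizePath(dir)
  if (!is.null(.paramCache[[key]])) return(.paramCache[[key]])
  ## na.strings: the nitrogen type class is literally named "NA"
  chg <- read.delim(file.path(dir, "ff_charges.tsv"), stringsAsFactors = FALSE,
                    na.strings = character(0))
  lj <- read.delim(file.path(dir, "ff_lj_types.tsv"), stringsAsFactors = FALSE,
                   na.strings = character(0))
  geo <- read.delim(file.path(dir, "residue_geometry.tsv"), stringsAsFactors = FALSE)
  bnd <- read.delim(file.path(dir, "residue_bonds.tsv"), stringsAsFactors = FALSE)
  ljr <- setNames(lj$rmin_half, lj$type)
  lje <- setNames(lj$eps, lj$type)

  pset <- list()
  for (res in unique(chg$residue)) {
    a <- chg[chg$residue == res, c("atom", "charge", "type")]
    g <- geo[geo$residue == res, ]
    b <- bnd[bnd$residue == res, c("atom1", "atom2")]
    if (!setequal(a$atom, g$atom))
      stop("parameter/geometry atom mismatch for ", res)
    a <- a[match(g$atom, a$atom), ]
    atoms <- data.frame(
      name = g$atom, element = g$element, charge = a$charge, type = a$type,
      rmin_half = unname(ljr[a$type]), eps = unname(lje[a$type]),
      stringsAsFactors = FALSE)
    atoms$is_h <- atoms$element == "H"
    ## mbondi2: hydrogen radius depends on the bonded heavy atom
    bondedTo <- function(atom) {
      c(b$atom2[b$atom1 == atom], b$atom1[b$atom2 == atom])
    }
    gbr <- .GB_RADIUS[atoms$element]
    for (i in which(atoms$is_h)) {
      heavy <- bondedTo(atoms$name[i])
      el <- atoms$element[match(heavy[1], atoms$name)]
      if (identical(el, "N")) gbr[i] <- 1.3
    }
    ## backbone N-H of a non-terminal residue is bonded within-residue,
    ## so the rule above covers it
    atoms$gb_radius <- unname(gbr)
    atoms$gb_screen <- unname(.GB_SCREEN[atoms$element])
    coords <- as.matrix(g[, c("x", "y", "z")])
    rownames(coords) <- g$atom
    formal <- if (res %in% names(.FORMAL_CHARGE)) .FORMAL_CHARGE[[res]] else 0
    if (abs(sum(atoms$charge) - formal) > 1e-3)
      stop("template charges of ", res, " do not sum to formal charge")
    pset[[res]] <- list(atoms = atoms, bonds = b, coords = coords,
                        formal = formal)
  }
  attr(pset, "lj_types") <- lj
  .paramCache[[key]] <- pset
  pset
}

## heavy neighbours (within the residue template) of a template atom
.templateNeighbors <- function(tpl, atom, heavyOnly = TRUE) {
  b <- tpl$bonds
  nb <- c(b$atom2[b$atom1 == atom], b$atom1[b$atom2 == atom])
  if (heavyOnly) {
    isH <- tpl$atoms$is_h[match(nb, tpl$atoms$name)]
    nb <- nb[!isH]
  }
  nb
}

## hydrogens attached to a heavy template atom
.templateHydrogens <- function(tpl, atom) {
  b <- tpl$bonds
  nb <- c(b$atom2[b$atom1 == atom], b$atom1[b$atom2 == atom])
  isH <- tpl$atoms$is_h[match(nb, tpl$atoms$name)]
  nb[isH]
}

## Terminal charge patches.  The zwitterionic termini are modelled as
## simple patches on the standard templates: the alpha-amino group gains
## H1..H3 (H2/H3 for proline) carrying the backbone amide-H charge each,
## with the balance of the +1 unit placed on N; the carboxylate gets
## O = OXT = -0.8055 e with the balance of the -1 unit placed on C.  This
## keeps every chain's total charge at the exact sum of formal charges.
.NTERM_H_CHARGE <- 0.2719
.CTERM_O_CHARGE <- -0.8055
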