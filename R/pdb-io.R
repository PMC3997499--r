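## PDB reading/writing.  Multi-MODEL PDB is the ensemble interchange
## format: one frame per MODEL record.  Parsing is delegated to bio3d;
## this layer applies the filtering policy (waters and counterions always
## stripped, HETATM optional, highest-occupancy alternate location kept)
## and converts to the package's Ensemble container.

.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "TIP4", "SPC", "SOL")
.ION_RESIDUES <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "BR",
                   "IOD", "CS", "LI", "RB", "SO4", "PO4")

#' Read a structure or multi-MODEL ensemble from a PDB file
#'
#' Each MODEL record becomes one frame (a file without MODEL records
#' yields a single-frame ensemble).  Water molecules and counterions are
#' always stripped.  For alternate locations, only the highest-occupancy
#' conformer is retained (ties: first in file).  HETATM records are
#' excluded unless `keepHet = TRUE`.
#'
#' @param path PDB file.
#' @param keepHet keep non-water, non-ion HETATM records?
#' @return an [Ensemble-class].
#' @seealso [writeStructure()], [partitionDimer()]
#' @export
readStructure <- function(path, keepHet = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB (frames with ",
                             "inconsistent atom counts?): ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- !(at$resid %in% .WATER_RESIDUES) & !(at$resid %in% .ION_RESIDUES)
  if (!keepHet) keep <- keep & at$type == "ATOM"
  idx <- which(keep)
  if (length(idx) == 0L) stop("zero atoms after filtering")
  at <- at[idx, ]

  ## alternate locations: keep the highest-occupancy conformer per
  ## (chain, residue, atom name); ties resolved by file order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  grp <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  ord <- order(grp, -occ, seq_along(grp))
  first <- !duplicated(grp[ord])
  sel <- sort(ord[first])
  at <- at[sel, ]
  idx <- idx[sel]

  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  cols <- bio3d::atom2xyz(idx)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, cols], ncol = 3, byrow = TRUE)
  })

  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(elem)
  if (any(bad)) elem[bad] <- .elementFromName(at$elety[bad])
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem, chain = chain,
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid, is_h = elem == "H",
    added_h = FALSE, stringsAsFactors = FALSE)
  new("Ensemble", atoms = atoms, frames = frames)
}

## PDB atom names encode the element in their leading characters
.elementFromName <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  el <- substr(n, 1, 1)
  el[substr(n, 1, 2) %in% c("CL", "BR", "FE", "MG", "ZN", "NA")] <-
    substr(n, 1, 2)[substr(n, 1, 2) %in% c("CL", "BR", "FE", "MG", "ZN", "NA")]
  ## hydrogens may be written as 1H.., 2H..
  el[grepl("^H", n)] <- "H"
  el
}

#' Write an ensemble as (multi-MODEL) PDB text
#'
#' Single-frame ensembles are written without MODEL records; multi-frame
#' ensembles get one MODEL/ENDMDL block per frame.  Atom serials beyond
#' the fixed-width PDB limit wrap around modulo 99999 (the reader never
#' relies on serials).  Round-tripping preserves names, numbering and
#' coordinates to the 3-decimal precision of the format.
#'
#' @param ens an [Ensemble-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(ens, path) {
  stopifnot(is(ens, "Ensemble"))
  a <- ens@atoms
  serial <- ((seq_len(nrow(a)) - 1L) %% 99999L) + 1L
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  multi <- length(ens@frames) > 1L
  nm <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
               sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  for (f in seq_along(ens@frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens@frames[[f]]
    lines <- sprintf(
      "ATOM  %5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm, " ", a$resname, substr(a$chain, 1, 1), a$resno,
      ifelse(nzchar(a$icode), a$icode, " "),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Partition the chains of a complex into two binding partners
#'
#' @param ens an [Ensemble-class].
#' @param chainsA,chainsB chain ids of the two partners; they must be
#'   disjoint, non-empty and together cover every chain of the ensemble.
#' @return a [DimerPartition-class].
#' @export
partitionDimer <- function(ens, chainsA, chainsB) {
  stopifnot(is(ens, "Ensemble"))
  have <- unique(ens@atoms$chain)
  unknown <- setdiff(c(chainsA, chainsB), have)
  if (length(unknown) > 0L)
    stop("unknown chain ", paste(unknown, collapse = ", "))
  if (length(intersect(chainsA, chainsB)) > 0L)
    stop("partners overlap")
  part <- new("DimerPartition", partnerA = as.character(chainsA),
              partnerB = as.character(chainsB))
  missing <- setdiff(have, c(chainsA, chainsB))
  if (length(missing) > 0L)
    stop("chains not assigned to a partner: ", paste(missing, collapse = ", "))
  part
}

#' Atom index sets of the two partners
#'
#' @param ens an [Ensemble-class].
#' @param part a [DimerPartition-class].
#' @return list with integer vectors `a` and `b`; together they cover
#'   all atoms exactly once.
#' @export
partitionIndices <- function(ens, part) {
  list(a = which(ens@atoms$chain %in% part@partnerA),
       b = which(ens@atoms$chain %in% part@partnerB))
}

#' Shift the residue numbering of one chain
#'
#' Adds a constant offset to the author residue numbers of a chain, e.g.
#' to move a construct-local numbering onto the full-length isoform
#' numbering convention.  Ordering and insertion codes are unchanged.
#'
#' @param ens an [Ensemble-class].
#' @param chain chain id.
#' @param offset integer shift.
#' @return the renumbered [Ensemble-class].
#' @export
renumberChain <- function(ens, chain, offset) {
  stopifnot(is(ens, "Ensemble"))
  if (!chain %in% ens@atoms$chain) stop("unknown chain ", chain)
  a <- ens@atoms
  a$resno[a$chain == chain] <- a$resno[a$chain == chain] + as.integer(offset)
  out <- new("Ensemble", atoms = a, frames = ens@frames)
  validObject(out)   # rejects duplicate (number, icode) pairs
  out
}
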