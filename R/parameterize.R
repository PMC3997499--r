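## Per-atom parameter assignment and in-silico alanine mutation.

#' Assign force-field parameters to every atom of an ensemble
#'
#' Matches every atom against the residue templates by name and attaches
#' partial charge, Lennard-Jones parameters, intrinsic Born radius and
#' descreening scale.  Chain termini are detected from chain ends and
#' receive the zwitterionic terminal patches (ammonium `H1..H3` / `N3`
#' nitrogen; carboxylate `O`/`OXT`), constructed so that each chain's
#' total charge equals the exact sum of residue formal charges.  The
#' structure must be complete, i.e. hydrogens built (see
#' [buildHydrogens()]).
#'
#' @param ens an [Ensemble-class], fully protonated.
#' @param pset parameter set from [loadParameterSet()].
#' @param part a [DimerPartition-class] for the ensemble's chains.
#' @return a [ParameterizedSystem-class].
#' @export
assignParameters <- function(ens, pset = loadParameterSet(), part) {
  stopifnot(is(ens, "Ensemble"), is(part, "DimerPartition"))
  a <- ens@atoms
  rkey <- paste(a$chain, a$resno, a$icode, sep = "|")
  resOrder <- unique(rkey)
  n <- nrow(a)
  charge <- rmin_half <- eps <- gb_radius <- gb_screen <- rep(NA_real_, n)

  for (ri in seq_along(resOrder)) {
    rows <- which(rkey == resOrder[ri])
    res <- a[rows, ]
    resname <- res$resname[1]
    tpl <- pset[[resname]]
    if (is.null(tpl))
      stop("no template for ", resname)
    chain <- res$chain[1]
    label <- paste0(chain, "/", res$resno[1], res$icode[1], " ", resname)
    isFirst <- ri == 1L || a$chain[which(rkey == resOrder[ri - 1L])[1]] != chain
    isLast <- ri == length(resOrder) ||
      a$chain[which(rkey == resOrder[ri + 1L])[1]] != chain

    tA <- tpl$atoms
    expected <- tA$name
    extraH <- character(0)
    if (isFirst) {
      extraH <- if (resname == "PRO") c("H2", "H3") else c("H1", "H2", "H3")
      expected <- c(setdiff(expected, "H"), extraH)
    }
    if (isLast) expected <- c(expected, "OXT")

    missing <- setdiff(expected, res$name)
    if (length(missing) > 0L) {
      mh <- tA$is_h[match(missing, tA$name)]
      mh[is.na(mh)] <- TRUE
      if (any(!mh))
        stop("missing heavy atom ", paste(missing[!mh], collapse = ","),
             " in ", label)
      stop("missing hydrogen(s) ", paste(missing, collapse = ","), " in ",
           label, " (run buildHydrogens first)")
    }
    unknown <- setdiff(res$name, expected)
    if (length(unknown) > 0L)
      stop("unexpected atom(s) ", paste(unknown, collapse = ","), " in ", label)

    m <- match(res$name, tA$name)
    charge[rows] <- tA$charge[m]
    rmin_half[rows] <- tA$rmin_half[m]
    eps[rows] <- tA$eps[m]
    gb_radius[rows] <- tA$gb_radius[m]
    gb_screen[rows] <- tA$gb_screen[m]

    ljH <- attr(pset, "lj_types")
    typeRow <- function(t) which(ljH$type == t)
    if (isFirst) {
      nh <- length(extraH)
      hs <- rows[res$name %in% extraH]
      charge[hs] <- .NTERM_H_CHARGE
      rmin_half[hs] <- ljH$rmin_half[typeRow("H")]
      eps[hs] <- ljH$eps[typeRow("H")]
      gb_radius[hs] <- 1.3
      gb_screen[hs] <- .GB_SCREEN[["H"]]
      ni <- rows[res$name == "N"]
      oldH <- if ("H" %in% tA$name) tA$charge[tA$name == "H"] else 0
      charge[ni] <- tA$charge[tA$name == "N"] + oldH + 1 - nh * .NTERM_H_CHARGE
      rmin_half[ni] <- ljH$rmin_half[typeRow("N3")]
      eps[ni] <- ljH$eps[typeRow("N3")]
    }
    if (isLast) {
      oi <- rows[res$name %in% c("O", "OXT")]
      oldO <- tA$charge[tA$name == "O"]
      charge[oi] <- .CTERM_O_CHARGE
      rmin_half[oi] <- ljH$rmin_half[typeRow("O2")]
      eps[oi] <- ljH$eps[typeRow("O2")]
      gb_radius[oi] <- .GB_RADIUS[["O"]]
      gb_screen[oi] <- .GB_SCREEN[["O"]]
      ci <- rows[res$name == "C"]
      charge[ci] <- tA$charge[tA$name == "C"] + oldO -
        2 * .CTERM_O_CHARGE - 1
    }
  }

  params <- data.frame(charge = charge, rmin_half = rmin_half, eps = eps,
                       gb_radius = gb_radius, gb_screen = gb_screen)
  sys <- new("ParameterizedSystem", ensemble = ens, params = params,
             partition = part)

  ## charge-closure invariant: zwitterionic termini cancel, so the total
  ## must equal the sum of residue formal charges
  formal <- sum(vapply(resOrder, function(k) {
    rn <- a$resname[which(rkey == k)[1]]
    pset[[rn]]$formal
  }, numeric(1)))
  if (abs(sum(params$charge) - formal) > 1e-3 * length(resOrder))
    stop("internal error: charge closure violated")
  sys
}

#' Residue-to-atom index map of a system
#'
#' @param sys a [ParameterizedSystem-class] (or [Ensemble-class]).
#' @return data.frame with one row per residue (`chain`, `resno`,
#'   `icode`, `resname`) plus a list column `atoms` of atom indices.
#' @export
residueIndex <- function(sys) {
  a <- if (is(sys, "ParameterizedSystem")) sys@ensemble@atoms else sys@atoms
  rkey <- paste(a$chain, a$resno, a$icode, sep = "|")
  resOrder <- unique(rkey)
  first <- match(resOrder, rkey)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  out$atoms <- lapply(resOrder, function(k) which(rkey == k))
  out
}

.BACKBONE_KEEP <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "C", "O", "OXT",
                    "CB")

#' Truncate a residue's side chain to alanine
#'
#' Removes all side-chain atoms beyond C-beta (including their
#' hydrogens), keeps C-beta at its original coordinates, renames the
#' residue to `ALA` and leaves the backbone untouched, in every frame.
#' Alanine's methyl hydrogens are not placed here; run
#' [buildHydrogens()] and [assignParameters()] on the result.  Mutating
#' an alanine is the identity operation; glycine (no C-beta) and proline
#' (backbone ring) are rejected, as is standard in alanine scanning.
#'
#' @param ens an [Ensemble-class].
#' @param chain chain id of the target residue.
#' @param resnum residue number of the target.
#' @param icode insertion code (default none).
#' @return the mutated [Ensemble-class].
#' @export
mutateToAlanine <- function(ens, chain, resnum, icode = "") {
  stopifnot(is(ens, "Ensemble"))
  a <- ens@atoms
  rows <- which(a$chain == chain & a$resno == resnum & a$icode == icode)
  if (length(rows) == 0L)
    stop("no residue ", resnum, icode, " in chain ", chain)
  resname <- a$resname[rows[1]]
  if (resname == "GLY") stop("cannot truncate glycine (no C-beta)")
  if (resname == "PRO") stop("cannot truncate proline (backbone ring)")
  if (!resname %in% names(loadParameterSet()))
    stop("unknown residue ", resname)
  if (resname == "ALA") return(ens)   # identity (rename is a no-op)

  drop <- rows[!a$name[rows] %in% .BACKBONE_KEEP]
  a$resname[rows] <- "ALA"
  if (length(drop) > 0L) {
    a <- a[-drop, ]
    frames <- lapply(ens@frames, function(x) x[-drop, , drop = FALSE])
  } else frames <- ens@frames
  rownames(a) <- NULL
  new("Ensemble", atoms = a, frames = frames)
}
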