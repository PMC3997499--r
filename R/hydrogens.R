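## Hydrogen (and terminal-atom) construction at ideal template geometry.
## Hydrogens are placed from the local frame of their bonded heavy atom
## using standard rules: tetrahedral completion for sp3 centres, in-plane
## completion for sp2 centres, staggered methyl/ammonium rotors, and
## anti-periplanar hydroxyl/thiol protons.  Existing hydrogens are never
## moved.

.H_BOND <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

#' Complete a structure with template-geometry hydrogens
#'
#' Adds every hydrogen the residue templates expect but the structure
#' lacks, in every frame, at ideal geometry; already-present hydrogens
#' are preserved.  Chain termini are completed for the zwitterionic
#' convention: the first residue of a chain gets an ammonium `H1..H3`
#' (`H2/H3` for proline; a pre-existing backbone `H` is renamed `H1`),
#' and the last residue gains `OXT` if absent.  Added atoms are flagged
#' in the atom table (`added_h`).
#'
#' @param ens an [Ensemble-class] (all frames are completed).
#' @param pset parameter set from [loadParameterSet()].
#' @param termini complete chain termini (ammonium hydrogens, OXT)?
#' @return the completed [Ensemble-class].
#' @examples
#' helix <- buildIdealHelix("ALYSG")
#' prot <- buildHydrogens(helix)
#' table(atomData(prot)$added_h)
#' @export
buildHydrogens <- function(ens, pset = loadParameterSet(), termini = TRUE) {
  stopifnot(is(ens, "Ensemble"))
  a <- ens@atoms
  rkey <- paste(a$chain, a$resno, a$icode, sep = "|")
  resOrder <- unique(rkey)
  nfr <- length(ens@frames)

  newAtoms <- list()
  newCoords <- lapply(seq_len(nfr), function(f) list())
  outOrder <- integer(0)   # indices into original atoms, -k for new atom k

  for (ri in seq_along(resOrder)) {
    rows <- which(rkey == resOrder[ri])
    res <- a[rows, ]
    resname <- res$resname[1]
    tpl <- pset[[resname]]
    if (is.null(tpl)) stop("no template for residue ", resname)
    chain <- res$chain[1]
    isFirst <- ri == 1L || a$chain[rows[1] - 1L] != chain
    isLast <- ri == length(resOrder) || {
      nxt <- which(rkey == resOrder[ri + 1L])[1]
      a$chain[nxt] != chain
    }

    ## rename a lone backbone H to H1 at the N-terminus
    if (termini && isFirst && resname != "PRO") {
      hi <- rows[res$name == "H"]
      if (length(hi) == 1L) {
        a$name[hi] <- "H1"
        res$name[res$name == "H"] <- "H1"
      }
    }

    outOrder <- c(outOrder, rows)
    present <- res$name

    ## expected hydrogens per heavy atom
    heavies <- tpl$atoms$name[!tpl$atoms$is_h]
    for (hv in heavies) {
      if (!hv %in% present) {
        if (hv %in% c("N", "CA", "C", "O"))
          stop("missing heavy anchor atom ", hv, " in ", resname, " ",
               chain, res$resno[1])
        next   # truncated side chain: nothing to protonate
      }
      expH <- .templateHydrogens(tpl, hv)
      if (termini && hv == "N" && isFirst)
        expH <- if (resname == "PRO") c("H2", "H3") else c("H1", "H2", "H3")
      missH <- setdiff(expH, present)
      if (length(missH) == 0L) next

      for (f in seq_len(nfr)) {
        pos <- .residuePositions(a, ens@frames[[f]], rows, rkey, ri, resOrder)
        hxyz <- .placeHydrogens(tpl, hv, missH, pos, present)
        for (k in seq_along(missH))
          newCoords[[f]][[length(newCoords[[f]]) + 1L]] <- hxyz[k, ]
      }
      for (h in missH) {
        newAtoms[[length(newAtoms) + 1L]] <- data.frame(
          serial = NA_integer_, name = h, element = "H", chain = chain,
          resno = res$resno[1], icode = res$icode[1], resname = resname,
          is_h = TRUE, added_h = TRUE, stringsAsFactors = FALSE)
        outOrder <- c(outOrder, -length(newAtoms))
        present <- c(present, h)
      }
      ## frame bookkeeping above appended per frame in the same order
    }

    ## carboxy terminus: complete the carboxylate
    if (termini && isLast && !"OXT" %in% present) {
      for (f in seq_len(nfr)) {
        pos <- .residuePositions(a, ens@frames[[f]], rows, rkey, ri, resOrder)
        if (!all(c("C", "CA", "O") %in% rownames(pos)))
          stop("missing heavy anchor atom for OXT in ", resname)
        u1 <- .unit(pos["CA", ] - pos["C", ])
        u2 <- .unit(pos["O", ] - pos["C", ])
        oxt <- pos["C", ] + 1.251 * -.unit(u1 + u2)
        newCoords[[f]][[length(newCoords[[f]]) + 1L]] <- oxt
      }
      newAtoms[[length(newAtoms) + 1L]] <- data.frame(
        serial = NA_integer_, name = "OXT", element = "O", chain = chain,
        resno = res$resno[1], icode = res$icode[1], resname = resname,
        is_h = FALSE, added_h = TRUE, stringsAsFactors = FALSE)
      outOrder <- c(outOrder, -length(newAtoms))
    }
  }

  if (length(newAtoms) == 0L) {
    out <- new("Ensemble", atoms = a, frames = ens@frames)
    return(out)
  }
  addA <- do.call(rbind, newAtoms)
  atoms <- rbind(a, addA)[ifelse(outOrder > 0, outOrder,
                                 nrow(a) - outOrder), ]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  frames <- lapply(seq_len(nfr), function(f) {
    addX <- do.call(rbind, newCoords[[f]])
    x <- rbind(ens@frames[[f]], addX)[ifelse(outOrder > 0, outOrder,
                                             nrow(a) - outOrder), , drop = FALSE]
    dimnames(x) <- NULL
    x
  })
  new("Ensemble", atoms = atoms, frames = frames)
}

## positions of this residue's atoms plus the adjacent backbone atoms
## (previous C, next N) as a named matrix
.residuePositions <- function(a, xyz, rows, rkey, ri, resOrder) {
  pos <- xyz[rows, , drop = FALSE]
  rownames(pos) <- a$name[rows]
  chain <- a$chain[rows[1]]
  if (ri > 1L) {
    prev <- which(rkey == resOrder[ri - 1L])
    if (a$chain[prev[1]] == chain) {
      pc <- prev[a$name[prev] == "C"]
      if (length(pc) == 1L) {
        pos <- rbind(pos, xyz[pc, ])
        rownames(pos)[nrow(pos)] <- "-C"
      }
    }
  }
  if (ri < length(resOrder)) {
    nxt <- which(rkey == resOrder[ri + 1L])
    if (a$chain[nxt[1]] == chain) {
      nn <- nxt[a$name[nxt] == "N"]
      if (length(nn) == 1L) {
        pos <- rbind(pos, xyz[nn, ])
        rownames(pos)[nrow(pos)] <- "+N"
      }
    }
  }
  pos
}

## Place the missing hydrogens of one heavy atom.  pos: named coordinate
## matrix of known atoms; present: names currently present.
.placeHydrogens <- function(tpl, heavy, missH, pos, present) {
  P <- pos[heavy, ]
  el <- tpl$atoms$element[match(heavy, tpl$atoms$name)]
  b <- .H_BOND[[el]]
  type <- tpl$atoms$type[match(heavy, tpl$atoms$name)]
  sp2 <- type %in% .SP2_TYPES
  ## an alpha-amino nitrogen gaining 2-3 protons is tetrahedral
  if (heavy == "N" && length(missH) >= 2L) sp2 <- FALSE

  nb <- .templateNeighbors(tpl, heavy, heavyOnly = FALSE)
  if (heavy == "N") nb <- c(nb, "-C")
  if (heavy == "C") nb <- c(nb, "+N")
  known <- intersect(c(nb, setdiff(.templateHydrogens(tpl, heavy), missH)),
                     rownames(pos))
  known <- setdiff(unique(known), missH)
  K <- pos[known, , drop = FALSE]
  if (nrow(K) == 0L)
    stop("missing heavy anchor atoms for hydrogen placement at ", heavy)

  out <- matrix(NA_real_, length(missH), 3)
  dirs <- t(apply(K, 1, function(x) .unit(x - P)))

  ## reference atom beyond the first neighbor, for rotor/dihedral rules
  refFor <- function(b1name) {
    cand <- .templateNeighbors(tpl, b1name, heavyOnly = TRUE)
    if (b1name == "CA" && heavy != "N") cand <- c("N", "C", cand)
    if (b1name == "N") cand <- c(cand, "-C")
    if (b1name == "C") cand <- c(cand, "+N")
    cand <- setdiff(intersect(cand, rownames(pos)), heavy)
    if (length(cand) == 0L) stop("no reference atom for rotor at ", heavy)
    pos[cand[1], ]
  }

  nK <- nrow(K)
  if (nK >= 3L && length(missH) == 1L) {
    d <- -.unit(colSums(dirs))
    out[1, ] <- P + b * d
  } else if (nK == 2L && length(missH) == 2L && !sp2) {
    u1 <- dirs[1, ]; u2 <- dirs[2, ]
    d <- -.unit(u1 + u2)
    n <- .unit(.cross(u1, u2))
    z <- 54.735 * pi / 180
    out[1, ] <- P + b * (cos(z) * d + sin(z) * n)
    out[2, ] <- P + b * (cos(z) * d - sin(z) * n)
  } else if (nK == 2L && length(missH) == 1L) {
    ## sp2 in-plane completion (also the sp3 fallback with 2 neighbors)
    d <- -.unit(dirs[1, ] + dirs[2, ])
    out[1, ] <- P + b * d
  } else if (nK == 1L && length(missH) == 3L) {
    B1 <- K[1, ]
    R <- refFor(known[1])
    phis <- c(180, 300, 60)
    ang <- if (sp2) 120 else 109.47
    for (k in 1:3)
      out[k, ] <- .placeInternal(R, B1, P, b, ang, phis[k])
  } else if (nK == 1L && length(missH) == 2L && sp2) {
    B1 <- K[1, ]
    R <- refFor(known[1])
    u <- .unit(P - B1)
    w <- (R - B1) - sum((R - B1) * u) * u
    w <- .unit(w)
    out[1, ] <- P + b * (0.5 * u + (sqrt(3) / 2) * w)
    out[2, ] <- P + b * (0.5 * u - (sqrt(3) / 2) * w)
  } else if (nK == 1L && length(missH) == 2L) {
    B1 <- K[1, ]
    R <- refFor(known[1])
    out[1, ] <- .placeInternal(R, B1, P, b, 109.47, 180)
    out[2, ] <- .placeInternal(R, B1, P, b, 109.47, 60)
  } else if (nK == 1L && length(missH) == 1L) {
    ## hydroxyl / thiol: anti-periplanar to the reference
    B1 <- K[1, ]
    R <- refFor(known[1])
    ang <- if (el == "S") 96 else 109.5
    out[1, ] <- .placeInternal(R, B1, P, b, ang, 180)
  } else {
    ## generic completion: place one at the open tetrahedral direction,
    ## then recurse for the rest
    d <- -.unit(colSums(dirs))
    out[1, ] <- P + b * d
    if (length(missH) > 1L) {
      pos2 <- rbind(pos, out[1, , drop = FALSE])
      rownames(pos2)[nrow(pos2)] <- missH[1]
      out[-1, ] <- .placeHydrogens(tpl, heavy, missH[-1], pos2,
                                   c(present, missH[1]))
    }
  }
  out
}
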