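## Synthetic-data generators.  These produce desk-scale stand-ins for
## every input class of the pipeline: ideal helical dimers with a
## controllable interface, seeded Gaussian pseudo-ensembles emulating MD
## snapshot sets, sigmoidal thermal-unfolding curves, and log-linear SEC
## standards.  The pseudo-ensembles are uncorrelated coordinate jitter,
## not physical dynamics; they exist to exercise estimators (means,
## SEMs, conservation laws), not to reproduce MD observables.

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

## ideal backbone internal coordinates (A, degrees)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.229,
            a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
            a_ca_c_o = 120.5, omega = 180)

#' Build an ideal alpha-helix
#'
#' Constructs a poly-peptide backbone at ideal helical torsions
#' (phi = -57, psi = -47 degrees by default) with standard bond
#' geometry, places side chains from a single template rotamer per
#' residue type (ideal template geometry superimposed on the local
#' backbone), and relieves steric clashes by a coarse 10-degree search
#' over the chi-1 rotation.  Heavy atoms only; run [buildHydrogens()]
#' before parameterization.  Consecutive C-alpha distances come out at
#' 3.8 +/- 0.1 A with a rise of ~1.5 A per residue.
#'
#' @param sequence one-letter amino-acid string, length >= 4.
#' @param start 3-vector: position of the first C-alpha (A).
#' @param axis helix axis direction (unit vector not required).
#' @param chain chain id.
#' @param phi,psi backbone torsions in degrees.
#' @param roll rotation of the helix about its own axis, degrees; shifts
#'   every residue's azimuth, e.g. to aim a given side chain at a
#'   partner helix.
#' @return a single-frame [Ensemble-class].
#' @export
buildIdealHelix <- function(sequence, start = c(0, 0, 0), axis = c(0, 0, 1),
                            chain = "A", phi = -57, psi = -47, roll = 0) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 4L) stop("sequence must have at least 4 residues")
  bad <- setdiff(seq1, names(.AA1TO3))
  if (length(bad) > 0L)
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ","))
  res3 <- unname(.AA1TO3[seq1])
  L <- length(res3)
  pset <- loadParameterSet()

  ## backbone by natural-extension construction
  N <- CA <- C <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$b_n_ca, 0, 0)
  ang <- .BB$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:L) {
    N[i, ] <- .placeInternal(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                             .BB$b_c_n, .BB$a_ca_c_n, psi)
    CA[i, ] <- .placeInternal(CA[i - 1, ], C[i - 1, ], N[i, ],
                              .BB$b_n_ca, .BB$a_c_n_ca, .BB$omega)
    C[i, ] <- .placeInternal(C[i - 1, ], N[i, ], CA[i, ],
                             .BB$b_ca_c, .BB$a_n_ca_c, phi)
  }

  atoms <- list(); coords <- list()
  placed <- matrix(numeric(0), 0, 3)   # all heavy atoms placed so far
  placedRes <- integer(0)
  for (i in seq_len(L)) {
    tpl <- pset[[res3[i]]]
    nm <- c("N", "CA", "C")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ])
    ## carbonyl oxygen: in the peptide plane, anti to the next N
    if (i < L) {
      u1 <- .unit(CA[i, ] - C[i, ])
      u2 <- .unit(N[i + 1, ] - C[i, ])
      o <- C[i, ] + .BB$b_c_o * -.unit(u1 + u2)
    } else {
      o <- .placeInternal(N[i, ], CA[i, ], C[i, ], .BB$b_c_o,
                          .BB$a_ca_c_o, psi + 180)
    }
    nm <- c(nm, "O"); xyz <- rbind(xyz, o)

    side <- tpl$atoms$name[!tpl$atoms$is_h &
                           !tpl$atoms$name %in% c("N", "CA", "C", "O")]
    if (length(side) > 0L) {
      k <- .kabsch(tpl$coords[c("N", "CA", "C"), ], rbind(N[i, ], CA[i, ], C[i, ]))
      sxyz <- .applyKabsch(tpl$coords[side, , drop = FALSE], k)
      rownames(sxyz) <- side
      ## clash relief: coarse chi-1 grid about the CA-CB axis
      if (nrow(placed) > 0L && "CB" %in% side && length(side) > 1L) {
        beyond <- setdiff(side, "CB")
        minDist <- function(S) {
          other <- placed[placedRes != i, , drop = FALSE]
          if (nrow(other) == 0L) return(Inf)
          min(.distmat(S, other))
        }
        if (minDist(sxyz[beyond, , drop = FALSE]) < 2.4) {
          axisCB <- sxyz["CB", ] - CA[i, ]
          best <- sxyz; bestD <- minDist(sxyz[beyond, , drop = FALSE])
          for (th in seq(10, 350, by = 10)) {
            Rm <- .rotmat(axisCB, th * pi / 180)
            cand <- sxyz
            cand[beyond, ] <- sweep(
              sweep(sxyz[beyond, , drop = FALSE], 2, sxyz["CB", ]) %*% t(Rm),
              2, sxyz["CB", ], "+")
            d <- minDist(cand[beyond, , drop = FALSE])
            if (d > bestD) { bestD <- d; best <- cand }
          }
          sxyz <- best
        }
      }
      nm <- c(nm, side); xyz <- rbind(xyz, sxyz)
    }
    rownames(xyz) <- NULL
    atoms[[i]] <- data.frame(
      serial = NA_integer_, name = unname(nm),
      element = unname(substr(nm, 1, 1)), chain = chain, resno = i, icode = "",
      resname = res3[i], is_h = FALSE, added_h = FALSE,
      stringsAsFactors = FALSE)
    coords[[i]] <- xyz
    placed <- rbind(placed, xyz)
    placedRes <- c(placedRes, rep(i, nrow(xyz)))
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  X <- do.call(rbind, coords)
  rownames(X) <- NULL

  ## orient the helix axis and anchor the first C-alpha
  ca <- X[a$name == "CA", , drop = FALSE]
  pc <- prcomp(ca)$rotation[, 1]
  if (sum(pc * (ca[nrow(ca), ] - ca[1, ])) < 0) pc <- -pc
  tgt <- .unit(axis)
  v <- .cross(pc, tgt)
  s <- sqrt(sum(v^2))
  if (s > 1e-9) {
    Rm <- .rotmat(v, atan2(s, sum(pc * tgt)))
    X <- X %*% t(Rm)
  } else if (sum(pc * tgt) < 0) {
    X <- -X
  }
  ## anchor: the helix axis runs through `start` along `axis`, with the
  ## first C-alpha at axial coordinate zero
  ca <- X[a$name == "CA", , drop = FALSE]
  X <- sweep(X, 2, colMeans(ca))
  ax1 <- sum(X[a$name == "CA", , drop = FALSE][1, ] * tgt)
  X <- sweep(X, 2, ax1 * tgt)
  if (roll != 0) X <- X %*% t(.rotmat(tgt, roll * pi / 180))
  X <- sweep(X, 2, start, "+")
  new("Ensemble", atoms = a, frames = list(unname(X)))
}

#' Build a two-helix dimer with a controllable interface
#'
#' Chain A runs along +z with its axis at y = +separation/2; chain B
#' sits at y = -separation/2.  With `c2_symmetric = TRUE` chain B is the
#' exact image of chain A under a 180-degree rotation about the x axis
#' through the bundle midpoint (hence antiparallel), which makes
#' downstream per-chain profiles exactly symmetric.  A "sticky"
#' interface is engineered through the sequences, e.g. an arginine on A
#' facing a glutamate on B.
#'
#' @param seq_a,seq_b one-letter sequences (B defaults to A).
#' @param separation axis-to-axis distance in A.
#' @param antiparallel antiparallel arrangement? (required for C2).
#' @param c2_symmetric make chain B the exact C2 image of chain A?
#' @param chains two chain ids.
#' @param roll_a,roll_b per-helix roll angles in degrees (see
#'   [buildIdealHelix()]); `roll_b` is applied before the antiparallel
#'   flip and is ignored for C2 dimers.
#' @return list with `ensemble` (heavy-atom [Ensemble-class]) and
#'   `partition` (a [DimerPartition-class]).
#' @export
buildHelixDimer <- function(seq_a, seq_b = seq_a, separation = 10,
                            antiparallel = TRUE, c2_symmetric = TRUE,
                            chains = c("A", "B"), roll_a = 0, roll_b = 0) {
  if (c2_symmetric && !antiparallel)
    stop("C2 symmetry about the inter-helix axis requires antiparallel")
  if (c2_symmetric && !identical(seq_a, seq_b))
    stop("C2 symmetry requires identical sequences")
  helA <- buildIdealHelix(seq_a, chain = chains[1], roll = roll_a)
  XA <- helA@frames[[1]]
  zmid <- mean(range(XA[, 3]))
  XA <- sweep(XA, 2, c(0, separation / 2, 0), "+")
  if (c2_symmetric) {
    aB <- helA@atoms
    aB$chain <- chains[2]
    ## 180 degrees about the x axis through (0, 0, zmid):
    ## (x, y, z) -> (x, -y, 2 zmid - z)
    XB <- cbind(XA[, 1], -XA[, 2], 2 * zmid - XA[, 3])
  } else {
    helB <- buildIdealHelix(seq_b, chain = chains[2], roll = roll_b)
    aB <- helB@atoms
    XB <- helB@frames[[1]]
    if (antiparallel) {
      zmB <- mean(range(XB[, 3]))
      XB <- cbind(XB[, 1], -XB[, 2], 2 * zmB - XB[, 3] + (zmid - zmB))
    }
    XB <- sweep(XB, 2, c(0, -separation / 2, 0), "+")
  }
  dmin <- min(.distmat(XA, XB))
  if (dmin < 2.0)
    stop(sprintf("steric collapse: minimum inter-chain distance %.2f A", dmin))
  atoms <- rbind(helA@atoms, aB)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  ens <- new("Ensemble", atoms = atoms, frames = list(rbind(XA, XB)))
  list(ensemble = ens,
       partition = partitionDimer(ens, chains[1], chains[2]))
}

#' Seeded Gaussian pseudo-ensemble
#'
#' Emulates an MD snapshot set by i.i.d. Gaussian displacement of every
#' atom in every frame (standard deviation `sigma` per coordinate).
#' Frame 1 is the unperturbed input.  A fixed seed gives byte-identical
#' output; the caller's RNG state is untouched.
#'
#' @param ens a (typically single-frame) [Ensemble-class]; frame 1 is
#'   the jitter reference.
#' @param sigma per-coordinate displacement scale in A (>= 0).
#' @param n_frames total number of frames (>= 1).
#' @param seed integer seed.
#' @return an [Ensemble-class] with `n_frames` frames.
#' @export
jitterEnsemble <- function(ens, sigma, n_frames, seed = 1L) {
  stopifnot(is(ens, "Ensemble"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_frames < 1L) stop("need at least one frame")
  X0 <- ens@frames[[1]]
  frames <- .withSeed(seed, {
    lapply(seq_len(n_frames), function(i) {
      if (i == 1L) X0
      else X0 + matrix(rnorm(length(X0), sd = sigma), nrow(X0), 3)
    })
  })
  new("Ensemble", atoms = ens@atoms, frames = frames)
}

#' Synthetic thermal-unfolding fluorescence curve
#'
#' Boltzmann sigmoid
#' `F(T) = f_min + (f_max - f_min) / (1 + exp((tm - T)/slope))` plus
#' i.i.d. Gaussian noise, with an optional exponential post-peak
#' aggregation decay starting at `aggregation_onset`.
#'
#' @param tm midpoint temperature (deg C), inside `t_range`.
#' @param slope transition width (deg C), > 0.
#' @param f_min,f_max baseline and plateau fluorescence (a.u.).
#' @param noise_sigma additive Gaussian noise (a.u.).
#' @param t_range temperature range, deg C.
#' @param step temperature step, > 0.
#' @param seed integer seed (noise only).
#' @param aggregation_onset optional temperature where signal decay
#'   starts; `aggregation_rate` is the exponential rate per deg C.
#' @param aggregation_rate see above.
#' @return data.frame with `temperature` and `fluorescence`.
#' @export
synthMeltingCurve <- function(tm, slope = 2, f_min = 0, f_max = 1000,
                              noise_sigma = 0, t_range = c(25, 95),
                              step = 0.5, seed = 1L,
                              aggregation_onset = NULL,
                              aggregation_rate = 0.02) {
  if (step <= 0) stop("step must be positive")
  if (slope <= 0) stop("slope must be positive")
  if (tm <= t_range[1] || tm >= t_range[2])
    stop("tm must lie inside t_range")
  temp <- seq(t_range[1], t_range[2], by = step)
  f <- f_min + (f_max - f_min) / (1 + exp((tm - temp) / slope))
  if (!is.null(aggregation_onset)) {
    dec <- temp > aggregation_onset
    f[dec] <- f_min + (f[dec] - f_min) *
      exp(-aggregation_rate * (temp[dec] - aggregation_onset))
  }
  if (noise_sigma > 0)
    f <- f + .withSeed(seed, rnorm(length(temp), sd = noise_sigma))
  data.frame(temperature = temp, fluorescence = f)
}

#' Synthetic SEC calibration standards
#'
#' Elution volumes generated from the log-linear model
#' `Ve = (log10(MW) - intercept) / slope` (+ optional Gaussian noise).
#' The default molecular-weight list is the classic gel-filtration
#' standard set (lysozyme through apoferritin).
#'
#' @param slope calibration slope (log10 Da per mL), must be negative.
#' @param intercept calibration intercept (log10 Da).
#' @param noise_sigma Gaussian noise on Ve (mL).
#' @param mw_list molecular weights in Da.
#' @param seed integer seed (noise only).
#' @return data.frame with `mw` and `ve`.
#' @export
synthSecStandards <- function(slope = -0.18, intercept = 7.2,
                              noise_sigma = 0,
                              mw_list = c(14000, 29000, 66000, 150000,
                                          200000, 443000),
                              seed = 1L) {
  if (slope >= 0) stop("SEC calibration slope must be negative")
  ve <- (log10(mw_list) - intercept) / slope
  if (noise_sigma > 0)
    ve <- ve + .withSeed(seed, rnorm(length(ve), sd = noise_sigma))
  data.frame(mw = mw_list, ve = ve)
}

#' "Sticky pair" dimer preset
#'
#' An antiparallel two-helix dimer carrying one deliberately sticky
#' interface residue on chain A whose side chain pairs with a charged
#' glutamate carboxylate on chain B and packs into a leucine groove
#' (Lennard-Jones contact).  The default core is a tryptophan: its
#' indole N-H donates a hydrogen bond to the carboxylate while the ring
#' buries hydrophobic surface, the combination that makes a residue a
#' genuine interface hot spot under an implicit-solvent effective
#' energy.  (A bare ion pair on the surface gains almost nothing net:
#' the generalized-Born desolvation penalty compensates the Coulomb
#' attraction.  `core_a = "R"` builds that variant, whose Arg-Glu pair
#' still dominates the inter-partner electrostatic pair ledger.)
#'
#' The two engineered side chains are posed by a coarse 10-degree
#' chi-1 grid search: sterically feasible rotamer combinations are
#' ranked by a heavy-atom contact score and the best few are re-scored
#' with the full-atom inter-partner nonbonded energy.
#'
#' @param len helix length in residues (>= 12; default 13).
#' @param separation axis-to-axis distance in A (default 13.5).
#' @param core_a residue (one-letter) of the sticky core on A.
#' @param chains two chain ids.
#' @return list with `ensemble` (heavy atoms), `partition`, and
#'   `sticky` (data.frame of the engineered pair; row 1 is the sticky
#'   core on chain A).
#' @export
buildStickyDimer <- function(len = 13, separation = 13.5, core_a = "W",
                             chains = c("A", "B")) {
  stopifnot(len >= 12)
  i <- ceiling(len / 2) + 1L       # sticky core on A
  j <- len + 1L - i                # facing glutamate on B
  mk <- function(center, core, collar) {
    s <- rep("A", len)
    s[intersect(center + collar, seq_len(len))] <- "L"
    s[center] <- core
    paste(s, collapse = "")
  }
  seqA <- mk(i, core_a, integer(0))
  seqB <- mk(j, "E", c(-4L, -3L, 3L, 4L))

  ## roll each helix so the engineered side chain points into the
  ## interface (azimuth -90 degrees before assembly)
  aimRoll <- function(seq1, pos) {
    h <- buildIdealHelix(seq1)
    X <- h@frames[[1]]; at <- h@atoms
    v <- X[at$resno == pos & at$name == "CB", ] -
      X[at$resno == pos & at$name == "CA", ]
    -90 - atan2(v[2], v[1]) * 180 / pi
  }
  d <- buildHelixDimer(seqA, seqB, separation = separation,
                       antiparallel = TRUE, c2_symmetric = FALSE,
                       chains = chains,
                       roll_a = aimRoll(seqA, i), roll_b = aimRoll(seqB, j))

  at <- d$ensemble@atoms
  X <- d$ensemble@frames[[1]]
  resA <- which(at$chain == chains[1] & at$resno == i)
  resB <- which(at$chain == chains[2] & at$resno == j)
  bb <- c("N", "CA", "C", "O", "CB")
  movA <- resA[!at$name[resA] %in% bb]
  movB <- resB[!at$name[resB] %in% bb]
  caA <- resA[at$name[resA] == "CA"]; cbA <- resA[at$name[resA] == "CB"]
  caB <- resB[at$name[resB] == "CA"]; cbB <- resB[at$name[resB] == "CB"]
  other <- setdiff(seq_len(nrow(X)), c(resA, resB))

  pset <- loadParameterSet()
  ljOf <- function(rows) {
    tpl <- pset[[at$resname[rows[1]]]]
    m <- match(at$name[rows], tpl$atoms$name)
    list(rh = tpl$atoms$rmin_half[m], eps = tpl$atoms$eps[m])
  }
  pA <- ljOf(resA); pB <- ljOf(resB)
  contactScore <- function(Xc) {
    r <- .distmat(Xc[resA, , drop = FALSE], Xc[resB, , drop = FALSE])
    rmin <- outer(pA$rh, pB$rh, "+")
    epsm <- sqrt(outer(pA$eps, pB$eps))
    sr6 <- (rmin / r)^6
    sum(epsm * (sr6^2 - 2 * sr6))
  }
  spin <- function(Xc, rows, ca, cb, theta) {
    Rm <- .rotmat(Xc[cb, ] - Xc[ca, ], theta * pi / 180)
    Xc[rows, ] <- sweep(sweep(Xc[rows, , drop = FALSE], 2, Xc[cb, ]) %*%
                          t(Rm), 2, Xc[cb, ], "+")
    Xc
  }
  cand <- list(); score <- numeric(0)
  for (thA in seq(0, 350, by = 10)) {
    XA2 <- spin(X, movA, caA, cbA, thA)
    for (thB in seq(0, 350, by = 10)) {
      Xc <- spin(XA2, movB, caB, cbB, thB)
      mv <- Xc[c(movA, movB), , drop = FALSE]
      if (min(.distmat(mv, Xc[other, , drop = FALSE])) < 2.6) next
      cand[[length(cand) + 1L]] <- Xc
      score <- c(score, contactScore(Xc))
    }
  }
  ## full-atom interaction energy of the engineered pair only, so the
  ## chosen pose optimizes the designed contact rather than incidental
  ## backbone interactions
  fullPairEnergy <- function(sys) {
    a2 <- atomData(sys)
    ra <- which(a2$chain == chains[1] & a2$resno == i)
    rb <- which(a2$chain == chains[2] & a2$resno == j)
    X2 <- frameCoords(sys)
    p <- atomParams(sys)
    r <- .distmat(X2[ra, , drop = FALSE], X2[rb, , drop = FALSE])
    rmin <- outer(p$rmin_half[ra], p$rmin_half[rb], "+")
    epsm <- sqrt(outer(p$eps[ra], p$eps[rb]))
    sr6 <- (rmin / r)^6
    sum(.COULOMB * outer(p$charge[ra], p$charge[rb]) / r) +
      sum(epsm * (sr6^2 - 2 * sr6))
  }
  if (length(cand) > 0L) {
    keep <- order(score)[seq_len(min(40L, length(cand)))]
    bestE <- Inf; bestX <- NULL
    for (k in keep) {
      ens <- tryCatch(
        buildHydrogens(new("Ensemble", atoms = at, frames = cand[k])),
        error = function(e) NULL)
      if (is.null(ens)) next
      sys <- assignParameters(ens, pset, d$partition)
      e <- fullPairEnergy(sys)
      if (e < bestE) { bestE <- e; bestX <- cand[[k]] }
    }
    if (!is.null(bestX))
      d$ensemble <- new("Ensemble", atoms = at, frames = list(bestX))
  }
  d$sticky <- data.frame(chain = chains, resno = c(i, j),
                         resname = c(unname(.AA1TO3[toupper(core_a)]), "GLU"),
                         stringsAsFactors = FALSE)
  d
}
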