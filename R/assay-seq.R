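## Sequence-derived properties: molecular weight, A280 extinction
## coefficient, and pairwise identity/similarity from a global
## alignment.

## average residue masses (Da); a free peptide adds one water
.RESIDUE_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                   V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                   I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                   K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                   F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MASS <- 18.015

.checkSeq <- function(seq) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L || !nzchar(s)) stop("empty sequence")
  letters1 <- strsplit(s, "")[[1]]
  bad <- setdiff(letters1, names(.RESIDUE_MASS))
  if (length(bad) > 0L)
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ","))
  letters1
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (18.015 Da).
#'
#' @param seq one-letter amino-acid string (or an `AAString`).
#' @return molecular weight in Da.
#' @examples
#' sequenceMw("G")    # 75.07
#' @export
sequenceMw <- function(seq) {
  aa <- .checkSeq(seq)
  sum(.RESIDUE_MASS[aa]) + .WATER_MASS
}

#' Molar extinction coefficient at 280 nm
#'
#' `eps = 5500 * nTrp + 1490 * nTyr + 125 * n_cystine_pairs`, with
#' cystine pairs counted as `floor(nCys / 2)` when `assume_cystines`.
#'
#' @param seq one-letter amino-acid string.
#' @param assume_cystines count cysteines as disulfide-paired (default
#'   TRUE, the usual computed-parameter convention)?
#' @return extinction coefficient in 1/(M cm).
#' @export
extinction280 <- function(seq, assume_cystines = TRUE) {
  aa <- .checkSeq(seq)
  n <- table(factor(aa, levels = names(.RESIDUE_MASS)))
  pairs <- if (assume_cystines) floor(n[["C"]] / 2) else 0
  5500 * n[["W"]] + 1490 * n[["Y"]] + 125 * pairs
}

#' Percent identity and similarity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties and a
#' substitution matrix (BLOSUM62 by default).  Identity is the fraction
#' of aligned columns, gaps excluded from the denominator, where both
#' residues are identical; similarity additionally counts columns with
#' a positive substitution score.  Both are reported as integer
#' percentages.  The measure is symmetric in its arguments.
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @param matrix substitution matrix name (shipped with Biostrings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return named numeric vector `c(identity, similarity)` in percent.
#' @export
identitySimilarity <- function(seq_a, seq_b, matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 0.5) {
  .checkSeq(seq_a); .checkSeq(seq_b)
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  submat <- get(matrix, envir = env)
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pa != "-" & sa != "-"
  pa <- pa[both]; sa <- sa[both]
  ident <- pa == sa
  pos <- submat[cbind(pa, sa)] > 0
  c(identity = round(100 * mean(ident)),
    similarity = round(100 * mean(pos)))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Bundled Hsp90 C-terminal-domain fragments
#'
#' The three C-terminal-domain fragments used for the template
#' comparisons: human Hsp90-alpha (UniProt P07900, residues 561-697),
#' yeast Hsp82 (P02829, 540-677) and E. coli HtpG (P0A6Z3, 510-624).
#' The entries are offline transcriptions bundled with the package; the
#' yeast and E. coli fragments are approximate transcriptions, so
#' percentages computed from them carry an uncertainty of a few points.
#'
#' @return named character vector with elements `human`, `yeast`,
#'   `ecoli`.
#' @export
hsp90CtdSequences <- function() {
  fa <- readFastaSequences(system.file("extdata", "hsp90_ctd_fragments.fasta",
                                       package = "HotspotGBSA"))
  setNames(fa, c("human", "yeast", "ecoli")[
    match(substr(names(fa), 1, 6), c("P07900", "P02829", "P0A6Z3"))])
}
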