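#!/usr/bin/env Rscript

## Thin command-line front end over the package's exported functions.
##
##   Rscript scripts/hotspot-tools.R <command> [options]
##
## commands:
##   scan      decomposition + hot/cold classification of a dimer PDB
##   alascan   alanine scanning at listed positions
##   burial    residue-wise relative burial
##   tm        melting temperature from a T/F table
##   sec       SEC calibration from a MW/Ve table (+ optional query Ve)
##   seqprops  molecular weight and extinction coefficient of sequences
##   align     pairwise identity/similarity of two FASTA records
##   synth     write synthetic inputs (helix-dimer | melt | sec)

suppressPackageStartupMessages({
  library(optparse)
  library(HotspotGBSA)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: hotspot-tools.R <scan|alascan|burial|tm|sec|seqprops|align|synth> ...")
cmd <- args[1]
rest <- args[-1]

optCommon <- list(
  make_option("--pdb", type = "character", help = "input (multi-MODEL) PDB"),
  make_option("--chains-a", type = "character", default = "A"),
  make_option("--chains-b", type = "character", default = "B"),
  make_option("--config", type = "character", default = NULL,
              help = "YAML with gb:/sasa:/thresholds: sections"),
  make_option("--out", type = "character", default = "out.tsv"),
  make_option("--positions", type = "character", default = NULL,
              help = "TSV with chain, resno columns (alascan)"),
  make_option("--input", type = "character", default = NULL,
              help = "tabular input (tm/sec) or FASTA (seqprops/align)"),
  make_option("--ve", type = "double", default = NA,
              help = "query elution volume for sec"),
  make_option("--what", type = "character", default = "helix-dimer"),
  make_option("--seq", type = "character", default = "AAALAAAA"),
  make_option("--separation", type = "double", default = 10),
  make_option("--sigma", type = "double", default = 0.2),
  make_option("--frames", type = "integer", default = 5L),
  make_option("--tm", type = "double", default = 73),
  make_option("--noise", type = "double", default = 0),
  make_option("--seed", type = "integer", default = 1L))
o <- parse_args(OptionParser(option_list = optCommon), args = rest)

loadSystem <- function(o) {
  ens <- buildHydrogens(readStructure(o$pdb))
  part <- partitionDimer(ens,
                         strsplit(o$`chains-a`, ",")[[1]],
                         strsplit(o$`chains-b`, ",")[[1]])
  assignParameters(ens, part = part)
}

cfg <- readRunConfig(o$config)
message(sprintf("ionic strength %.3f M | probe %.2f A | %d sphere points | hot < %.2f",
                cfg$gb$ionic_strength, cfg$sasa$probe_radius,
                cfg$sasa$n_sphere_points, cfg$thresholds@hot_cutoff))

if (cmd == "scan") {
  sys <- loadSystem(o)
  rt <- decomposeResidues(sys, gb = cfg$gb, sasa = cfg$sasa)
  rep <- classifySpots(rt, cfg$thresholds,
                       relativeBurial(sys, sasa = cfg$sasa))
  exportReport(rep, o$out)
  print(rep)
} else if (cmd == "alascan") {
  sys <- loadSystem(o)
  pos <- read.delim(o$positions)
  sc <- alanineScan(sys, pos, gb = cfg$gb, sasa = cfg$sasa)
  write.table(sc@table, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
  print(sc)
} else if (cmd == "burial") {
  sys <- loadSystem(o)
  bur <- relativeBurial(sys, sasa = cfg$sasa)
  write.table(bur, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
} else if (cmd == "tm") {
  cv <- read.delim(o$input)
  r1 <- tmFromDerivative(cv)
  r2 <- tryCatch(tmSigmoidFit(cv), error = function(e) NULL)
  print(r1)
  if (!is.null(r2)) print(r2)
} else if (cmd == "sec") {
  cal <- secCalibrate(read.delim(o$input))
  print(cal)
  if (!is.na(o$ve)) print(predictMw(cal, o$ve))
} else if (cmd == "seqprops") {
  fa <- readFastaSequences(o$input)
  for (nm in names(fa))
    cat(sprintf("%s\tMW %.1f Da\teps280 %d /M/cm\n", nm,
                sequenceMw(fa[[nm]]), extinction280(fa[[nm]])))
} else if (cmd == "align") {
  fa <- readFastaSequences(o$input)
  if (length(fa) < 2L) stop("align needs a FASTA with two records")
  print(identitySimilarity(fa[[1]], fa[[2]]))
} else if (cmd == "synth") {
  if (o$what == "helix-dimer") {
    d <- buildHelixDimer(o$seq, separation = o$separation)
    writeStructure(jitterEnsemble(d$ensemble, o$sigma, o$frames,
                                  seed = o$seed), o$out)
  } else if (o$what == "melt") {
    write.table(synthMeltingCurve(o$tm, noise_sigma = o$noise, seed = o$seed),
                o$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (o$what == "sec") {
    write.table(synthSecStandards(noise_sigma = o$noise, seed = o$seed),
                o$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unknown synth target: ", o$what)
  cat("wrote", o$out, "\n")
} else {
  stop("unknown command: ", cmd)
}
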