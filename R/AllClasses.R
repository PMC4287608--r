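# Core S4 containers for the stochastic-variation QTL pipeline.

#' @include AllGenerics.R
NULL

#' Genetic map
#'
#' Ordered marker positions (centiMorgan) per chromosome; the coordinate
#' system shared by the genotype simulator, the genome scans and the hotspot
#' analysis.
#'
#' @slot chrom character, chromosome id per marker (grouped).
#' @slot marker character, genome-wide unique marker ids.
#' @slot pos numeric, cM position per marker, nondecreasing within chromosome.
#' @export
setClass("GeneticMap",
  representation(chrom = "character", marker = "character", pos = "numeric"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  n <- length(object@marker)
  if (length(object@chrom) != n || length(object@pos) != n)
    msg <- c(msg, "chrom, marker and pos must have equal length")
  if (n == 0L) msg <- c(msg, "map has no markers")
  if (anyDuplicated(object@marker))
    msg <- c(msg, "marker ids must be unique genome-wide")
  if (any(!is.finite(object@pos)) || any(object@pos < 0))
    msg <- c(msg, "positions must be finite and >= 0")
  # chromosomes must be contiguous blocks, positions nondecreasing within
  if (n > 0L && !length(msg)) {
    r <- rle(object@chrom)
    if (anyDuplicated(r$values))
      msg <- c(msg, "markers of one chromosome must be contiguous")
    bad <- tapply(object@pos, factor(object@chrom, unique(object@chrom)),
                  function(p) is.unsorted(p))
    if (any(bad)) msg <- c(msg, "positions must be nondecreasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap
#'
#' @param chrom chromosome id per marker.
#' @param marker marker ids (unique).
#' @param pos cM positions.
#' @return A [GeneticMap-class] object, markers sorted within chromosome.
#' @examples
#' GeneticMap(rep("I", 3), c("m1", "m2", "m3"), c(0, 5, 10))
#' @export
GeneticMap <- function(chrom, marker, pos) {
  chrom <- as.character(chrom); marker <- as.character(marker)
  pos <- as.numeric(pos)
  o <- order(factor(chrom, levels = unique(chrom)), pos)
  new("GeneticMap", chrom = chrom[o], marker = marker[o], pos = pos[o])
}

#' @describeIn GeneticMap chromosome ids in map order.
#' @param x a GeneticMap.
#' @export
setMethod("chromosomes", "GeneticMap", function(x) unique(x@chrom))

#' @describeIn GeneticMap marker ids in map order.
#' @export
setMethod("markerNames", "GeneticMap", function(x) x@marker)

#' @describeIn GeneticMap data.frame of (chrom, marker, pos).
#' @export
setMethod("markerTable", "GeneticMap", function(x)
  data.frame(chrom = x@chrom, marker = x@marker, pos = x@pos,
             stringsAsFactors = FALSE))

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@marker), "markers on",
      length(unique(object@chrom)), "chromosomes\n")
  for (ch in chromosomes(object)) {
    p <- object@pos[object@chrom == ch]
    cat(sprintf("  %s: %d markers, %.1f-%.1f cM\n", ch, length(p), min(p), max(p)))
  }
})

#' Experimental design specification for the simulator
#'
#' A perfectly balanced randomized complete block design: every line appears
#' once per block, in every block of every experiment.
#'
#' @slot nLines number of RILs.
#' @slot nExperiments number of independent experiments.
#' @slot repsPerExperiment blocks (= replicates) per experiment.
#' @slot seed integer seed making all simulator output reproducible.
#' @export
setClass("DesignSpec",
  representation(nLines = "integer", nExperiments = "integer",
                 repsPerExperiment = "integer", seed = "integer"))

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (object@nLines < 1L) msg <- c(msg, "nLines must be >= 1")
  if (object@nExperiments < 1L) msg <- c(msg, "nExperiments must be >= 1")
  if (object@repsPerExperiment < 1L) msg <- c(msg, "repsPerExperiment must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignSpec
#'
#' Defaults reflect the reciprocal-RIL metabolomics design this package
#' is built around: 316 reciprocal
#' RILs measured in duplicate (2 randomized complete blocks) in each of 2
#' independent experiments.
#'
#' @param nLines,nExperiments,repsPerExperiment,seed see slots.
#' @return A [DesignSpec-class].
#' @export
DesignSpec <- function(nLines = 316L, nExperiments = 2L,
                       repsPerExperiment = 2L, seed = 1L) {
  new("DesignSpec", nLines = as.integer(nLines),
      nExperiments = as.integer(nExperiments),
      repsPerExperiment = as.integer(repsPerExperiment),
      seed = as.integer(seed))
}

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf("DesignSpec: %d lines x %d experiments x %d blocks (seed %d)\n",
              object@nLines, object@nExperiments, object@repsPerExperiment,
              object@seed))
})

#' Reciprocal RIL genotypes
#'
#' Fully inbred line-by-marker biallelic genotypes plus a per-line cytoplasm
#' label. "A" is the first parent's allele, "B" the second's; cytoplasm labels
#' are "A_CYT"/"B_CYT" and double as an extra single-locus marker in the
#' marker models.
#'
#' @slot alleles character matrix (lines x markers) of "A"/"B" (NA = missing).
#' @slot cytoplasmLabel character per line, "A_CYT" or "B_CYT".
#' @slot map the [GeneticMap-class] the columns refer to.
#' @export
setClass("RILGenotypes",
  representation(alleles = "matrix", cytoplasmLabel = "character",
                 map = "GeneticMap"))

setValidity("RILGenotypes", function(object) {
  msg <- character()
  a <- object@alleles
  if (!is.character(a)) msg <- c(msg, "alleles must be a character matrix")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "alleles must have line rownames and marker colnames")
  else {
    if (!identical(colnames(a), markerNames(object@map)))
      msg <- c(msg, "allele columns must match the map's markers in order")
    if (!all(a[!is.na(a)] %in% c("A", "B")))
      msg <- c(msg, "allele codes must be 'A' or 'B' (no heterozygotes)")
    if (length(object@cytoplasmLabel) != nrow(a))
      msg <- c(msg, "one cytoplasm label per line is required")
    if (!all(object@cytoplasmLabel %in% c("A_CYT", "B_CYT")))
      msg <- c(msg, "cytoplasm labels must be 'A_CYT' or 'B_CYT'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct RILGenotypes
#'
#' @param alleles character matrix of "A"/"B", rows = lines, cols = markers.
#' @param cytoplasm per-line "A_CYT"/"B_CYT" labels.
#' @param map the [GeneticMap-class].
#' @return A [RILGenotypes-class].
#' @export
RILGenotypes <- function(alleles, cytoplasm, map) {
  new("RILGenotypes", alleles = alleles,
      cytoplasmLabel = as.character(cytoplasm), map = map)
}

#' @describeIn RILGenotypes line ids.
#' @param x a RILGenotypes.
#' @export
setMethod("lineNames", "RILGenotypes", function(x) rownames(x@alleles))

#' @describeIn RILGenotypes raw "A"/"B" allele matrix.
#' @export
setMethod("alleles", "RILGenotypes", function(x) x@alleles)

#' @describeIn RILGenotypes numeric allele coding: A = +1, B = -1, so an
#'   additive effect equals half the difference between class means.
#' @export
setMethod("alleleCodes", "RILGenotypes", function(x) {
  m <- matrix(NA_real_, nrow(x@alleles), ncol(x@alleles),
              dimnames = dimnames(x@alleles))
  m[x@alleles == "A"] <- 1
  m[x@alleles == "B"] <- -1
  m
})

#' @describeIn RILGenotypes per-line cytoplasm labels (named by line).
#' @export
setMethod("cytoplasm", "RILGenotypes", function(x) {
  stats::setNames(x@cytoplasmLabel, rownames(x@alleles))
})

#' @describeIn RILGenotypes the underlying genetic map.
#' @export
setMethod("markerTable", "RILGenotypes", function(x) markerTable(x@map))

setMethod("show", "RILGenotypes", function(object) {
  cat(sprintf("RILGenotypes: %d lines x %d markers (%d A_CYT / %d B_CYT)\n",
              nrow(object@alleles), ncol(object@alleles),
              sum(object@cytoplasmLabel == "A_CYT"),
              sum(object@cytoplasmLabel == "B_CYT")))
})

#' Simulator ground truth: the genetic architecture
#'
#' Holds the generating values of the phenotype model: for line l and trait t
#' with marker codes x in \{-1, +1\} and cytoplasm code z in \{-1, +1\},
#' \deqn{\mu_{lt} = grandMean + \sum a x + c_{\mu} z + \sum \gamma x_1 x_2}
#' \deqn{\log\sigma_{lt} = \log(baseSd) + \sum b x + c_{\sigma} z}
#' Used as the oracle for parameter-recovery tests.
#'
#' @slot traits trait ids covered by this architecture.
#' @slot grandMean baseline trait mean.
#' @slot meanQTL data.frame(chrom, pos, effect, trait): additive effects a on
#'   the line mean.
#' @slot varQTL data.frame(chrom, pos, effect, trait): effects b on log line SD.
#' @slot cytoMeanEffect named numeric per trait, cytoplasm effect on the mean.
#' @slot cytoSdEffect named numeric per trait, cytoplasm effect on log SD.
#' @slot epistasis data.frame(chrom1, pos1, chrom2, pos2, effect, trait):
#'   pairwise interaction effects on the mean.
#' @slot baseSd baseline within-line SD (> 0).
#' @slot experimentEffects additive shift per experiment.
#' @slot blockEffects additive shift per block within experiment (recycled).
#' @export
setClass("TrueArchitecture",
  representation(traits = "character", grandMean = "numeric",
                 meanQTL = "data.frame", varQTL = "data.frame",
                 cytoMeanEffect = "numeric", cytoSdEffect = "numeric",
                 epistasis = "data.frame", baseSd = "numeric",
                 experimentEffects = "numeric", blockEffects = "numeric"))

setValidity("TrueArchitecture", function(object) {
  msg <- character()
  if (length(object@baseSd) != 1L || !is.finite(object@baseSd) ||
      object@baseSd <= 0)
    msg <- c(msg, "baseSd must be a single finite value > 0")
  if (!length(object@traits)) msg <- c(msg, "at least one trait id required")
  eff <- c(object@meanQTL$effect, object@varQTL$effect, object@cytoMeanEffect,
           object@cytoSdEffect, object@epistasis$effect, object@grandMean,
           object@experimentEffects, object@blockEffects)
  if (any(!is.finite(eff))) msg <- c(msg, "all effects must be finite")
  if (length(msg)) msg else TRUE
})

.qtlFrame <- function(df, cols) {
  if (is.null(df) || !nrow(as.data.frame(df))) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$trait <- character(0)
    if ("chrom" %in% cols) out$chrom <- character(0)
    if ("chrom1" %in% cols) { out$chrom1 <- character(0); out$chrom2 <- character(0) }
    return(out[, c(cols, "trait")])
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c(cols, "trait") %in% names(df)))
  df[, c(cols, "trait")]
}

#' Construct a TrueArchitecture
#'
#' @param traits trait ids.
#' @param grandMean baseline mean (default 10).
#' @param meanQTL,varQTL data.frames with columns chrom, pos, effect, trait
#'   (NULL for none).
#' @param cytoMeanEffect,cytoSdEffect scalar (recycled over traits) or named
#'   numeric per trait.
#' @param epistasis data.frame with chrom1, pos1, chrom2, pos2, effect, trait.
#' @param baseSd baseline within-line SD, > 0 (default 1).
#' @param experimentEffects,blockEffects additive shifts.
#' @return A [TrueArchitecture-class].
#' @export
TrueArchitecture <- function(traits, grandMean = 10, meanQTL = NULL,
                             varQTL = NULL, cytoMeanEffect = 0,
                             cytoSdEffect = 0, epistasis = NULL, baseSd = 1,
                             experimentEffects = 0, blockEffects = 0) {
  traits <- as.character(traits)
  expand <- function(v) {
    if (is.null(names(v)) && length(v) == 1L)
      return(stats::setNames(rep(as.numeric(v), length(traits)), traits))
    out <- stats::setNames(rep(0, length(traits)), traits)
    out[names(v)] <- as.numeric(v)
    out
  }
  new("TrueArchitecture", traits = traits, grandMean = as.numeric(grandMean),
      meanQTL = .qtlFrame(meanQTL, c("chrom", "pos", "effect")),
      varQTL = .qtlFrame(varQTL, c("chrom", "pos", "effect")),
      cytoMeanEffect = expand(cytoMeanEffect),
      cytoSdEffect = expand(cytoSdEffect),
      epistasis = .qtlFrame(epistasis,
                            c("chrom1", "pos1", "chrom2", "pos2", "effect")),
      baseSd = as.numeric(baseSd),
      experimentEffects = as.numeric(experimentEffects),
      blockEffects = as.numeric(blockEffects))
}

setMethod("show", "TrueArchitecture", function(object) {
  cat(sprintf(paste0("TrueArchitecture: %d traits, %d mean-QTL, %d vQTL, ",
                     "%d epistatic pairs, baseSd %.3g\n"),
              length(object@traits), nrow(object@meanQTL), nrow(object@varQTL),
              nrow(object@epistasis), object@baseSd))
})

#' Per-line coefficient-of-variation table
#'
#' Holds per (line, phenotype, experiment) CV estimates and their per-line
#' aggregation (mean of per-experiment CVs), with undefined entries flagged
#' explicitly rather than silently zeroed.
#'
#' @slot perExperiment data.frame(line, phenotype, experiment, n, mean, sd,
#'   cv, defined).
#' @slot perLine data.frame(line, phenotype, nExperiments, meanCV, grandMean,
#'   defined).
#' @export
setClass("LineCVTable",
  representation(perExperiment = "data.frame", perLine = "data.frame"))

setValidity("LineCVTable", function(object) {
  msg <- character()
  pe <- object@perExperiment; pl <- object@perLine
  if (!all(c("line", "phenotype", "experiment", "n", "mean", "sd", "cv",
             "defined") %in% names(pe)))
    msg <- c(msg, "perExperiment is missing required columns")
  if (!all(c("line", "phenotype", "nExperiments", "meanCV", "grandMean",
             "defined") %in% names(pl)))
    msg <- c(msg, "perLine is missing required columns")
  if (!length(msg) && any(pe$cv[pe$defined] < 0, na.rm = TRUE))
    msg <- c(msg, "CV must be >= 0 where defined")
  if (length(msg)) msg else TRUE
})

#' @describeIn LineCVTable per-(line, phenotype) aggregated table.
#' @param x a LineCVTable.
#' @export
setMethod("perLineCV", "LineCVTable", function(x) x@perLine)

#' @describeIn LineCVTable per-(line, phenotype, experiment) table.
#' @export
setMethod("perExperimentCV", "LineCVTable", function(x) x@perExperiment)

setMethod("show", "LineCVTable", function(object) {
  pl <- object@perLine
  cat(sprintf("LineCVTable: %d lines x %d phenotypes (%d undefined entries)\n",
              length(unique(pl$line)), length(unique(pl$phenotype)),
              sum(!pl$defined)))
})

#' Conditional genotype probability grid
#'
#' P(allele A) for every line at every pseudomarker position of a fixed-step
#' grid covering the map, conditioned on the flanking observed markers via
#' RIL-expanded Haldane recombination fractions. At a genotyped, non-missing
#' marker the probability is exactly 0 or 1.
#'
#' @slot chrom chromosome id per grid position.
#' @slot pos cM per grid position.
#' @slot markerId marker id where a position coincides with a marker, else NA.
#' @slot probA numeric matrix, lines x positions, in [0, 1].
#' @export
setClass("GenotypeProbabilityGrid",
  representation(chrom = "character", pos = "numeric", markerId = "character",
                 probA = "matrix"))

setValidity("GenotypeProbabilityGrid", function(object) {
  msg <- character()
  p <- object@probA
  if (ncol(p) != length(object@pos) || length(object@chrom) != length(object@pos))
    msg <- c(msg, "probA columns must match grid positions")
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeProbabilityGrid data.frame(chrom, pos, markerId).
#' @param x a GenotypeProbabilityGrid.
#' @export
setMethod("gridPositions", "GenotypeProbabilityGrid", function(x)
  data.frame(chrom = x@chrom, pos = x@pos, markerId = x@markerId,
             stringsAsFactors = FALSE))

#' @describeIn GenotypeProbabilityGrid lines x positions P(A) matrix.
#' @export
setMethod("alleleProbs", "GenotypeProbabilityGrid", function(x) x@probA)

#' @describeIn GenotypeProbabilityGrid line ids.
#' @export
setMethod("lineNames", "GenotypeProbabilityGrid", function(x) rownames(x@probA))

setMethod("show", "GenotypeProbabilityGrid", function(object) {
  cat(sprintf(paste0("GenotypeProbabilityGrid: %d lines x %d positions ",
                     "(%d at markers) on %d chromosomes\n"),
              nrow(object@probA), length(object@pos),
              sum(!is.na(object@markerId)), length(unique(object@chrom))))
})

#' Genome-scan result
#'
#' Per-position LOD and additive-effect curves from one composite interval
#' mapping scan of a single line-level phenotype.
#'
#' @slot chrom,pos grid coordinates.
#' @slot lod LOD score per position (>= 0, capped at \code{lodCap}).
#' @slot effect additive effect a per position (half the difference between
#'   expected A- and B-class means).
#' @slot capped logical per position: LOD hit the degenerate-fit cap.
#' @slot cofactors marker ids used as background cofactors.
#' @slot n number of lines scanned.
#' @slot lodCap the cap applied to degenerate perfect fits.
#' @export
setClass("ScanResult",
  representation(chrom = "character", pos = "numeric", lod = "numeric",
                 effect = "numeric", capped = "logical",
                 cofactors = "character", n = "integer", lodCap = "numeric"))

setValidity("ScanResult", function(object) {
  msg <- character()
  k <- length(object@pos)
  if (length(object@lod) != k || length(object@effect) != k ||
      length(object@chrom) != k || length(object@capped) != k)
    msg <- c(msg, "per-position slots must have equal length")
  if (any(object@lod < -1e-9, na.rm = TRUE)) msg <- c(msg, "LOD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScanResult data.frame(chrom, pos, lod, effect, capped).
#' @param x a ScanResult.
#' @export
setMethod("scanTable", "ScanResult", function(x)
  data.frame(chrom = x@chrom, pos = x@pos, lod = x@lod, effect = x@effect,
             capped = x@capped, stringsAsFactors = FALSE))

setMethod("show", "ScanResult", function(object) {
  i <- which.max(object@lod)
  cat(sprintf(paste0("ScanResult: %d positions, %d cofactors, n = %d; ",
                     "max LOD %.2f at %s:%.1f cM\n"),
              length(object@pos), length(object@cofactors), object@n,
              object@lod[i], object@chrom[i], object@pos[i]))
})

#' Epistasis network
#'
#' Loci as nodes (with main-effect breadth: the fraction of phenotypes the
#' locus significantly affects) and locus pairs as edges (interaction
#' breadth), after the cross-phenotype breadth filter.
#'
#' @slot nodes data.frame(locus, breadth, nPhenotypes).
#' @slot edges data.frame(locus1, locus2, breadth, nPhenotypes).
#' @slot fdr the per-model FDR significance level used.
#' @slot edgeMin minimum interaction breadth for a retained edge.
#' @export
setClass("EpistasisNetwork",
  representation(nodes = "data.frame", edges = "data.frame", fdr = "numeric",
                 edgeMin = "numeric"))

setValidity("EpistasisNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    if (any(object@edges$locus1 == object@edges$locus2))
      msg <- c(msg, "edges must connect distinct loci")
    if (any(object@edges$breadth < 0 | object@edges$breadth > 1))
      msg <- c(msg, "edge breadths must lie in [0, 1]")
  }
  if (nrow(object@nodes) &&
      any(object@nodes$breadth < 0 | object@nodes$breadth > 1))
    msg <- c(msg, "node breadths must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EpistasisNetwork node table.
#' @param x an EpistasisNetwork.
#' @export
setMethod("networkNodes", "EpistasisNetwork", function(x) x@nodes)

#' @describeIn EpistasisNetwork edge table.
#' @export
setMethod("networkEdges", "EpistasisNetwork", function(x) x@edges)

setMethod("show", "EpistasisNetwork", function(object) {
  cat(sprintf("EpistasisNetwork: %d loci, %d interactions (breadth >= %.2f)\n",
              nrow(object@nodes), nrow(object@edges), object@edgeMin))
})
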