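# Genetic-map construction, map functions and TSV I/O.

#' Haldane recombination fraction
#'
#' r(d) = (1 - exp(-2 d / 100)) / 2 for a map distance d in cM.
#'
#' @param d map distance in cM (vectorized).
#' @return recombination fraction in [0, 0.5).
#' @export
haldaneR <- function(d) (1 - exp(-2 * d / 100)) / 2

#' RIL-by-selfing switch probability
#'
#' The two-point probability that a fully inbred selfed RIL carries different
#' parental alleles at two loci d cM apart: R = 2r / (1 + 2r) with r the
#' Haldane recombination fraction.
#'
#' @param d map distance in cM (vectorized).
#' @return switch probability in [0, 0.5).
#' @export
rilSwitchProb <- function(d) {
  r <- haldaneR(d)
  2 * r / (1 + 2 * r)
}

#' Build an evenly spaced genetic map
#'
#' Markers are laid out at 0, spacing, 2*spacing, ... per chromosome; the
#' chromosome endpoint is always included even when the length is not a
#' multiple of the spacing. Chromosomes are named with Roman numerals.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param chromLength chromosome length in cM (>= spacing).
#' @param markerSpacing marker spacing in cM (> 0).
#' @return A [GeneticMap-class].
#' @examples
#' buildDefaultMap(5, 90, 5)    # the package's default 450 cM genome
#' @export
buildDefaultMap <- function(nChromosomes = 5, chromLength = 90,
                            markerSpacing = 5) {
  if (nChromosomes < 1) stop("nChromosomes must be >= 1")
  if (markerSpacing <= 0) stop("markerSpacing must be > 0")
  if (chromLength < markerSpacing) stop("chromLength must be >= markerSpacing")
  pos1 <- unique(c(seq(0, chromLength, by = markerSpacing), chromLength))
  chroms <- as.character(utils::as.roman(seq_len(nChromosomes)))
  chrom <- rep(chroms, each = length(pos1))
  pos <- rep(pos1, nChromosomes)
  marker <- sprintf("m%s_%g", chrom, pos)
  GeneticMap(chrom, marker, pos)
}

#' Read / write a genetic map as TSV
#'
#' Columns: chromosome, marker, cM.
#'
#' @param path file path.
#' @return `readGeneticMap` returns a [GeneticMap-class]; `writeGeneticMap`
#'   returns `path` invisibly.
#' @export
readGeneticMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chromosome", "marker", "cM") %in% names(df)))
  GeneticMap(df$chromosome, df$marker, df$cM)
}

#' @rdname readGeneticMap
#' @param map a [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path) {
  df <- markerTable(map)
  names(df) <- c("chromosome", "marker", "cM")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# locate (chrom, pos) pairs on the map, erroring when absent
.matchLocus <- function(map, chrom, pos, tol = 1e-6) {
  idx <- mapply(function(ch, p) {
    i <- which(map@chrom == ch & abs(map@pos - p) <= tol)
    if (!length(i)) stop(sprintf("locus %s:%g is not on the map", ch, p))
    i[1L]
  }, as.character(chrom), as.numeric(pos))
  as.integer(idx)
}
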