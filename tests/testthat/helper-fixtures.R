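# Shared fixtures, built in code at test time.

# a small two-chromosome map with 5 cM spacing
toyMap <- function(nChrom = 2, len = 40, spacing = 5) {
  buildDefaultMap(nChrom, len, spacing)
}

# genotypes for n lines on the toy map
toyGeno <- function(n = 100, seed = 42, map = toyMap()) {
  simulateRILGenotypes(map, DesignSpec(n, seed = seed))
}

# hand-build a LineCVTable from per-line statistics of one or more phenotypes
cvTableFromStats <- function(df) {
  stopifnot(all(c("line", "phenotype", "meanCV", "grandMean") %in% names(df)))
  pl <- data.frame(line = df$line, phenotype = df$phenotype,
                   nExperiments = 1L, meanCV = df$meanCV,
                   grandMean = df$grandMean,
                   defined = is.finite(df$meanCV), stringsAsFactors = FALSE)
  pe <- data.frame(line = df$line, phenotype = df$phenotype,
                   experiment = "E1", n = 2L, mean = df$grandMean,
                   sd = df$meanCV * df$grandMean, cv = df$meanCV,
                   defined = is.finite(df$meanCV), stringsAsFactors = FALSE)
  new("LineCVTable", perExperiment = pe, perLine = pl)
}

# hand-build a ScanResult from a LOD curve on one or more chromosomes
scanFromCurve <- function(lod, chrom = rep("I", length(lod)),
                          pos = seq_along(lod), effect = rep(0, length(lod))) {
  new("ScanResult", chrom = chrom, pos = as.numeric(pos), lod = as.numeric(lod),
      effect = as.numeric(effect), capped = rep(FALSE, length(lod)),
      cofactors = character(0), n = 100L, lodCap = 300)
}

# brute-force single-marker regression LOD: the independent oracle
singleMarkerLod <- function(x, y) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  (n / 2) * log10(rss0 / rss1)
}

# line-level phenotype vector from simulated observations, for one trait
lineStatistic <- function(obs, phenotype, statistic = c("cv", "mean")) {
  statistic <- match.arg(statistic)
  tab <- computeLineCV(obs)
  pl <- perLineCV(tab)
  d <- pl[pl$phenotype == phenotype & pl$defined, ]
  stats::setNames(if (statistic == "cv") d$meanCV else d$grandMean, d$line)
}
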