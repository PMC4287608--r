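# Reciprocal-RIL genotype and phenotype simulator.
#
# The simulator is first-class: its generating model is the ground truth
# against which CV computation, heritability decomposition, QTL scans and
# the permutation nulls are validated by parameter recovery.

#' Simulate reciprocal RIL genotypes
#'
#' Genotypes are generated marker-to-marker along each chromosome as a
#' two-state Markov chain whose switch probability between adjacent markers
#' d cM apart is the RIL-by-selfing expansion R = 2r/(1+2r) of the Haldane
#' recombination fraction r = (1 - exp(-2d/100))/2. The first marker of each
#' chromosome is an independent fair coin per line. Cytoplasm is assigned
#' "A_CYT" to the first ceiling(n/2) lines and "B_CYT" to the rest, then the
#' line order is shuffled under the seed, emulating a reciprocal cross.
#'
#' @param map a [GeneticMap-class].
#' @param design a [DesignSpec-class]; `nLines` and `seed` are used.
#' @return A [RILGenotypes-class]; fixed seed gives bit-identical output.
#' @examples
#' g <- simulateRILGenotypes(buildDefaultMap(2, 20, 10), DesignSpec(8, seed = 1))
#' alleles(g)
#' @export
simulateRILGenotypes <- function(map, design = DesignSpec()) {
  stopifnot(is(map, "GeneticMap"), is(design, "DesignSpec"))
  n <- design@nLines
  set.seed(design@seed)
  mt <- markerTable(map)
  nm <- nrow(mt)
  x <- matrix(NA_integer_, n, nm)
  for (ch in chromosomes(map)) {
    j <- which(mt$chrom == ch)
    x[, j[1L]] <- sample(c(1L, -1L), n, replace = TRUE)
    if (length(j) > 1L) {
      R <- rilSwitchProb(diff(mt$pos[j]))
      for (k in seq_along(R)) {
        flip <- stats::runif(n) < R[k]
        x[, j[k + 1L]] <- ifelse(flip, -x[, j[k]], x[, j[k]])
      }
    }
  }
  lines <- sprintf("RIL%03d", seq_len(n))
  cyto <- rep(c("A_CYT", "B_CYT"), c(ceiling(n / 2), floor(n / 2)))
  ord <- sample.int(n)              # shuffle line order (cytoplasm with it)
  a <- matrix(ifelse(x == 1L, "A", "B"), n, nm,
              dimnames = list(lines, mt$marker))
  # permute rows and cytoplasm together, then relabel lines in the new order
  a <- a[ord, , drop = FALSE]
  cyto <- cyto[ord]
  rownames(a) <- lines
  RILGenotypes(a, cyto, map)
}

#' Simulate replicated phenotypes under a known architecture
#'
#' For line l and trait t, with marker codes x in \{-1,+1\} (A = +1) and
#' cytoplasm code z in \{-1,+1\} (A_CYT = +1):
#' mean mu = grandMean + sum(a x) + cMean z + sum(gamma x1 x2);
#' log sd = log(baseSd) + sum(b x) + cSd z.
#' Each observation in experiment e, block b is
#' mu + experimentEffect[e] + blockEffect[b] + sd * eps with eps ~ N(0, 1),
#' or exp() of that linear predictor's noise when `family = "lognormal"`.
#'
#' @param geno a [RILGenotypes-class].
#' @param arch a [TrueArchitecture-class]; all loci must lie on the map.
#' @param design a [DesignSpec-class].
#' @param family observation model: "normal" (default) draws the observation
#'   as mu + noise; "lognormal" draws exp(N(log mu, sd/mu)) for strictly
#'   positive abundances (requires mu > 0).
#' @param maxLogSd guard: abs(log sd) beyond this aborts with the offending
#'   trait/line (overflow protection).
#' @return data.frame(line, experiment, block, phenotype, value), long format;
#'   fixed seed gives bit-identical output.
#' @export
simulatePhenotypes <- function(geno, arch, design = DesignSpec(),
                               family = c("normal", "lognormal"),
                               maxLogSd = 25) {
  stopifnot(is(geno, "RILGenotypes"), is(arch, "TrueArchitecture"),
            is(design, "DesignSpec"))
  family <- match.arg(family)
  set.seed(design@seed + 1L)        # distinct stream from the genotypes
  X <- alleleCodes(geno)
  lines <- lineNames(geno)
  n <- length(lines)
  z <- ifelse(cytoplasm(geno) == "A_CYT", 1, -1)
  traits <- arch@traits
  map <- geno@map

  mu <- matrix(arch@grandMean, n, length(traits),
               dimnames = list(lines, traits))
  logsd <- matrix(log(arch@baseSd), n, length(traits),
                  dimnames = list(lines, traits))
  if (nrow(arch@meanQTL)) {
    idx <- .matchLocus(map, arch@meanQTL$chrom, arch@meanQTL$pos)
    for (i in seq_along(idx))
      mu[, arch@meanQTL$trait[i]] <- mu[, arch@meanQTL$trait[i]] +
        arch@meanQTL$effect[i] * X[, idx[i]]
  }
  if (nrow(arch@varQTL)) {
    idx <- .matchLocus(map, arch@varQTL$chrom, arch@varQTL$pos)
    for (i in seq_along(idx))
      logsd[, arch@varQTL$trait[i]] <- logsd[, arch@varQTL$trait[i]] +
        arch@varQTL$effect[i] * X[, idx[i]]
  }
  if (nrow(arch@epistasis)) {
    i1 <- .matchLocus(map, arch@epistasis$chrom1, arch@epistasis$pos1)
    i2 <- .matchLocus(map, arch@epistasis$chrom2, arch@epistasis$pos2)
    for (i in seq_along(i1))
      mu[, arch@epistasis$trait[i]] <- mu[, arch@epistasis$trait[i]] +
        arch@epistasis$effect[i] * X[, i1[i]] * X[, i2[i]]
  }
  mu <- mu + outer(z, arch@cytoMeanEffect[traits])
  logsd <- logsd + outer(z, arch@cytoSdEffect[traits])
  if (any(abs(logsd) > maxLogSd)) {
    bad <- which(abs(logsd) > maxLogSd, arr.ind = TRUE)[1L, ]
    stop(sprintf("simulated log SD overflow for trait '%s', line '%s'",
                 traits[bad[2L]], lines[bad[1L]]))
  }
  sdm <- exp(logsd)

  ee <- rep(arch@experimentEffects, length.out = design@nExperiments)
  be <- rep(arch@blockEffects, length.out = design@repsPerExperiment)
  out <- vector("list", design@nExperiments * design@repsPerExperiment)
  k <- 0L
  for (e in seq_len(design@nExperiments)) {
    for (b in seq_len(design@repsPerExperiment)) {
      k <- k + 1L
      eps <- matrix(stats::rnorm(n * length(traits)), n, length(traits))
      if (family == "normal") {
        val <- mu + ee[e] + be[b] + sdm * eps
      } else {
        m <- mu + ee[e] + be[b]
        if (any(m <= 0))
          stop("lognormal family requires strictly positive means")
        val <- exp(log(m) + (sdm / m) * eps)
      }
      out[[k]] <- data.frame(
        line = rep(lines, times = length(traits)),
        experiment = sprintf("E%d", e),
        block = sprintf("E%d_B%d", e, b),
        phenotype = rep(traits, each = n),
        value = as.vector(val),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Random trait architecture for recovery experiments
#'
#' Convenience generator for recovery experiments: draws, for each trait, a
#' configurable number of mean-QTL and variance-QTL at random marker
#' positions, optional cytoplasm effects, and returns the resulting
#' [TrueArchitecture-class].
#'
#' @param map a [GeneticMap-class].
#' @param traits trait ids.
#' @param nMeanQTL,nVarQTL QTL per trait.
#' @param meanEffect,varEffect effect magnitudes (a on the mean; b on log SD);
#'   signs are drawn at random.
#' @param cytoMeanEffect,cytoSdEffect scalar cytoplasm effects for all traits.
#' @param grandMean,baseSd baseline mean and within-line SD.
#' @param seed integer seed.
#' @return A [TrueArchitecture-class].
#' @export
randomArchitecture <- function(map, traits, nMeanQTL = 2, nVarQTL = 1,
                               meanEffect = 0.5, varEffect = log(1.5),
                               cytoMeanEffect = 0, cytoSdEffect = 0,
                               grandMean = 10, baseSd = 1, seed = 1) {
  set.seed(seed)
  mt <- markerTable(map)
  draw <- function(k, eff) {
    if (k == 0) return(NULL)
    do.call(rbind, lapply(traits, function(tr) {
      i <- sample.int(nrow(mt), k)
      data.frame(chrom = mt$chrom[i], pos = mt$pos[i],
                 effect = sample(c(-1, 1), k, replace = TRUE) * eff,
                 trait = tr, stringsAsFactors = FALSE)
    }))
  }
  TrueArchitecture(traits, grandMean = grandMean,
                   meanQTL = draw(nMeanQTL, meanEffect),
                   varQTL = draw(nVarQTL, varEffect),
                   cytoMeanEffect = cytoMeanEffect,
                   cytoSdEffect = cytoSdEffect, baseSd = baseSd)
}

#' Genotype / phenotype / truth file I/O
#'
#' Genotypes: TSV with columns line, cytoplasm, then one column per marker
#' ("A"/"B"). Phenotypes: long-format CSV (line, experiment, block,
#' phenotype, value). Truth: YAML serialization of a TrueArchitecture.
#'
#' @param geno a [RILGenotypes-class].
#' @param path output path.
#' @return the path, invisibly (writers); the parsed object (readers).
#' @export
writeGenotypes <- function(geno, path) {
  df <- data.frame(line = lineNames(geno),
                   cytoplasm = as.vector(cytoplasm(geno)),
                   alleles(geno), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @param map the [GeneticMap-class] the genotype columns refer to.
#' @export
readGenotypes <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  a <- as.matrix(df[, markerNames(map), drop = FALSE])
  rownames(a) <- df$line
  RILGenotypes(a, df$cytoplasm, map)
}

#' @rdname writeGenotypes
#' @param obs long-format phenotype data.frame.
#' @export
writePhenotypes <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "experiment", "block", "phenotype", "value")
                %in% names(df)))
  df
}

#' @rdname writeGenotypes
#' @param arch a [TrueArchitecture-class].
#' @export
writeArchitecture <- function(arch, path) {
  lst <- list(traits = arch@traits, grandMean = arch@grandMean,
              baseSd = arch@baseSd,
              meanQTL = arch@meanQTL, varQTL = arch@varQTL,
              cytoMeanEffect = as.list(arch@cytoMeanEffect),
              cytoSdEffect = as.list(arch@cytoSdEffect),
              epistasis = arch@epistasis,
              experimentEffects = arch@experimentEffects,
              blockEffects = arch@blockEffects)
  yaml::write_yaml(lst, path)
  invisible(path)
}
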