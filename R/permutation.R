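# Structured negative control: permute whole multi-phenotype sample vectors
# across lines within randomized blocks. Each sample keeps all its
# phenotype values together, so every per-sample statistic (means, SDs,
# phenotype-phenotype correlations) is preserved exactly; only the
# line-to-sample link is broken. Genotypes are untouched.

#' Permute line-to-sample links within blocks
#'
#' Within each (experiment, block), the assignment of complete sample
#' vectors (all phenotypes measured on one plant) to lines is replaced by a
#' uniform random permutation. Vectors are never split across phenotypes.
#'
#' @param obs long-format data.frame(line, experiment, block, phenotype,
#'   value); every line must contribute exactly one sample per block.
#' @param seed optional integer seed.
#' @return the permuted observations (same dimensions, same per-block
#'   multiset of sample vectors).
#' @export
permuteLinks <- function(obs, seed = NULL) {
  stopifnot(all(c("line", "experiment", "block", "phenotype", "value")
                %in% names(obs)))
  if (!is.null(seed)) set.seed(seed)
  out <- obs
  blocks <- unique(obs[, c("experiment", "block")])
  for (i in seq_len(nrow(blocks))) {
    sel <- obs$experiment == blocks$experiment[i] & obs$block == blocks$block[i]
    d <- obs[sel, ]
    counts <- table(d$line)
    if (length(unique(as.vector(counts))) != 1L)
      stop(sprintf("unequal sample counts within block %s/%s",
                   blocks$experiment[i], blocks$block[i]))
    lines <- sort(unique(d$line))
    relabel <- stats::setNames(sample(lines), lines)
    out$line[sel] <- unname(relabel[d$line])
  }
  out
}

#' Null QTL census under structured permutation
#'
#' For each of `nPerm` structured permutations of the observations,
#' recomputes the per-line CV (or mean) of every phenotype and re-runs the
#' full genome scan, counting significant QTL across phenotypes. The
#' observed count is computed the same way on the unpermuted data. Scan
#' errors for individual phenotypes are recorded and skipped, never
#' aborting the census.
#'
#' @param obs long-format observations.
#' @param geno a [RILGenotypes-class].
#' @param nPerm number of structured permutations (0 gives the observed
#'   count only).
#' @param statistic "cv" or "mean": the line-level phenotype scanned.
#' @param step grid step in cM.
#' @param nCofactors,window,lodMin scan settings (defaults: 3 cofactors,
#'   10 cM window, fixed LOD >= 2 significance).
#' @param seed optional integer seed for the permutation stream.
#' @return list(observed, counts, maxCount, fraction = maxCount/observed,
#'   nPerm, errors).
#' @export
nullQtlCensus <- function(obs, geno, nPerm = 100, statistic = c("cv", "mean"),
                          step = 2, nCofactors = 3, window = 10, lodMin = 2,
                          seed = NULL) {
  stopifnot(is(geno, "RILGenotypes"))
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  grid <- genotypeProbabilities(geno, step = step)
  errors <- character(0)
  census <- function(o) {
    tab <- computeLineCV(o)
    pl <- perLineCV(tab)
    total <- 0L
    for (ph in unique(pl$phenotype)) {
      d <- pl[pl$phenotype == ph & pl$defined, ]
      y <- stats::setNames(if (statistic == "cv") d$meanCV else d$grandMean,
                           d$line)
      cnt <- tryCatch({
        cof <- selectCofactors(grid, y, k = nCofactors)
        sc <- cimScan(grid, y, cofactors = cof, window = window)
        nrow(findPeaks(sc, lodMin = lodMin))
      }, error = function(e) {
        errors <<- c(errors, sprintf("%s: %s", ph, conditionMessage(e)))
        0L
      })
      total <- total + cnt
    }
    total
  }
  observed <- census(obs)
  counts <- integer(0)
  if (nPerm > 0)
    counts <- vapply(seq_len(nPerm), function(i) census(permuteLinks(obs)),
                     integer(1))
  maxCount <- if (length(counts)) max(counts) else NA_integer_
  list(observed = observed, counts = counts, maxCount = maxCount,
       fraction = if (length(counts) && observed > 0) maxCount / observed
                  else NA_real_,
       nPerm = nPerm, errors = errors)
}
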