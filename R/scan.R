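# Composite interval mapping of line-level phenotypes by Haley-Knott
# regression: conditional genotype probabilities, forward cofactor
# selection, LOD scans with windowed cofactor exclusion, permutation
# thresholds, peak calling with one-LOD support intervals, and effect
# scaling. Fully inbred RILs with near-complete marker data make the
# regression approximation essentially exact, and it admits clean
# brute-force oracles.

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' P(allele A) at every grid position given the nearest non-missing flanking
#' markers, from two-point RIL switch probabilities R(d) = 2r/(1+2r) with r
#' the Haldane recombination fraction. The grid covers each chromosome at a
#' fixed step and always includes every marker position exactly; at a
#' genotyped, non-missing marker the probability is exactly 0 or 1.
#' Positions beyond a line's terminal informative marker condition on the
#' single available flank; a fully missing line gets probability 0.5
#' everywhere and is flagged in the `fullyMissing` attribute.
#'
#' @param geno a [RILGenotypes-class].
#' @param step grid step in cM (> 0), default 1.
#' @return A [GenotypeProbabilityGrid-class].
#' @export
genotypeProbabilities <- function(geno, step = 1) {
  stopifnot(is(geno, "RILGenotypes"))
  if (step <= 0) stop("step must be > 0")
  map <- geno@map
  mt <- markerTable(map)
  X <- alleleCodes(geno)
  n <- nrow(X)
  chromL <- list(); posL <- list(); midL <- list(); probL <- list()
  for (ch in chromosomes(map)) {
    j <- which(mt$chrom == ch)
    mp <- mt$pos[j]
    Xc <- X[, j, drop = FALSE]
    m <- length(j)
    qs <- sort(unique(round(c(seq(min(mp), max(mp), by = step), mp), 9)))
    # nearest non-missing marker index at/left and at/right, per line
    lastObs <- matrix(NA_integer_, n, m)
    nextObs <- matrix(NA_integer_, n, m)
    prev <- rep(NA_integer_, n)
    for (k in seq_len(m)) {
      prev <- ifelse(!is.na(Xc[, k]), k, prev)
      lastObs[, k] <- prev
    }
    nxt <- rep(NA_integer_, n)
    for (k in rev(seq_len(m))) {
      nxt <- ifelse(!is.na(Xc[, k]), k, nxt)
      nextObs[, k] <- nxt
    }
    P <- matrix(NA_real_, n, length(qs))
    mid <- rep(NA_character_, length(qs))
    for (qi in seq_along(qs)) {
      q <- qs[qi]
      li <- findInterval(q, mp)
      ri <- li + 1L
      im <- which(abs(mp - q) <= 1e-9)
      if (length(im)) mid[qi] <- mt$marker[j[im[1L]]]
      Lidx <- if (li >= 1L) lastObs[, li] else rep(NA_integer_, n)
      Ridx <- if (ri <= m) nextObs[, ri] else rep(NA_integer_, n)
      xl <- ifelse(is.na(Lidx), NA_real_, Xc[cbind(seq_len(n), Lidx)])
      xr <- ifelse(is.na(Ridx), NA_real_, Xc[cbind(seq_len(n), Ridx)])
      RL <- rilSwitchProb(q - ifelse(is.na(Lidx), 0, mp[Lidx]))
      RR <- rilSwitchProb(ifelse(is.na(Ridx), 0, mp[Ridx]) - q)
      fLA <- ifelse(is.na(xl), 1, ifelse(xl == 1, 1 - RL, RL))
      fLB <- ifelse(is.na(xl), 1, ifelse(xl == 1, RL, 1 - RL))
      fRA <- ifelse(is.na(xr), 1, ifelse(xr == 1, 1 - RR, RR))
      fRB <- ifelse(is.na(xr), 1, ifelse(xr == 1, RR, 1 - RR))
      wA <- fLA * fRA; wB <- fLB * fRB
      P[, qi] <- wA / (wA + wB)
    }
    chromL[[ch]] <- rep(ch, length(qs)); posL[[ch]] <- qs
    midL[[ch]] <- mid; probL[[ch]] <- P
  }
  probA <- do.call(cbind, probL)
  rownames(probA) <- rownames(X)
  grid <- new("GenotypeProbabilityGrid",
              chrom = unlist(chromL, use.names = FALSE),
              pos = unlist(posL, use.names = FALSE),
              markerId = unlist(midL, use.names = FALSE), probA = probA)
  fm <- rownames(X)[rowSums(!is.na(X)) == 0L]
  attr(grid, "fullyMissing") <- fm
  grid
}

# --- internal fast linear-algebra cores -------------------------------------

# orthonormal basis of the column space of X (rank-safe)
.qBasis <- function(X) {
  qrX <- qr(X)
  qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

# HK scan over grid columns. G: n x P expected-code matrix (2*probA - 1);
# cofactor regressors are grid columns (exact +/-1 at markers). Returns
# lod/effect/capped vectors.
.scanCore <- function(G, chromIdx, cm, y, cofIdx, window, lodCap) {
  n <- length(y)
  P <- ncol(G)
  lod <- numeric(P); eff <- numeric(P); capped <- logical(P)
  k <- length(cofIdx)
  if (k) {
    dropMat <- vapply(cofIdx, function(cc)
      chromIdx == chromIdx[cc] & abs(cm - cm[cc]) <= window, logical(P))
    dropMat <- matrix(dropMat, nrow = P)
    key <- as.vector(dropMat %*% 2^(seq_len(k) - 1))
  } else key <- rep(0, P)
  for (gkey in unique(key)) {
    jj <- which(key == gkey)
    keep <- if (k) cofIdx[!dropMat[jj[1L], ]] else integer(0)
    Q <- .qBasis(cbind(rep(1, n), G[, keep, drop = FALSE]))
    ry <- y - Q %*% crossprod(Q, y)
    rssR <- sum(ry^2)
    Gs <- G[, jj, drop = FALSE]
    Gr <- Gs - Q %*% crossprod(Q, Gs)
    num <- as.vector(crossprod(Gr, ry))
    den <- colSums(Gr^2)
    ok <- den > 1e-10 * n
    beta <- ifelse(ok, num / den, 0)
    rssF <- rssR - ifelse(ok, num^2 / den, 0)
    if (rssR <= 0) {
      lod[jj] <- 0; eff[jj] <- 0
    } else {
      deg <- rssF < 1e-12 * rssR
      l <- (n / 2) * log10(rssR / pmax(rssF, 1e-300))
      l[deg] <- lodCap
      lod[jj] <- pmax(l, 0)
      eff[jj] <- beta
      capped[jj] <- deg
    }
  }
  list(lod = lod, effect = eff, capped = capped)
}

# forward cofactor selection over candidate columns; returns indices into
# the candidate matrix, plus indices skipped as collinear
.selectCore <- function(Xm, y, k) {
  n <- length(y)
  sel <- integer(0); skipped <- integer(0)
  X <- matrix(1, n, 1)
  for (s in seq_len(k)) {
    Q <- .qBasis(X)
    ry <- y - Q %*% crossprod(Q, y)
    C <- Xm - Q %*% crossprod(Q, Xm)
    den <- colSums(C^2)
    num <- as.vector(crossprod(C, ry))
    score <- ifelse(den > 1e-10 * n, num^2 / den, -Inf)
    score[sel] <- -Inf
    skipped <- union(skipped, setdiff(which(!is.finite(score) & den <= 1e-10 * n),
                                      sel))
    if (all(!is.finite(score))) break
    pick <- which.max(score)          # ties resolved to the lowest map index
    sel <- c(sel, pick)
    X <- cbind(X, Xm[, pick])
  }
  list(sel = sel, skipped = skipped)
}

.gridData <- function(grid, y) {
  ln <- lineNames(grid)
  if (!is.null(names(y))) {
    y <- y[ln]
  } else stopifnot(length(y) == length(ln))
  keep <- is.finite(y)
  G <- 2 * grid@probA[keep, , drop = FALSE] - 1
  list(G = G, y = as.numeric(y[keep]),
       chromIdx = as.integer(factor(grid@chrom, unique(grid@chrom))),
       cm = grid@pos,
       markerCols = which(!is.na(grid@markerId)),
       markerIds = grid@markerId[!is.na(grid@markerId)])
}

#' Forward selection of background cofactor markers
#'
#' Greedy forward regression on the genotyped markers: at each of `k` steps
#' the marker giving the largest reduction in residual sum of squares of the
#' linear fit is added. Deterministic; ties break to the earlier marker in
#' map order; collinear candidates are skipped (recorded in the `skipped`
#' attribute).
#'
#' @param grid a [GenotypeProbabilityGrid-class].
#' @param y phenotype values, named by line or aligned with `lineNames(grid)`;
#'   NA lines are dropped.
#' @param k number of cofactors (>= 0), default 3.
#' @return character vector of selected marker ids (may be shorter than `k`
#'   if candidates run out).
#' @export
selectCofactors <- function(grid, y, k = 3) {
  stopifnot(is(grid, "GenotypeProbabilityGrid"), k >= 0)
  if (k == 0) return(character(0))
  gd <- .gridData(grid, y)
  Xm <- gd$G[, gd$markerCols, drop = FALSE]
  res <- .selectCore(Xm, gd$y, k)
  out <- gd$markerIds[res$sel]
  attr(out, "skipped") <- gd$markerIds[res$skipped]
  out
}

#' Composite interval mapping scan (Haley-Knott regression)
#'
#' At each grid position, background cofactors lying within `window` cM of
#' the position on the same chromosome are dropped; the reduced model is
#' intercept + retained cofactors and the full model adds the position's
#' expected allele code (2 P(A) - 1). LOD = (n/2) log10(RSS_reduced /
#' RSS_full). The additive effect is the regression coefficient on the
#' expected code, i.e. half the difference between the A and B class means
#' (positive = A allele increases the phenotype). Degenerate perfect fits
#' (RSS_full < 1e-12 RSS_reduced) are capped at `lodCap` and flagged.
#'
#' @param grid a [GenotypeProbabilityGrid-class].
#' @param y phenotype values (named by line or aligned); NA lines dropped.
#' @param cofactors marker ids to use as cofactors (e.g. from
#'   [selectCofactors()]); empty for simple interval mapping.
#' @param window cM exclusion window around the test position (default 10).
#' @param lodCap cap for degenerate fits (default 300).
#' @param minLines minimum lines with defined phenotype (default 10).
#' @return A [ScanResult-class].
#' @export
cimScan <- function(grid, y, cofactors = character(0), window = 10,
                    lodCap = 300, minLines = 10) {
  stopifnot(is(grid, "GenotypeProbabilityGrid"), window >= 0)
  gd <- .gridData(grid, y)
  if (length(gd$y) < minLines)
    stop("phenotype defined for fewer than ", minLines, " lines")
  cofIdx <- gd$markerCols[match(cofactors, gd$markerIds)]
  if (length(cofactors) && anyNA(cofIdx))
    stop("unknown cofactor marker id(s): ",
         paste(cofactors[is.na(cofIdx)], collapse = ", "))
  res <- .scanCore(gd$G, gd$chromIdx, gd$cm, gd$y, cofIdx, window, lodCap)
  new("ScanResult", chrom = grid@chrom, pos = grid@pos, lod = res$lod,
      effect = res$effect, capped = res$capped,
      cofactors = as.character(cofactors), n = length(gd$y), lodCap = lodCap)
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Permutes phenotype values across lines, rescans the genome per
#' permutation (reselecting cofactors by default, the statistically correct
#' scheme; `reselect = FALSE` freezes the supplied set for speed), and
#' returns the empirical (1 - alpha) quantile of the genome-wide maximum
#' LOD as the order statistic sorted[ceiling((1 - alpha) * nPerm)]
#' (type-1 empirical quantile, for bit-reproducibility).
#'
#' @param grid a [GenotypeProbabilityGrid-class].
#' @param y phenotype values (named by line or aligned); NA lines dropped.
#' @param nPerm number of permutations (>= 100 recommended; default 1000).
#' @param alpha genome-wide significance level, default 0.05.
#' @param nCofactors cofactors reselected inside each permutation (default 3).
#' @param cofactors frozen cofactor set, used when `reselect = FALSE`.
#' @param window,lodCap as in [cimScan()].
#' @param reselect reselect cofactors per permutation (default TRUE).
#' @param seed optional integer seed for the permutation stream.
#' @return the LOD threshold (numeric), with the per-permutation maxima in
#'   attribute `maxLods`.
#' @export
permutationThreshold <- function(grid, y, nPerm = 1000, alpha = 0.05,
                                 nCofactors = 3, cofactors = character(0),
                                 window = 10, lodCap = 300, reselect = TRUE,
                                 seed = NULL) {
  stopifnot(is(grid, "GenotypeProbabilityGrid"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  gd <- .gridData(grid, y)
  if (stats::var(gd$y) == 0) stop("constant phenotype: threshold degenerate")
  if (!is.null(seed)) set.seed(seed)
  n <- length(gd$y)
  Xm <- gd$G[, gd$markerCols, drop = FALSE]
  frozenIdx <- gd$markerCols[match(cofactors, gd$markerIds)]
  maxes <- vapply(seq_len(nPerm), function(i) {
    yp <- gd$y[sample.int(n)]
    cofIdx <- if (reselect) {
      if (nCofactors > 0) gd$markerCols[.selectCore(Xm, yp, nCofactors)$sel]
      else integer(0)
    } else frozenIdx
    max(.scanCore(gd$G, gd$chromIdx, gd$cm, yp, cofIdx, window, lodCap)$lod)
  }, 0)
  thr <- sort(maxes)[ceiling((1 - alpha) * nPerm)]
  attr(thr, "maxLods") <- maxes
  thr
}

#' Call QTL peaks with one-LOD support intervals
#'
#' Local maxima with LOD >= `lodMin`; two maxima on one chromosome are
#' distinct peaks only if the curve dips at least 1 LOD below the smaller of
#' the two between them. The one-LOD support interval is the widest
#' contiguous region around the peak with LOD >= peak - 1, clipped to the
#' chromosome. When `traitMean` is supplied, the percent effect
#' 100 |2a| / |mean| is attached.
#'
#' @param scan a [ScanResult-class].
#' @param lodMin minimum peak LOD (> 0), default 2 (the conservative fixed
#'   rule; a permutation threshold may be passed instead).
#' @param traitMean mean of the trait across lines, for percent effects.
#' @return data.frame(chrom, peakCM, lod, intervalLow, intervalHigh,
#'   additiveEffect, percentEffect), zero rows if no peak qualifies.
#' @export
findPeaks <- function(scan, lodMin = 2, traitMean = NULL) {
  stopifnot(is(scan, "ScanResult"))
  if (lodMin <= 0) stop("lodMin must be > 0")
  out <- list()
  for (ch in unique(scan@chrom)) {
    jj <- which(scan@chrom == ch)
    l <- scan@lod[jj]; p <- scan@pos[jj]
    m <- length(jj)
    if (!m) next
    isMax <- l >= lodMin &
      l >= c(-Inf, l[-m]) & l >= c(l[-1], -Inf)
    cand <- which(isMax)
    if (!length(cand)) next
    cand <- cand[order(-l[cand], p[cand])]
    acc <- integer(0)
    for (ci in cand) {
      sep <- TRUE
      for (ai in acc) {
        lo <- min(ci, ai); hi <- max(ci, ai)
        dip <- min(l[lo:hi])
        if (dip > min(l[ci], l[ai]) - 1) { sep <- FALSE; break }
      }
      if (sep) acc <- c(acc, ci)
    }
    for (ai in sort(acc)) {
      thr <- l[ai] - 1
      lo <- ai; while (lo > 1 && l[lo - 1] >= thr) lo <- lo - 1
      hi <- ai; while (hi < m && l[hi + 1] >= thr) hi <- hi + 1
      a <- scan@effect[jj[ai]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, peakCM = p[ai], lod = l[ai], intervalLow = p[lo],
        intervalHigh = p[hi], additiveEffect = a,
        percentEffect = if (is.null(traitMean)) NA_real_
                        else percentEffect(a, traitMean),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), peakCM = numeric(0),
                      lod = numeric(0), intervalLow = numeric(0),
                      intervalHigh = numeric(0), additiveEffect = numeric(0),
                      percentEffect = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(factor(res$chrom, unique(scan@chrom)), res$peakCM), ,
      drop = FALSE]
}

#' Percent effect of a QTL
#'
#' The allelic-substitution effect 2a as a percentage of the trait mean
#' across lines: 100 |2a| / |mean|.
#'
#' @param a additive effect (half the class-mean difference).
#' @param traitMean mean of the line-level trait across lines (non-zero).
#' @return percent effect (>= 0); NA with a warning when the mean is zero.
#' @export
percentEffect <- function(a, traitMean) {
  out <- ifelse(traitMean == 0, NA_real_, 100 * abs(2 * a) / abs(traitMean))
  if (any(traitMean == 0)) warning("zero trait mean: percent effect undefined")
  out
}

#' @rdname cimScan
#' @param x a [ScanResult-class].
#' @param path output CSV path.
#' @export
writeScan <- function(x, path) {
  utils::write.csv(scanTable(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
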