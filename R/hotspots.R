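# QTL hotspot detection: sliding-window counts of peaks across many
# phenotypes, a uniform-relocation permutation threshold, and hotspot naming.

.chromRanges <- function(map) {
  mt <- markerTable(map)
  do.call(rbind, lapply(chromosomes(map), function(ch) {
    p <- mt$pos[mt$chrom == ch]
    data.frame(chrom = ch, lo = min(p), hi = max(p), stringsAsFactors = FALSE)
  }))
}

.windowCenters <- function(map, step) {
  cr <- .chromRanges(map)
  lapply(stats::setNames(seq_len(nrow(cr)), cr$chrom), function(i)
    sort(unique(round(c(seq(cr$lo[i], cr$hi[i], by = step), cr$hi[i]), 9))))
}

# counts of distinct phenotypes with >= 1 peak in each half-open window
# [c - w/2, c + w/2); returns list of per-chromosome count vectors
.windowCountsCore <- function(chrom, pos, phen, centers, window) {
  w2 <- window / 2
  phenInt <- as.integer(factor(phen))
  lapply(stats::setNames(names(centers), names(centers)), function(ch) {
    cen <- centers[[ch]]
    cnt <- integer(length(cen))
    sel <- which(chrom == ch)
    if (!length(sel)) return(cnt)
    lo <- findInterval(pos[sel] - w2, cen) + 1L   # first center > q - w/2
    hi <- findInterval(pos[sel] + w2, cen)        # last center <= q + w/2
    ok <- lo <= hi
    if (!any(ok)) return(cnt)
    len <- hi[ok] - lo[ok] + 1L
    wi <- sequence(len, from = lo[ok])
    ph <- rep(phenInt[sel][ok], len)
    u <- !duplicated(wi + (ph - 1) * (length(cen) + 1L))  # 1 per phenotype
    as.integer(tabulate(wi[u], nbins = length(cen)))
  })
}

#' Sliding-window QTL counts across phenotypes
#'
#' Places each phenotype's QTL peaks on the map and, for half-open windows
#' [c - w/2, c + w/2) centered on a fixed grid, counts the number of
#' distinct phenotypes with at least one peak inside the window.
#'
#' @param peaks data.frame with columns phenotype, chrom, peakCM (e.g.
#'   row-bound [findPeaks()] results with a phenotype column added).
#' @param map the [GeneticMap-class]; peaks off the map are rejected.
#' @param window window width in cM (> 0), default 5.
#' @param step window-center spacing in cM (> 0), default 1.
#' @return data.frame(chrom, center, count), deterministic and invariant to
#'   peak row order.
#' @export
windowCounts <- function(peaks, map, window = 5, step = 1) {
  stopifnot(is(map, "GeneticMap"))
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  cr <- .chromRanges(map)
  if (nrow(peaks)) {
    m <- match(peaks$chrom, cr$chrom)
    if (anyNA(m) || any(peaks$peakCM < cr$lo[m] - 1e-9) ||
        any(peaks$peakCM > cr$hi[m] + 1e-9))
      stop("peaks off the map")
  }
  centers <- .windowCenters(map, step)
  cnt <- .windowCountsCore(peaks$chrom, peaks$peakCM,
                           as.character(peaks$phenotype), centers, window)
  out <- data.frame(
    chrom = rep(names(centers), lengths(centers)),
    center = unlist(centers, use.names = FALSE),
    count = unlist(cnt, use.names = FALSE), stringsAsFactors = FALSE)
  attr(out, "window") <- window; attr(out, "step") <- step
  out
}

#' Permutation threshold for hotspot size
#'
#' Null model: every phenotype keeps its number of peaks, but each peak is
#' relocated to a uniform random position on the genome (chromosome chosen
#' proportional to map length). The threshold is the empirical (1 - alpha)
#' quantile (type-1 order statistic) of the genome-wide maximum window count
#' over `nPerm` such relocations.
#'
#' @inheritParams windowCounts
#' @param nPerm number of permutations (>= 100 recommended), default 1000.
#' @param alpha significance level, default 0.05.
#' @param seed optional integer seed.
#' @return integer count threshold with per-permutation maxima in attribute
#'   `maxCounts`; NA (with a warning) when there are no peaks.
#' @export
hotspotThreshold <- function(peaks, map, window = 5, step = 1, nPerm = 1000,
                             alpha = 0.05, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  if (!nrow(peaks)) {
    warning("no peaks: hotspot threshold undefined")
    return(NA_integer_)
  }
  if (!is.null(seed)) set.seed(seed)
  cr <- .chromRanges(map)
  len <- cr$hi - cr$lo
  centers <- .windowCenters(map, step)
  phen <- as.character(peaks$phenotype)
  np <- nrow(peaks)
  maxes <- vapply(seq_len(nPerm), function(i) {
    u <- stats::runif(np, 0, sum(len))
    ci <- findInterval(u, cumsum(len), left.open = TRUE) + 1L
    qpos <- cr$lo[ci] + (u - c(0, cumsum(len))[ci])
    max(unlist(.windowCountsCore(cr$chrom[ci], qpos, phen, centers, window)))
  }, 0)
  thr <- sort(maxes)[ceiling((1 - alpha) * nPerm)]
  out <- as.integer(thr)
  attr(out, "maxCounts") <- as.integer(maxes)
  out
}

.romanize <- function(ch) {
  suppressWarnings(n <- as.integer(ch))
  ifelse(is.na(n), ch, as.character(utils::as.roman(n)))
}

#' Name significant hotspots
#'
#' Windows whose count exceeds the threshold are merged when contiguous
#' (adjacent centers on one chromosome); each merged region emits one
#' hotspot at its maximal-count window center (ties to the leftmost window)
#' named PREFIX.CHROM.cM, the chromosome as a Roman numeral and the position
#' rounded to the nearest cM (e.g. "M.CV.II.16").
#'
#' @param counts output of [windowCounts()].
#' @param threshold count threshold (e.g. from [hotspotThreshold()]).
#' @param prefix phenotype-class prefix, e.g. "M.CV" or "M.AV".
#' @return data.frame(name, chrom, cM, count), zero rows if nothing exceeds
#'   the threshold.
#' @export
nameHotspots <- function(counts, threshold, prefix) {
  step <- attr(counts, "step")
  if (is.null(step)) step <- 1
  out <- list()
  for (ch in unique(counts$chrom)) {
    d <- counts[counts$chrom == ch, ]
    d <- d[order(d$center), ]
    supra <- d$count > threshold
    if (!any(supra)) next
    grp <- cumsum(c(TRUE, diff(which(supra)) > 1))
    idx <- split(which(supra), grp)
    for (ii in idx) {
      best <- ii[which.max(d$count[ii])]   # which.max: leftmost on ties
      out[[length(out) + 1L]] <- data.frame(
        name = sprintf("%s.%s.%d", prefix, .romanize(ch),
                       as.integer(round(d$center[best]))),
        chrom = ch, cM = d$center[best], count = d$count[best],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(0), chrom = character(0),
                      cM = numeric(0), count = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
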