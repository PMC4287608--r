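# Per-line CV phenotypes and population-level noise statistics.

#' Per-line, per-experiment coefficient of variation
#'
#' For every (line, experiment, phenotype) cell, CV = sample SD (n-1
#' denominator) of the absolute replicate values divided by their mean.
#' Cells with fewer than `minReps` replicates, or with |mean| at or below
#' the floor, are flagged undefined — never silently zeroed. The per-line
#' CV is the arithmetic mean of the defined per-experiment CVs, giving
#' independent biological replicate measures of within-line noise.
#'
#' @param obs long-format data.frame(line, experiment, block, phenotype,
#'   value) (block optional here).
#' @param minReps minimum replicates per cell (>= 2).
#' @param meanFloor |mean| at or below this is undefined; default
#'   1e-12 * max(|value|) per phenotype, guarding signals bounded away from 0.
#' @return A [LineCVTable-class].
#' @examples
#' obs <- data.frame(line = "L1", experiment = "E1", block = c("B1", "B2", "B3"),
#'                   phenotype = "p", value = c(1, 2, 3))
#' perExperimentCV(computeLineCV(obs))$cv   # sd = 1, mean = 2 -> 0.5
#' @export
computeLineCV <- function(obs, minReps = 2, meanFloor = NULL) {
  if (minReps < 2) stop("minReps must be >= 2")
  stopifnot(all(c("line", "experiment", "phenotype", "value") %in% names(obs)))
  if (any(!is.finite(obs$value))) stop("phenotype values must be finite")
  v <- abs(obs$value)
  key <- interaction(obs$line, obs$experiment, obs$phenotype, drop = TRUE,
                     lex.order = TRUE, sep = "\t")
  n <- as.vector(tapply(v, key, length))
  m <- as.vector(tapply(v, key, mean))
  s <- as.vector(tapply(v, key, stats::sd))
  ks <- strsplit(levels(key), "\t", fixed = TRUE)
  pe <- data.frame(line = vapply(ks, `[`, "", 1L),
                   experiment = vapply(ks, `[`, "", 2L),
                   phenotype = vapply(ks, `[`, "", 3L),
                   n = n, mean = m, sd = s, stringsAsFactors = FALSE)
  if (is.null(meanFloor)) {
    mx <- tapply(v, obs$phenotype, max)
    floorByPhen <- 1e-12 * mx[pe$phenotype]
  } else floorByPhen <- rep(meanFloor, nrow(pe))
  pe$defined <- pe$n >= minReps & abs(pe$mean) > floorByPhen
  pe$cv <- ifelse(pe$defined, pe$sd / pe$mean, NA_real_)
  pe <- pe[, c("line", "phenotype", "experiment", "n", "mean", "sd", "cv",
               "defined")]

  key2 <- interaction(pe$line, pe$phenotype, drop = TRUE, lex.order = TRUE,
                      sep = "\t")
  meanCV <- as.vector(tapply(ifelse(pe$defined, pe$cv, NA_real_), key2,
                             function(x) mean(x, na.rm = TRUE)))
  nExp <- as.vector(tapply(pe$defined, key2, sum))
  ks2 <- strsplit(levels(key2), "\t", fixed = TRUE)
  # grand mean of the raw (absolute) values across all replicates
  key3 <- interaction(obs$line, obs$phenotype, drop = TRUE, lex.order = TRUE,
                      sep = "\t")
  gm <- tapply(v, key3, mean)
  pl <- data.frame(line = vapply(ks2, `[`, "", 1L),
                   phenotype = vapply(ks2, `[`, "", 2L),
                   nExperiments = nExp, meanCV = meanCV,
                   grandMean = as.vector(gm[levels(key2)]),
                   stringsAsFactors = FALSE)
  pl$defined <- pl$nExperiments > 0 & is.finite(pl$meanCV)
  pl$meanCV[!pl$defined] <- NA_real_
  new("LineCVTable", perExperiment = pe, perLine = pl)
}

.skewness <- function(x) {
  x <- x[is.finite(x)]; n <- length(x)
  m <- mean(x); m2 <- mean((x - m)^2)
  if (n < 3 || m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

.exKurtosis <- function(x) {
  x <- x[is.finite(x)]; n <- length(x)
  m <- mean(x); m2 <- mean((x - m)^2)
  if (n < 4 || m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

#' Population (genetic) coefficient of variation per phenotype
#'
#' The genetic CV of a line-level statistic: SD across lines divided by mean
#' across lines, computed for both the per-line mean CV (how much within-line
#' noise varies genetically) and the per-line grand mean (how much the
#' average phenotype varies genetically), together with moment-based skewness
#' and excess kurtosis of both statistics.
#'
#' @param table a [LineCVTable-class].
#' @param minLines phenotypes with fewer defined lines are flagged and
#'   excluded from downstream percentile ranking (default 3).
#' @return data.frame(phenotype, nLines, popCVofCV, popCVofMean, skewCV,
#'   kurtCV, skewMean, kurtMean, defined).
#' @export
populationGeneticCV <- function(table, minLines = 3) {
  stopifnot(is(table, "LineCVTable"))
  pl <- perLineCV(table)
  phens <- sort(unique(pl$phenotype))
  out <- lapply(phens, function(ph) {
    d <- pl[pl$phenotype == ph & pl$defined, ]
    cvv <- d$meanCV; mv <- d$grandMean
    ok <- nrow(d) >= minLines
    pc <- function(x) {
      m <- mean(x)
      if (!length(x) || m == 0) NA_real_ else stats::sd(x) / m
    }
    data.frame(phenotype = ph, nLines = nrow(d),
               popCVofCV = if (ok) pc(cvv) else NA_real_,
               popCVofMean = if (ok) pc(mv) else NA_real_,
               skewCV = .skewness(cvv), kurtCV = .exKurtosis(cvv),
               skewMean = .skewness(mv), kurtMean = .exKurtosis(mv),
               defined = ok && is.finite(pc(cvv)) && is.finite(pc(mv)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentile classification of phenotypes
#'
#' Labels each phenotype by where its population CV-of-CV and CV-of-mean fall
#' in the cross-phenotype distribution: HIGH_CV_LOW_MEAN (CV-of-CV in the top
#' tail AND CV-of-mean in the bottom tail), LOW_BOTH (both in the bottom
#' tail), HIGH_MEAN_MID_CV (CV-of-mean in the top tail, CV-of-CV in neither
#' tail), else NONE. Each tail holds floor(n * tail) phenotypes; ties are
#' broken by stable phenotype-id order, so the labels are deterministic and
#' independent of input row order.
#'
#' @param summary output of [populationGeneticCV()].
#' @param tail tail fraction in (0, 0.5); default 0.05.
#' @return the summary with a `class` column added.
#' @export
classifyPercentiles <- function(summary, tail = 0.05) {
  if (tail <= 0 || tail >= 0.5) stop("tail must lie in (0, 0.5)")
  s <- summary[summary$defined, ]
  s <- s[order(s$phenotype), ]
  n <- nrow(s)
  k <- floor(n * tail)
  tailSet <- function(value, top) {
    o <- order(value, s$phenotype)          # stable: ties by phenotype id
    if (top) o <- order(-value, s$phenotype)
    s$phenotype[o[seq_len(k)]]
  }
  topCV <- tailSet(s$popCVofCV, TRUE); botCV <- tailSet(s$popCVofCV, FALSE)
  topM <- tailSet(s$popCVofMean, TRUE); botM <- tailSet(s$popCVofMean, FALSE)
  lab <- function(ph) {
    if (ph %in% topCV && ph %in% botM) return("HIGH_CV_LOW_MEAN")
    if (ph %in% botCV && ph %in% botM) return("LOW_BOTH")
    if (ph %in% topM && !(ph %in% topCV) && !(ph %in% botCV))
      return("HIGH_MEAN_MID_CV")
    "NONE"
  }
  cls <- stats::setNames(vapply(s$phenotype, lab, ""), s$phenotype)
  out <- summary
  out$class <- ifelse(out$defined, unname(cls[out$phenotype]), "NONE")
  out
}

#' Association between line means and line CVs
#'
#' Pearson and Spearman correlations with p-values. With
#' `level = "lines"` (default) the correlation is computed per phenotype
#' across lines between the per-line grand mean and the per-line mean CV;
#' with `level = "phenotypes"` a single correlation across phenotypes between
#' the phenotype-level averages of the two statistics. Zero-variance inputs
#' yield flagged undefined coefficients, never zeros.
#'
#' @param table a [LineCVTable-class].
#' @param level "lines" or "phenotypes".
#' @return data.frame with pearsonR, pearsonP, spearmanR, spearmanP, n,
#'   defined (one row per phenotype, or a single row).
#' @export
cvMeanAssociation <- function(table, level = c("lines", "phenotypes")) {
  stopifnot(is(table, "LineCVTable"))
  level <- match.arg(level)
  pl <- perLineCV(table)
  corRow <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(pearsonR = NA_real_, pearsonP = NA_real_,
                        spearmanR = NA_real_, spearmanP = NA_real_,
                        n = length(x), defined = FALSE))
    pt <- stats::cor.test(x, y, method = "pearson")
    st <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(pearsonR = unname(pt$estimate), pearsonP = pt$p.value,
               spearmanR = unname(st$estimate), spearmanP = st$p.value,
               n = length(x), defined = TRUE)
  }
  if (level == "lines") {
    phens <- sort(unique(pl$phenotype))
    out <- do.call(rbind, lapply(phens, function(ph) {
      d <- pl[pl$phenotype == ph & pl$defined, ]
      cbind(data.frame(phenotype = ph, stringsAsFactors = FALSE),
            corRow(d$grandMean, d$meanCV))
    }))
    rownames(out) <- NULL
    out
  } else {
    mcv <- tapply(pl$meanCV[pl$defined], pl$phenotype[pl$defined], mean)
    mm <- tapply(pl$grandMean[pl$defined], pl$phenotype[pl$defined], mean)
    ph <- intersect(names(mcv), names(mm))
    corRow(as.vector(mm[ph]), as.vector(mcv[ph]))
  }
}

#' Distribution diagnostics for line-level statistics
#'
#' Moment-based skewness and excess kurtosis of the per-line mean CV and the
#' per-line grand mean across lines, per phenotype — the normality
#' diagnostics used to compare the distributional behaviour of noise and
#' mean phenotypes.
#'
#' @param table a [LineCVTable-class].
#' @return data.frame(phenotype, nLines, skewCV, kurtCV, skewMean, kurtMean,
#'   defined).
#' @export
distributionDiagnostics <- function(table) {
  stopifnot(is(table, "LineCVTable"))
  pl <- perLineCV(table)
  phens <- sort(unique(pl$phenotype))
  out <- lapply(phens, function(ph) {
    d <- pl[pl$phenotype == ph & pl$defined, ]
    data.frame(phenotype = ph, nLines = nrow(d),
               skewCV = if (nrow(d) >= 4) .skewness(d$meanCV) else NA_real_,
               kurtCV = if (nrow(d) >= 4) .exKurtosis(d$meanCV) else NA_real_,
               skewMean = if (nrow(d) >= 4) .skewness(d$grandMean) else NA_real_,
               kurtMean = if (nrow(d) >= 4) .exKurtosis(d$grandMean) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$defined <- is.finite(out$skewCV)
  out
}

#' Write the per-line CV table as CSV
#'
#' One row per (line, phenotype) with the mean per-line CV — the standard
#' "average per line CV" table layout used for sharing noise phenotypes.
#'
#' @param table a [LineCVTable-class].
#' @param path output CSV path.
#' @export
writeLineCV <- function(table, path) {
  utils::write.csv(perLineCV(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
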