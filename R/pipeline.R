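# End-to-end orchestration: simulate (or load) -> CV -> heritability ->
# mean & CV genome scans -> hotspots -> marker ANOVA -> optional structured
# null census, with every stage writing versioned outputs and a JSON
# manifest holding parameters, per-stage seeds and file checksums.

.defaultConfig <- function() {
  list(
    simulate = list(nLines = 316, nExperiments = 2, repsPerExperiment = 2,
                    nChromosomes = 5, chromLength = 90, markerSpacing = 5,
                    nTraits = 30, nMeanQTL = 2, nVarQTL = 1,
                    meanEffect = 0.5, varEffect = log(1.5),
                    cytoMeanEffect = 0, cytoSdEffect = 0,
                    grandMean = 10, baseSd = 1, family = "normal"),
    cv = list(minReps = 2, tail = 0.05),
    scan = list(step = 1, nCofactors = 3, window = 10, nPerm = 0,
                lodMin = 2, alpha = 0.05),
    hotspots = list(window = 5, step = 1, nPerm = 1000, alpha = 0.05),
    anova = list(edgeMin = 0.10, fdr = 0.05),
    nullCensus = list(enabled = FALSE, nPerm = 10)
  )
}

.mergeConfig <- function(user, def) {
  for (nm in names(def)) {
    if (is.null(user[[nm]])) user[[nm]] <- def[[nm]]
    else if (is.list(def[[nm]]))
      user[[nm]] <- .mergeConfig(user[[nm]], def[[nm]])
  }
  user
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> CV -> heritability -> genome scans (mean
#' and CV) -> hotspots -> marker ANOVA -> optional structured-permutation
#' null census, writing all stage outputs and a manifest to `outDir`. The
#' single root seed expands deterministically into per-stage seeds, so the
#' same config and seed reproduce every output.
#'
#' @param config a list, or path to a YAML file, following the structure of
#'   the package default (see the methods vignette); omitted entries take
#'   defaults. Supply `inputs = list(map=, genotypes=, phenotypes=)` paths
#'   instead of `simulate` to analyse existing data.
#' @param outDir output directory (created if needed).
#' @param seed root integer seed.
#' @return the manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("noiseqtl_run_"),
                        seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config, .defaultConfig())
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  put <- function(name) { f <- file.path(outDir, name); files <<- c(files, f); f }
  seeds <- list(simulate = seed, scan = seed + 1000L, hotspot = seed + 2000L,
                census = seed + 3000L)

  # --- stage: data -----------------------------------------------------------
  if (!is.null(cfg$inputs)) {
    map <- readGeneticMap(cfg$inputs$map)
    geno <- readGenotypes(cfg$inputs$genotypes, map)
    obs <- readPhenotypes(cfg$inputs$phenotypes)
    design <- NULL
    arch <- NULL
  } else {
    sc <- cfg$simulate
    map <- buildDefaultMap(sc$nChromosomes, sc$chromLength, sc$markerSpacing)
    design <- DesignSpec(sc$nLines, sc$nExperiments, sc$repsPerExperiment,
                         seed = seeds$simulate)
    geno <- simulateRILGenotypes(map, design)
    traits <- sprintf("T%03d", seq_len(sc$nTraits))
    arch <- randomArchitecture(map, traits, nMeanQTL = sc$nMeanQTL,
                               nVarQTL = sc$nVarQTL,
                               meanEffect = sc$meanEffect,
                               varEffect = sc$varEffect,
                               cytoMeanEffect = sc$cytoMeanEffect,
                               cytoSdEffect = sc$cytoSdEffect,
                               grandMean = sc$grandMean, baseSd = sc$baseSd,
                               seed = seeds$simulate)
    obs <- simulatePhenotypes(geno, arch, design, family = sc$family)
    writeGeneticMap(map, put("map.tsv"))
    writeGenotypes(geno, put("genotypes.tsv"))
    writePhenotypes(obs, put("phenotypes.csv"))
    writeArchitecture(arch, put("truth.yaml"))
  }

  # --- stage: CV -------------------------------------------------------------
  cvTab <- computeLineCV(obs, minReps = cfg$cv$minReps)
  writeLineCV(cvTab, put("line_cv.csv"))
  popSummary <- classifyPercentiles(populationGeneticCV(cvTab),
                                    tail = cfg$cv$tail)
  utils::write.csv(popSummary, put("population_summary.csv"),
                   row.names = FALSE)

  # --- stage: heritability ---------------------------------------------------
  herCV <- heritabilityAcrossPhenotypes(cvTab, geno, "cv")
  herMean <- heritabilityAcrossPhenotypes(cvTab, geno, "mean")
  writeHeritability(herCV, put("heritability_cv.csv"))
  writeHeritability(herMean, put("heritability_mean.csv"))

  # --- stage: genome scans ---------------------------------------------------
  grid <- genotypeProbabilities(geno, step = cfg$scan$step)
  pl <- perLineCV(cvTab)
  scanOne <- function(statistic) {
    peaks <- list()
    for (ph in sort(unique(pl$phenotype))) {
      d <- pl[pl$phenotype == ph & pl$defined, ]
      y <- stats::setNames(if (statistic == "cv") d$meanCV else d$grandMean,
                           d$line)
      res <- tryCatch({
        cof <- selectCofactors(grid, y, k = cfg$scan$nCofactors)
        sc <- cimScan(grid, y, cofactors = cof, window = cfg$scan$window)
        thr <- if (cfg$scan$nPerm > 0)
          permutationThreshold(grid, y, nPerm = cfg$scan$nPerm,
                               alpha = cfg$scan$alpha,
                               nCofactors = cfg$scan$nCofactors,
                               window = cfg$scan$window,
                               seed = seeds$scan + match(ph, unique(pl$phenotype)))
          else NA_real_
        pk <- findPeaks(sc, lodMin = cfg$scan$lodMin, traitMean = mean(y))
        if (nrow(pk)) {
          pk$phenotype <- ph
          pk$permThreshold <- as.numeric(thr)
        }
        pk
      }, error = function(e) NULL)
      if (!is.null(res) && nrow(res)) peaks[[ph]] <- res
    }
    if (length(peaks)) do.call(rbind, peaks)
    else data.frame(chrom = character(0), peakCM = numeric(0), lod = numeric(0),
                    intervalLow = numeric(0), intervalHigh = numeric(0),
                    additiveEffect = numeric(0), percentEffect = numeric(0),
                    phenotype = character(0), permThreshold = numeric(0))
  }
  peaksCV <- scanOne("cv")
  peaksMean <- scanOne("mean")
  utils::write.csv(peaksCV, put("peaks_cv.csv"), row.names = FALSE)
  utils::write.csv(peaksMean, put("peaks_mean.csv"), row.names = FALSE)

  # --- stage: hotspots -------------------------------------------------------
  hot <- function(peaks, prefix, seedOff) {
    if (!nrow(peaks)) return(list(counts = NULL, hotspots = NULL,
                                  threshold = NA_integer_))
    counts <- windowCounts(peaks, map, window = cfg$hotspots$window,
                           step = cfg$hotspots$step)
    thr <- hotspotThreshold(peaks, map, window = cfg$hotspots$window,
                            step = cfg$hotspots$step,
                            nPerm = cfg$hotspots$nPerm,
                            alpha = cfg$hotspots$alpha,
                            seed = seeds$hotspot + seedOff)
    list(counts = counts, hotspots = nameHotspots(counts, thr, prefix),
         threshold = thr)
  }
  hotCV <- hot(peaksCV, "M.CV", 0L)
  hotMean <- hot(peaksMean, "M.AV", 1L)
  for (nm in c("CV", "Mean")) {
    h <- if (nm == "CV") hotCV else hotMean
    if (!is.null(h$counts))
      utils::write.csv(h$counts, put(sprintf("window_counts_%s.csv",
                                             tolower(nm))), row.names = FALSE)
    if (!is.null(h$hotspots))
      utils::write.csv(h$hotspots, put(sprintf("hotspots_%s.csv",
                                               tolower(nm))), row.names = FALSE)
  }

  # --- stage: marker ANOVA ---------------------------------------------------
  anovaOut <- NULL
  hs <- unique(rbind(if (!is.null(hotCV$hotspots)) hotCV$hotspots[, c("chrom", "cM")],
                     if (!is.null(hotMean$hotspots)) hotMean$hotspots[, c("chrom", "cM")]))
  if (!is.null(hs) && nrow(hs)) {
    markers <- unique(nearestMarker(map, hs$chrom, hs$cM))
    markers <- c(markers, "CYTOPLASM")
    results <- list()
    for (ph in sort(unique(pl$phenotype))) {
      d <- pl[pl$phenotype == ph & pl$defined, ]
      y <- stats::setNames(d$meanCV, d$line)
      results[[ph]] <- tryCatch(
        suppressWarnings(pairwiseEpistasisAnova(y, geno, markers)),
        error = function(e) NULL)
    }
    results <- Filter(Negate(is.null), results)
    if (length(results)) {
      flat <- do.call(rbind, lapply(names(results), function(ph)
        cbind(phenotype = ph, results[[ph]])))
      utils::write.csv(flat, put("epistasis_anova_cv.csv"), row.names = FALSE)
      net <- buildNetwork(results, edgeMin = cfg$anova$edgeMin,
                          fdr = cfg$anova$fdr)
      writeNetworkSIF(net, file.path(outDir, "epistasis_network_cv"))
      files <- c(files, file.path(outDir, "epistasis_network_cv.sif"))
      anovaOut <- net
    }
  }

  # --- stage: structured null census ----------------------------------------
  censusOut <- NULL
  if (isTRUE(cfg$nullCensus$enabled)) {
    censusOut <- nullQtlCensus(obs, geno, nPerm = cfg$nullCensus$nPerm,
                               step = max(cfg$scan$step, 2),
                               nCofactors = cfg$scan$nCofactors,
                               window = cfg$scan$window,
                               lodMin = cfg$scan$lodMin,
                               seed = seeds$census)
    utils::write.csv(data.frame(permutation = seq_along(censusOut$counts),
                                qtlCount = censusOut$counts),
                     put("null_census.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "noiseQTL",
    version = as.character(utils::packageVersion("noiseQTL")),
    seed = seed, seeds = seeds, config = cfg,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    observedQtl = list(cv = nrow(peaksCV), mean = nrow(peaksMean)),
    hotspotThresholds = list(cv = as.integer(hotCV$threshold),
                             mean = as.integer(hotMean$threshold)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, outDir = outDir, peaksCV = peaksCV,
                 peaksMean = peaksMean, heritabilityCV = herCV,
                 heritabilityMean = herMean, network = anovaOut,
                 census = censusOut, hotspotsCV = hotCV$hotspots,
                 hotspotsMean = hotMean$hotspots))
}

#' Summary tables for a pipeline run
#'
#' Per-statistic QTL-count frequency tables (how many phenotypes detected 0,
#' 1, 2, ... QTL), percent-effect distributions, a CV-vs-mean heritability
#' table, and the hotspot overlap between the mean and CV scans.
#'
#' @param run the list returned by [runPipeline()].
#' @return list of data.frames: qtlCountFreq, effectSummary, heritability,
#'   hotspotOverlap.
#' @export
summarizeRun <- function(run) {
  freq <- function(peaks, phens) {
    cnt <- table(factor(peaks$phenotype, levels = phens))
    as.data.frame(table(nQTL = factor(as.vector(cnt),
                                      levels = 0:max(0, as.vector(cnt)))),
                  responseName = "nPhenotypes")
  }
  phens <- sort(unique(c(run$heritabilityCV$phenotype,
                         run$peaksCV$phenotype, run$peaksMean$phenotype)))
  effSummary <- do.call(rbind, lapply(
    list(cv = run$peaksCV, mean = run$peaksMean), function(p) {
      if (!nrow(p)) return(data.frame(n = 0, meanPercentEffect = NA_real_,
                                      medianPercentEffect = NA_real_))
      data.frame(n = nrow(p),
                 meanPercentEffect = mean(p$percentEffect, na.rm = TRUE),
                 medianPercentEffect = stats::median(p$percentEffect,
                                                     na.rm = TRUE))
    }))
  effSummary$statistic <- rownames(effSummary)
  her <- merge(run$heritabilityCV[, c("phenotype", "h2Nuclear",
                                      "h2Organellar")],
               run$heritabilityMean[, c("phenotype", "h2Nuclear",
                                        "h2Organellar")],
               by = "phenotype", suffixes = c("CV", "Mean"))
  overlap <- if (!is.null(run$hotspotsCV) && !is.null(run$hotspotsMean) &&
                 nrow(run$hotspotsCV) && nrow(run$hotspotsMean)) {
    both <- merge(run$hotspotsCV, run$hotspotsMean, by = "chrom",
                  suffixes = c("CV", "Mean"))
    both[abs(both$cMCV - both$cMMean) <= 5, , drop = FALSE]
  } else data.frame()
  list(qtlCountFreq = list(cv = freq(run$peaksCV, phens),
                           mean = freq(run$peaksMean, phens)),
       effectSummary = effSummary, heritability = her,
       hotspotOverlap = overlap)
}
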