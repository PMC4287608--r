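# Composite interval mapping: genotype probabilities, cofactor selection,
# HK scans vs brute-force oracles, permutation thresholds, peak calling.

test_that("genotype probabilities are exact at markers and match the two-point
          enumeration oracle between them", {
  map <- GeneticMap(rep("I", 2), c("a", "b"), c(0, 20))
  g <- toyGeno(200, seed = 3, map = map)
  grid <- genotypeProbabilities(g, step = 10)
  gp <- gridPositions(grid)
  P <- alleleProbs(grid)
  # at markers: exactly 0/1 matching the observed allele
  X <- alleleCodes(g)
  expect_identical(unname(P[, which(gp$markerId %in% "a")]),
                   unname(as.numeric(X[, "a"] == 1)))
  expect_identical(unname(P[, which(gp$markerId %in% "b")]),
                   unname(as.numeric(X[, "b"] == 1)))
  # midpoint: enumeration over the four flank-state paths, independently
  mid <- which(gp$pos == 10)
  R1 <- rilSwitchProb(10); R2 <- rilSwitchProb(10)
  oracle <- function(xl, xr) {
    wA <- (if (xl == 1) 1 - R1 else R1) * (if (xr == 1) 1 - R2 else R2)
    wB <- (if (xl == 1) R1 else 1 - R1) * (if (xr == 1) R2 else 1 - R2)
    wA / (wA + wB)
  }
  for (i in 1:20) {
    expect_equal(unname(P[i, mid]), oracle(X[i, "a"], X[i, "b"]),
                 tolerance = 1e-12)
  }
  # concordant AA flanks give the closed form; discordant give exactly 0.5
  expect_equal(oracle(1, 1),
               (1 - R1) * (1 - R2) / ((1 - R1) * (1 - R2) + R1 * R2),
               tolerance = 1e-15)
  expect_equal(oracle(1, -1), 0.5, tolerance = 1e-15)
  expect_equal(oracle(-1, 1), 0.5, tolerance = 1e-15)
})

test_that("missing genotypes condition on the nearest non-missing flank", {
  map <- GeneticMap(rep("I", 3), c("a", "b", "c"), c(0, 10, 20))
  a <- matrix("A", 4, 3, dimnames = list(sprintf("L%d", 1:4),
                                         c("a", "b", "c")))
  a[1, 2] <- NA          # L1 missing the middle marker
  a[2, ] <- c("B", NA, "B")
  a[3, ] <- NA           # fully missing line
  g <- RILGenotypes(a, rep("A_CYT", 4), map)
  grid <- genotypeProbabilities(g, step = 10)
  gp <- gridPositions(grid)
  P <- alleleProbs(grid)
  mid <- which(gp$pos == 10)
  # L1: flanks a (A) and c (A), 10 cM each side
  R <- rilSwitchProb(10)
  expect_equal(unname(P[1, mid]), (1 - R)^2 / ((1 - R)^2 + R^2),
               tolerance = 1e-12)
  expect_equal(unname(P[2, mid]), R^2 / (R^2 + (1 - R)^2), tolerance = 1e-12)
  expect_equal(unname(P[3, ]), rep(0.5, ncol(P)))
  expect_equal(attr(grid, "fullyMissing"), "L3")
})

test_that("forward cofactor selection is exact for noiseless signals and
          matches a brute-force greedy lm oracle", {
  g <- toyGeno(120, seed = 5)
  grid <- genotypeProbabilities(g, step = 5)
  X <- alleleCodes(g)
  expect_identical(selectCofactors(grid, setNames(rnorm(120), lineNames(g)),
                                   k = 0), character(0))
  # noiseless single-marker signal: that marker is picked first
  y0 <- setNames(X[, "mII_20"] * 2, lineNames(g))
  expect_equal(selectCofactors(grid, y0, k = 1)[1], "mII_20")
  # brute-force greedy oracle over all markers, via lm at every step
  set.seed(6)
  y <- setNames(0.8 * X[, "mI_10"] - 0.5 * X[, "mII_30"] + rnorm(120),
                lineNames(g))
  sel <- selectCofactors(grid, y, k = 3)
  chosen <- character(0)
  for (s in 1:3) {
    rss <- vapply(colnames(X), function(m) {
      if (m %in% chosen) return(Inf)
      d <- data.frame(y = y, X[, c(chosen, m), drop = FALSE])
      sum(resid(lm(y ~ ., data = d))^2)
    }, 0)
    chosen <- c(chosen, names(which.min(rss)))
  }
  expect_equal(as.vector(sel), chosen)
})

test_that("CIM with zero cofactors equals single-marker regression at every
          marker (brute-force oracle, 1e-8)", {
  map <- buildDefaultMap(2, 45, 5)
  g <- simulateRILGenotypes(map, DesignSpec(100, seed = 7))
  X <- alleleCodes(g)
  set.seed(8)
  y <- setNames(0.6 * X[, "mI_20"] + rnorm(100), lineNames(g))
  grid <- genotypeProbabilities(g, step = 1)
  sc <- cimScan(grid, y, cofactors = character(0))
  st <- scanTable(sc)
  gp <- gridPositions(grid)
  for (m in markerNames(map)) {
    j <- which(gp$markerId == m)
    expect_equal(st$lod[j], singleMarkerLod(X[, m], y), tolerance = 1e-8)
    # additive effect = half the class-mean difference = lm slope on +-1
    expect_equal(st$effect[j], unname(coef(lm(y ~ X[, m]))[2]),
                 tolerance = 1e-8)
  }
  expect_true(all(st$lod >= 0))
})

test_that("an infinite window drops same-chromosome cofactors entirely", {
  g <- toyGeno(100, seed = 9)
  X <- alleleCodes(g)
  set.seed(10)
  y <- setNames(0.5 * X[, "mI_15"] + rnorm(100), lineNames(g))
  grid <- genotypeProbabilities(g, step = 5)
  scInf <- cimScan(grid, y, cofactors = c("mI_10", "mI_25"), window = Inf)
  sc0 <- cimScan(grid, y, cofactors = character(0))
  onI <- scanTable(scInf)$chrom == "I"
  expect_equal(scanTable(scInf)$lod[onI], scanTable(sc0)$lod[onI],
               tolerance = 1e-10)
})

test_that("the scan is invariant to affine phenotype transforms", {
  g <- toyGeno(80, seed = 11)
  set.seed(12)
  y <- setNames(rnorm(80), lineNames(g))
  grid <- genotypeProbabilities(g, step = 5)
  cof <- selectCofactors(grid, y, 2)
  a <- cimScan(grid, y, cof)
  b <- cimScan(grid, setNames(3 * y - 7, names(y)), cof)
  expect_equal(scanTable(a)$lod, scanTable(b)$lod, tolerance = 1e-9)
  expect_equal(3 * scanTable(a)$effect, scanTable(b)$effect, tolerance = 1e-9)
})

test_that("degenerate perfect fits are capped and flagged", {
  g <- toyGeno(60, seed = 13)
  X <- alleleCodes(g)
  y <- setNames(X[, "mI_20"] * 1.0, lineNames(g))   # exact fit at the marker
  grid <- genotypeProbabilities(g, step = 5)
  sc <- cimScan(grid, y)
  st <- scanTable(sc)
  j <- which(gridPositions(grid)$markerId == "mI_20")
  expect_true(st$capped[j])
  expect_equal(st$lod[j], 300)
})

test_that("the permutation threshold is the documented order statistic and
          rejects constant phenotypes", {
  g <- toyGeno(60, seed = 15)
  set.seed(16)
  y <- setNames(rnorm(60), lineNames(g))
  grid <- genotypeProbabilities(g, step = 5)
  thr <- permutationThreshold(grid, y, nPerm = 60, alpha = 0.05,
                              nCofactors = 0, seed = 17)
  mx <- attr(thr, "maxLods")
  expect_equal(as.numeric(thr), sort(mx)[ceiling(0.95 * 60)])
  expect_error(permutationThreshold(grid, setNames(rep(1, 60), names(y)),
                                    nPerm = 10), "constant")
})

test_that("threshold distribution is exchangeable under pre-permutation", {
  g <- toyGeno(80, seed = 19)
  set.seed(20)
  y <- setNames(rnorm(80), lineNames(g))
  grid <- genotypeProbabilities(g, step = 5)
  t1 <- permutationThreshold(grid, y, nPerm = 80, nCofactors = 0, seed = 21)
  yp <- setNames(sample(y), names(y))
  t2 <- permutationThreshold(grid, yp, nPerm = 80, nCofactors = 0, seed = 22)
  ks <- suppressWarnings(ks.test(attr(t1, "maxLods"), attr(t2, "maxLods")))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak calling applies the dip rule and one-LOD intervals", {
  expect_equal(nrow(findPeaks(scanFromCurve(rep(0, 8)), 2)), 0)
  pk <- findPeaks(scanFromCurve(c(0, 1, 3, 1, 0.5, 2.5, 1, 0)), lodMin = 2)
  expect_equal(nrow(pk), 2)                  # dip to 0.5 <= 2.5 - 1
  expect_equal(pk$peakCM, c(3, 6))
  expect_equal(pk$lod, c(3, 2.5))
  # LOD >= peak - 1 regions collapse to the peaks themselves here
  expect_equal(pk$intervalLow, c(3, 6))
  expect_equal(pk$intervalHigh, c(3, 6))
  # a gentler curve expands the one-LOD interval across its neighbours
  pk1 <- findPeaks(scanFromCurve(c(1.2, 2.0, 3, 2.4, 1.9, 0.2)), lodMin = 2)
  expect_equal(nrow(pk1), 1)
  expect_equal(c(pk1$intervalLow, pk1$intervalHigh), c(2, 4))
  # a shallow dip (< 1 LOD below the smaller peak) merges the maxima
  pk2 <- findPeaks(scanFromCurve(c(0, 1, 3, 2.2, 2.8, 1, 0)), lodMin = 2)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$peakCM, 3)
})

test_that("a planted QTL is localized: one peak on the true chromosome in
          most runs, median error <= 5 cM", {
  map <- buildDefaultMap(3, 60, 5)
  found <- 0; errs <- c()
  for (i in 1:30) {
    g <- simulateRILGenotypes(map, DesignSpec(300, seed = 600 + i))
    X <- alleleCodes(g)
    set.seed(700 + i)
    y <- setNames(0.5 * X[, "mII_30"] + rnorm(300), lineNames(g))
    grid <- genotypeProbabilities(g, step = 2)
    cof <- selectCofactors(grid, y, 3)
    pk <- findPeaks(cimScan(grid, y, cof), lodMin = 2)
    onTrue <- pk[pk$chrom == "II", ]
    if (nrow(onTrue) == 1) found <- found + 1
    if (nrow(onTrue)) errs <- c(errs, abs(onTrue$peakCM[1] - 30))
  }
  expect_gte(found / 30, 0.8)
  expect_lte(median(errs), 5)
})

test_that("percent effect follows the allelic-substitution convention", {
  expect_equal(percentEffect(0, 5), 0)
  expect_equal(percentEffect(0.1, 1), 20)
  expect_warning(pe <- percentEffect(0.3, 0), "undefined")
  expect_true(is.na(pe))
  # recovery from the generator: a = 0.25 on grand mean 2.5 -> 20%
  map <- toyMap()
  d <- DesignSpec(400, seed = 23)
  g <- simulateRILGenotypes(map, d)
  arch <- TrueArchitecture("T1", grandMean = 2.5, baseSd = 0.3,
    meanQTL = data.frame(chrom = "I", pos = 20, effect = 0.25, trait = "T1"))
  obs <- simulatePhenotypes(g, arch, d)
  y <- lineStatistic(obs, "T1", "mean")
  grid <- genotypeProbabilities(g, step = 2)
  pk <- findPeaks(cimScan(grid, y), lodMin = 2, traitMean = mean(y))
  expect_equal(pk$percentEffect[which.max(pk$lod)], 20, tolerance = 0.15)
})
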