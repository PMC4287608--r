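# Hotspot-marker additive and pairwise-epistasis ANOVA, FDR, networks.

test_that("a constant phenotype yields zero sums of squares and effects", {
  g <- toyGeno(40, seed = 1)
  y <- setNames(rep(3, 40), lineNames(g))
  res <- additiveAnova(y, g, c("mI_10", "mII_20", "CYTOPLASM"))
  expect_true(all(res$ss < 1e-20))
  expect_true(all(abs(res$effect) < 1e-12))
})

test_that("Type III equals sequential SS on a balanced orthogonal design", {
  # construct a perfectly balanced 2-marker design: all 4 cells equal size
  map <- GeneticMap(c("I", "II"), c("m1", "m2"), c(0, 0))
  cells <- expand.grid(a = c("A", "B"), b = c("A", "B"),
                       rep = 1:8, stringsAsFactors = FALSE)
  al <- as.matrix(cells[, c("a", "b")])
  dimnames(al) <- list(sprintf("L%02d", seq_len(nrow(al))), c("m1", "m2"))
  g <- RILGenotypes(al, rep(c("A_CYT", "B_CYT"), 16), map)
  set.seed(2)
  X <- alleleCodes(g)
  y <- setNames(0.7 * X[, "m1"] - 0.4 * X[, "m2"] + rnorm(32, 0, 0.5),
                lineNames(g))
  res <- additiveAnova(y, g, c("m1", "m2"))
  seqSS <- anova(lm(y ~ X[, "m1"] + X[, "m2"]))[["Sum Sq"]][1:2]
  expect_equal(res$ss[match(c("m1", "m2"), res$term)], seqSS,
               tolerance = 1e-10)
})

test_that("F and p match a from-scratch normal-equations oracle on a small
          fixture", {
  map <- GeneticMap(c("I", "II"), c("m1", "m2"), c(0, 0))
  al <- matrix(c("A","A","B","B","A","B","A","B",
                 "A","B","A","B","B","A","B","A"), 8, 2,
               dimnames = list(sprintf("L%d", 1:8), c("m1", "m2")))
  g <- RILGenotypes(al, rep(c("A_CYT", "B_CYT"), 4), map)
  y <- setNames(c(5.1, 3.2, 4.8, 2.2, 6.0, 2.9, 5.5, 3.1), lineNames(g))
  res <- additiveAnova(y, g, c("m1", "m2"))
  # oracle: explicit least squares and marginal F-tests
  X <- cbind(intercept = 1, alleleCodes(g))
  b <- solve(t(X) %*% X, t(X) %*% y)
  rssF <- sum((y - X %*% b)^2)
  dfRes <- 8 - 3
  for (m in c("m1", "m2")) {
    Xr <- X[, setdiff(colnames(X), m)]
    br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
    ssm <- sum((y - Xr %*% br)^2) - rssF
    Fm <- ssm / (rssF / dfRes)
    pm <- pf(Fm, 1, dfRes, lower.tail = FALSE)
    i <- match(m, res$term)
    expect_equal(res$ss[i], ssm, tolerance = 1e-10)
    expect_equal(res$fStat[i], Fm, tolerance = 1e-10)
    expect_equal(res$p[i], pm, tolerance = 1e-10)
    expect_equal(res$effect[i], unname(2 * b[m, 1]), tolerance = 1e-10)
  }
})

test_that("a pure interaction loads on the product term only, in a balanced
          design, and no three-way terms exist", {
  map <- GeneticMap(c("I", "II"), c("m1", "m2"), c(0, 0))
  cells <- expand.grid(a = c("A", "B"), b = c("A", "B"), rep = 1:6,
                       stringsAsFactors = FALSE)
  al <- as.matrix(cells[, c("a", "b")])
  dimnames(al) <- list(sprintf("L%02d", seq_len(nrow(al))), c("m1", "m2"))
  g <- RILGenotypes(al, rep(c("A_CYT", "B_CYT"), 12), map)
  X <- alleleCodes(g)
  y <- setNames(X[, "m1"] * X[, "m2"], lineNames(g))
  res <- pairwiseEpistasisAnova(y, g, c("m1", "m2"))
  expect_gt(res$ss[res$term == "m1:m2"], 1)
  expect_lt(res$ss[res$term == "m1"], 1e-20)
  expect_lt(res$ss[res$term == "m2"], 1e-20)
  expect_true(all(lengths(gregexpr(":", res$term[grepl(":", res$term)])) == 1))
  # q-values are monotone nondecreasing in p (over defined p-values)
  ok <- is.finite(res$p)
  o <- order(res$p[ok])
  expect_true(all(diff(res$q[ok][o]) >= -1e-15))
})

test_that("pairs with an empty genotype cell are flagged untestable and
          confounded markers are dropped", {
  map <- GeneticMap(c("I", "I", "II"), c("m1", "m1b", "m2"), c(0, 0, 0))
  al <- cbind(m1 = rep(c("A", "B"), each = 10),
              m1b = rep(c("A", "B"), each = 10),
              m2 = rep(c("A", "B"), 10))
  rownames(al) <- sprintf("L%02d", 1:20)
  g <- RILGenotypes(al, rep(c("A_CYT", "B_CYT"), 10), map)
  set.seed(4)
  y <- setNames(rnorm(20), lineNames(g))
  expect_warning(res <- pairwiseEpistasisAnova(y, g, c("m1", "m1b", "m2")),
                 "confounded")
  expect_false("m1b" %in% res$term)
  # force an empty 2x2 cell: m3 = A exactly when m1 = A except never B/B
  al2 <- cbind(m1 = c(rep("A", 12), rep("B", 8)),
               m2 = c(rep("A", 6), rep("B", 6), rep("A", 8)))
  rownames(al2) <- sprintf("L%02d", 1:20)
  map2 <- GeneticMap(c("I", "II"), c("m1", "m2"), c(0, 0))
  g2 <- RILGenotypes(al2, rep(c("A_CYT", "B_CYT"), 10), map2)
  y2 <- setNames(rnorm(20), lineNames(g2))
  res2 <- pairwiseEpistasisAnova(y2, g2, c("m1", "m2"))
  expect_true("m1:m2" %in% attr(res2, "untestable"))
  expect_false("m1:m2" %in% res2$term)
})

test_that("network construction recovers a planted cytoplasm-by-nuclear
          interaction breadth and honours the boundary rule", {
  map <- toyMap()
  d <- DesignSpec(200, seed = 5)
  g <- simulateRILGenotypes(map, d)
  X <- alleleCodes(g)
  z <- ifelse(cytoplasm(g) == "A_CYT", 1, -1)
  set.seed(6)
  results <- lapply(1:20, function(i) {
    y <- if (i <= 6) 0.8 * X[, "mI_20"] * z + rnorm(200, 0, 0.5)
         else rnorm(200, 0, 0.5)
    pairwiseEpistasisAnova(setNames(y, lineNames(g)), g,
                           c("mI_20", "mII_30", "CYTOPLASM"))
  })
  names(results) <- sprintf("T%02d", 1:20)
  net <- buildNetwork(results, edgeMin = 0.10, fdr = 0.05)
  e <- networkEdges(net)
  planted <- e[(e$locus1 == "mI_20" & e$locus2 == "CYTOPLASM") |
               (e$locus1 == "CYTOPLASM" & e$locus2 == "mI_20"), ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$breadth, 0.3, tolerance = 0.15)
  # boundary: breadth exactly at edgeMin is retained
  fake <- lapply(1:10, function(i) {
    data.frame(term = c("A", "B", "A:B"),
               p = c(0.5, 0.5, if (i == 1) 1e-6 else 0.9),
               q = c(0.5, 0.5, if (i == 1) 1e-6 else 0.9),
               ss = 1, df = 1, fStat = 1, effect = 0)
  })
  net2 <- buildNetwork(fake, edgeMin = 0.10)
  expect_equal(nrow(networkEdges(net2)), 1)
  expect_equal(networkEdges(net2)$breadth, 0.1)
})

test_that("an additive architecture produces spurious interactions at about
          the FDR level", {
  map <- toyMap()
  d <- DesignSpec(200, seed = 7)
  g <- simulateRILGenotypes(map, d)
  X <- alleleCodes(g)
  set.seed(8)
  anySig <- vapply(1:40, function(i) {
    y <- setNames(0.5 * X[, "mI_10"] + rnorm(200, 0, 1), lineNames(g))
    res <- pairwiseEpistasisAnova(y, g, c("mI_10", "mII_20", "CYTOPLASM"))
    any(res$q[grepl(":", res$term)] < 0.05, na.rm = TRUE)
  }, NA)
  expect_lte(mean(anySig), 0.12)
})

test_that("interaction degrees and their median match a brute-force recount", {
  nodes <- data.frame(locus = c("a", "b", "c", "d", "e"),
                      breadth = 0.2, nPhenotypes = 2L)
  star <- data.frame(locus1 = "a", locus2 = c("b", "c", "d", "e"),
                     breadth = 0.2, nPhenotypes = 2L)
  net <- new("EpistasisNetwork", nodes = nodes, edges = star, fdr = 0.05,
             edgeMin = 0.1)
  ipl <- interactionsPerLocus(net)
  expect_equal(unname(ipl$degrees["a"]), 4L)
  expect_equal(ipl$median, 1)
  empty <- new("EpistasisNetwork", nodes = nodes, edges = star[0, ],
               fdr = 0.05, edgeMin = 0.1)
  ipl0 <- interactionsPerLocus(empty)
  expect_true(all(ipl0$degrees == 0))
  expect_equal(ipl0$median, 0)
  # random planted networks: recount by looping over edges
  set.seed(9)
  for (rep in 1:5) {
    loci <- sprintf("L%d", 1:6)
    allPairs <- t(combn(loci, 2))
    pick <- allPairs[runif(nrow(allPairs)) < 0.4, , drop = FALSE]
    netR <- new("EpistasisNetwork",
                nodes = data.frame(locus = loci, breadth = 0.5,
                                   nPhenotypes = 1L),
                edges = data.frame(locus1 = pick[, 1], locus2 = pick[, 2],
                                   breadth = 0.5, nPhenotypes = 1L),
                fdr = 0.05, edgeMin = 0.1)
    deg <- interactionsPerLocus(netR)$degrees
    for (l in loci)
      expect_equal(unname(deg[l]), sum(pick == l))
  }
})

test_that("SIF export round-trips edges", {
  nodes <- data.frame(locus = c("a", "b"), breadth = 0.5, nPhenotypes = 1L)
  edges <- data.frame(locus1 = "a", locus2 = "b", breadth = 0.5,
                      nPhenotypes = 1L)
  net <- new("EpistasisNetwork", nodes = nodes, edges = edges, fdr = 0.05,
             edgeMin = 0.1)
  td <- withr::local_tempdir()
  writeNetworkSIF(net, file.path(td, "net"))
  expect_equal(readLines(file.path(td, "net.sif")), "a\tepistasis\tb")
  expect_true(file.exists(file.path(td, "net_nodes.csv")))
})
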