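# Hotspot-marker ANOVA models: additive main-effect model and all-pairwise
# epistasis model with the cytoplasm as an extra single-locus marker,
# Type III sums of squares (car), per-model FDR, and epistasis-network
# construction with a cross-phenotype breadth filter.

# assemble the -1/+1 design columns for the requested loci; for biallelic
# loci this numeric coding IS the sum-to-zero contrast, so car's Type III
# sums of squares are the marginal ones
.markerDesign <- function(geno, markers) {
  X <- alleleCodes(geno)
  cols <- lapply(markers, function(m) {
    if (m == "CYTOPLASM") ifelse(cytoplasm(geno) == "A_CYT", 1, -1)
    else if (m %in% colnames(X)) X[, m]
    else stop("unknown marker: ", m)
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(lineNames(geno), markers)
  out
}

#' Nearest genotyped marker to a map position
#'
#' The marker "most closely associated" with a hotspot: the genotyped marker
#' nearest the hotspot's cM position on its chromosome, ties to the leftmost.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome id(s).
#' @param cM position(s).
#' @return marker id(s).
#' @export
nearestMarker <- function(map, chrom, cM) {
  mt <- markerTable(map)
  mapply(function(ch, p) {
    d <- mt[mt$chrom == ch, ]
    if (!nrow(d)) stop("unknown chromosome: ", ch)
    d$marker[which.min(abs(d$pos - p))]
  }, as.character(chrom), as.numeric(cM), USE.NAMES = FALSE)
}

.dropConfounded <- function(M) {
  drop <- integer(0)
  for (j in seq_len(ncol(M))[-1]) {
    for (i in seq_len(j - 1)) {
      if (i %in% drop) next
      if (all(M[, i] == M[, j]) || all(M[, i] == -M[, j])) {
        drop <- c(drop, j)
        warning(sprintf("marker %s confounded with %s: dropped",
                        colnames(M)[j], colnames(M)[i]))
        break
      }
    }
  }
  if (length(drop)) M[, -drop, drop = FALSE] else M
}

.anovaCommon <- function(y, M, interactions) {
  keep <- is.finite(y)
  y <- y[keep]; M <- M[keep, , drop = FALSE]
  classCounts <- apply(M, 2, function(x) min(table(factor(x, c(-1, 1)))))
  if (any(classCounts < 2))
    stop("fewer than 2 lines in a genotype class at marker(s): ",
         paste(colnames(M)[classCounts < 2], collapse = ", "))
  df <- data.frame(y = y, M, check.names = FALSE)
  terms <- colnames(M)
  untestable <- character(0)
  if (interactions) {
    pairs <- utils::combn(colnames(M), 2, simplify = FALSE)
    for (pr in pairs) {
      cells <- table(M[, pr[1]], M[, pr[2]])
      nm <- paste(pr, collapse = ":")
      if (any(dim(cells) < 2) || any(cells == 0)) {
        untestable <- c(untestable, nm)
      } else terms <- c(terms, nm)
    }
  }
  form <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", colnames(M)), collapse = " + "),
    if (length(terms) > length(colnames(M)))
      paste("+", paste(vapply(strsplit(setdiff(terms, colnames(M)), ":"),
                              function(p) sprintf("`%s`:`%s`", p[1], p[2]), ""),
                       collapse = " + "))
    else ""))
  fit <- stats::lm(form, data = df)
  a3 <- tryCatch(car::Anova(fit, type = "III"), error = function(e) NULL)
  if (!is.null(a3)) {
    rn <- gsub("`", "", rownames(a3))
    tab <- data.frame(term = rn, ss = a3[["Sum Sq"]], df = a3[["Df"]],
                      fStat = a3[["F value"]], p = a3[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
    tab <- tab[!tab$term %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  } else {
    # degenerate residual (zero within rounding): marginal drop-one SS,
    # computed directly; F/p undefined for a saturated fit
    mm <- stats::model.matrix(fit)
    rssFull <- sum(stats::resid(fit)^2)
    dfRes <- fit$df.residual
    asg <- attr(mm, "assign")
    labs <- attr(stats::terms(fit), "term.labels")
    tab <- do.call(rbind, lapply(seq_along(labs), function(ti) {
      keep <- asg != ti
      rssRed <- sum(stats::resid(stats::lm.fit(mm[, keep, drop = FALSE],
                                               y))^2)
      ss <- max(rssRed - rssFull, 0)
      fv <- if (rssFull > 1e-12 * max(ss, 1)) (ss / 1) / (rssFull / dfRes)
            else if (ss > 1e-12) Inf else NA_real_
      data.frame(term = gsub("`", "", labs[ti]), ss = ss, df = 1L,
                 fStat = fv,
                 p = if (is.na(fv)) NA_real_ else if (is.infinite(fv)) 0
                     else stats::pf(fv, 1, dfRes, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  # allelic-substitution effects: 2 x the coefficient on the -1/+1 code for
  # main effects; the raw interaction coefficient for pairwise terms
  cf <- stats::coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  tab$effect <- ifelse(grepl(":", tab$term), cf[tab$term], 2 * cf[tab$term])
  tab$effect[is.na(tab$effect)] <- 0
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  rownames(tab) <- NULL
  attr(tab, "untestable") <- untestable
  tab
}

#' Additive hotspot-marker ANOVA
#'
#' Linear model with the selected hotspot markers (plus "CYTOPLASM") as
#' main-effect terms; Type III sums of squares, two-sided F-tests, BH
#' q-values across the model's terms, and allelic-substitution effects
#' (difference between adjusted class means; positive = A allele increases
#' the phenotype).
#'
#' @param y phenotype values per line (named by line, or aligned with
#'   `lineNames(geno)`); NA lines dropped.
#' @param geno a [RILGenotypes-class].
#' @param markers marker ids; include "CYTOPLASM" to test the organellar
#'   genome as a locus. Confounded (identical) markers are dropped with a
#'   warning.
#' @return data.frame(term, ss, df, fStat, p, effect, q).
#' @export
additiveAnova <- function(y, geno, markers) {
  stopifnot(is(geno, "RILGenotypes"))
  M <- .dropConfounded(.markerDesign(geno, markers))
  if (!is.null(names(y))) y <- y[rownames(M)]
  .anovaCommon(as.numeric(y), M, interactions = FALSE)
}

#' All-pairwise marker epistasis ANOVA
#'
#' The additive model plus every pairwise marker-by-marker interaction
#' (cytoplasm included as a locus, so cytoplasm-by-nuclear interactions are
#' tested). Pairs with an empty 2x2 genotype cell are skipped and listed in
#' the `untestable` attribute. BH FDR is applied within the model across
#' its terms. No three-way terms are fitted.
#'
#' @inheritParams additiveAnova
#' @return data.frame(term, ss, df, fStat, p, effect, q); interaction terms
#'   are named "locus1:locus2".
#' @export
pairwiseEpistasisAnova <- function(y, geno, markers) {
  stopifnot(is(geno, "RILGenotypes"))
  M <- .dropConfounded(.markerDesign(geno, markers))
  if (!is.null(names(y))) y <- y[rownames(M)]
  .anovaCommon(as.numeric(y), M, interactions = TRUE)
}

#' Build the epistasis network across phenotypes
#'
#' Node breadth = fraction of phenotypes for which the locus's main effect is
#' significant (q < `fdr`); edge breadth = fraction with a significant
#' pairwise interaction. Edges with breadth below `edgeMin` are dropped
#' (breadth exactly at `edgeMin` is retained). Deterministic and invariant
#' to phenotype order.
#'
#' @param results named list of per-phenotype [pairwiseEpistasisAnova()]
#'   tables.
#' @param edgeMin minimum interaction breadth, default 0.10.
#' @param fdr per-model significance level on q-values, default 0.05.
#' @return An [EpistasisNetwork-class].
#' @export
buildNetwork <- function(results, edgeMin = 0.10, fdr = 0.05) {
  if (!length(results)) stop("results for at least one phenotype required")
  nPhen <- length(results)
  allTerms <- unique(unlist(lapply(results, `[[`, "term")))
  sigCount <- stats::setNames(numeric(length(allTerms)), allTerms)
  for (res in results) {
    sig <- res$term[res$q < fdr & is.finite(res$q)]
    sigCount[sig] <- sigCount[sig] + 1
  }
  breadth <- sigCount / nPhen
  main <- allTerms[!grepl(":", allTerms)]
  inter <- allTerms[grepl(":", allTerms)]
  nodes <- data.frame(locus = sort(main),
                      breadth = unname(breadth[sort(main)]),
                      nPhenotypes = as.integer(sigCount[sort(main)]),
                      stringsAsFactors = FALSE)
  if (length(inter)) {
    sp <- strsplit(inter, ":", fixed = TRUE)
    edges <- data.frame(locus1 = vapply(sp, `[`, "", 1L),
                        locus2 = vapply(sp, `[`, "", 2L),
                        breadth = unname(breadth[inter]),
                        nPhenotypes = as.integer(sigCount[inter]),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$breadth >= edgeMin, , drop = FALSE]
    edges <- edges[order(edges$locus1, edges$locus2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(locus1 = character(0), locus2 = character(0),
                        breadth = numeric(0), nPhenotypes = integer(0),
                        stringsAsFactors = FALSE)
  }
  new("EpistasisNetwork", nodes = nodes, edges = edges, fdr = fdr,
      edgeMin = edgeMin)
}

#' Interaction degree per locus
#'
#' Number of retained epistatic interactions each locus participates in,
#' and the median over loci (zero-degree loci included).
#'
#' @param network an [EpistasisNetwork-class].
#' @return list(degrees = named integer vector, median = numeric).
#' @export
interactionsPerLocus <- function(network) {
  stopifnot(is(network, "EpistasisNetwork"))
  nodes <- networkNodes(network)$locus
  deg <- stats::setNames(integer(length(nodes)), nodes)
  e <- networkEdges(network)
  if (nrow(e)) {
    t1 <- table(factor(e$locus1, nodes)); t2 <- table(factor(e$locus2, nodes))
    deg <- deg + as.integer(t1) + as.integer(t2)
    names(deg) <- nodes
  }
  list(degrees = deg, median = stats::median(deg))
}

#' Export a network as SIF plus attribute tables
#'
#' Writes `<prefix>.sif` ("locus1 epistasis locus2" lines, readable by
#' standard network viewers), `<prefix>_nodes.csv` and `<prefix>_edges.csv`.
#'
#' @param network an [EpistasisNetwork-class].
#' @param prefix output path prefix.
#' @export
writeNetworkSIF <- function(network, prefix) {
  e <- networkEdges(network)
  sif <- if (nrow(e)) sprintf("%s\tepistasis\t%s", e$locus1, e$locus2)
         else character(0)
  writeLines(sif, paste0(prefix, ".sif"))
  utils::write.csv(networkNodes(network), paste0(prefix, "_nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(e, paste0(prefix, "_edges.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}
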