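# Broad-sense heritability from the line-heritability ANOVA model:
#   y = mu + C (cytoplasm) + G(C) (line within cytoplasm) + E (experiment) + e
# On balanced data, variance components come from equating observed mean
# squares to their expectations (method of moments); unbalanced data fall
# back to REML.

#' Fit the line-heritability model for one phenotype
#'
#' Decomposes the phenotypic variance of a line-level measurement (typically
#' the per-experiment CV or mean of a trait) into organellar (cytoplasm),
#' nuclear (line within cytoplasm), experiment, and residual components, and
#' converts them to broad-sense heritabilities
#' H_nuclear = s2_G / s2_P and H_organellar = s2_C / s2_P with
#' s2_P = s2_C + s2_G + s2_E + s2_e.
#'
#' On a perfectly balanced design (equal lines per cytoplasm class, every
#' line measured equally often in every experiment) the components are
#' method-of-moments solutions of the expected mean squares:
#' s2_G = (MS_G - MS_res) / (r e), s2_C = (MS_C - MS_G) / (r e g),
#' s2_E = (MS_E - MS_res) / (r N), s2_e = MS_res, where r = replicates per
#' (line, experiment) cell, e = experiments, g = lines per cytoplasm class,
#' N = lines. Negative estimates are truncated to 0 and flagged. F-tests:
#' cytoplasm against the line-within-cytoplasm mean square (its proper
#' random-effects denominator), line and experiment against the residual.
#' Unbalanced data are handled by REML (`lme4::lmer`) with a warning; p
#' values are not reported on that path.
#'
#' @param data data.frame(line, cytoplasm, experiment, value), one or more
#'   observations per (line, experiment).
#' @param includeExperiment logical; include s2_E in the phenotypic total
#'   (default TRUE).
#' @return one-row data.frame: varCyto, varLine, varExperiment, varResidual,
#'   h2Nuclear, h2Organellar, fCyto, pCyto, fLine, pLine, fExperiment,
#'   pExperiment, truncated (any component truncated), degenerate, balanced.
#' @export
fitHeritability <- function(data, includeExperiment = TRUE) {
  stopifnot(all(c("line", "cytoplasm", "experiment", "value") %in% names(data)))
  data <- data[is.finite(data$value), ]
  if (!nrow(data)) stop("no finite observations supplied")
  byLine <- tapply(data$cytoplasm, data$line, function(x) length(unique(x)))
  if (any(byLine != 1L)) stop("each line must have exactly one cytoplasm label")
  data$line <- factor(data$line)
  data$cytoplasm <- factor(data$cytoplasm)
  data$experiment <- factor(data$experiment)
  N <- nlevels(data$line)
  e <- nlevels(data$experiment)
  cellN <- table(data$line, data$experiment)
  classN <- table(tapply(as.character(data$cytoplasm), data$line, `[`, 1L))
  balanced <- length(unique(as.vector(cellN))) == 1L && all(cellN > 0) &&
    length(classN) == 2L && length(unique(as.vector(classN))) == 1L

  out <- data.frame(varCyto = NA_real_, varLine = NA_real_,
                    varExperiment = NA_real_, varResidual = NA_real_,
                    h2Nuclear = NA_real_, h2Organellar = NA_real_,
                    fCyto = NA_real_, pCyto = NA_real_, fLine = NA_real_,
                    pLine = NA_real_, fExperiment = NA_real_,
                    pExperiment = NA_real_, truncated = FALSE,
                    degenerate = FALSE, balanced = balanced)

  if (stats::var(data$value) == 0) {  # all observations equal
    out[, c("varCyto", "varLine", "varExperiment", "varResidual",
            "h2Nuclear", "h2Organellar")] <- 0
    if (e < 2L) out$varExperiment <- NA_real_
    out$degenerate <- TRUE
    return(out)
  }

  if (balanced) {
    r <- as.vector(cellN)[1L]
    g <- as.vector(classN)[1L]
    form <- if (e > 1L) value ~ cytoplasm + line + experiment
            else value ~ cytoplasm + line
    an <- stats::anova(stats::lm(form, data = data))
    ms <- stats::setNames(an[["Mean Sq"]], rownames(an))
    df <- stats::setNames(an[["Df"]], rownames(an))
    msRes <- ms[["Residuals"]]
    s2G <- (ms[["line"]] - msRes) / (r * e)
    s2C <- (ms[["cytoplasm"]] - ms[["line"]]) / (r * e * g)
    s2E <- if (e > 1L) (ms[["experiment"]] - msRes) / (r * N) else NA_real_
    out$fCyto <- ms[["cytoplasm"]] / ms[["line"]]
    out$pCyto <- stats::pf(out$fCyto, df[["cytoplasm"]], df[["line"]],
                           lower.tail = FALSE)
    out$fLine <- ms[["line"]] / msRes
    out$pLine <- stats::pf(out$fLine, df[["line"]], df[["Residuals"]],
                           lower.tail = FALSE)
    if (e > 1L) {
      out$fExperiment <- ms[["experiment"]] / msRes
      out$pExperiment <- stats::pf(out$fExperiment, df[["experiment"]],
                                   df[["Residuals"]], lower.tail = FALSE)
    }
    s2e <- msRes
  } else {
    warning("unbalanced design: falling back to REML variance components")
    form <- if (e > 1L)
      value ~ (1 | cytoplasm) + (1 | line) + (1 | experiment)
    else value ~ (1 | cytoplasm) + (1 | line)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data,
                 control = lme4::lmerControl(check.nlev.gtr.1 = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(grp) {
      i <- which(vc$grp == grp)
      if (length(i)) vc$vcov[i] else NA_real_
    }
    s2C <- getv("cytoplasm"); s2G <- getv("line")
    s2E <- if (e > 1L) getv("experiment") else NA_real_
    s2e <- getv("Residual")
  }

  trunc <- function(x) if (is.na(x)) x else max(x, 0)
  out$truncated <- isTRUE(s2C < 0) || isTRUE(s2G < 0) || isTRUE(s2E < 0)
  s2C <- trunc(s2C); s2G <- trunc(s2G); s2E <- trunc(s2E)
  out$varCyto <- s2C; out$varLine <- s2G
  out$varExperiment <- s2E; out$varResidual <- s2e
  s2P <- s2C + s2G + s2e +
    if (includeExperiment && e > 1L && is.finite(s2E)) s2E else 0
  if (s2P > 0) {
    out$h2Nuclear <- s2G / s2P
    out$h2Organellar <- s2C / s2P
  } else {
    out$h2Nuclear <- 0; out$h2Organellar <- 0; out$degenerate <- TRUE
  }
  out
}

#' Heritability of CV (or mean) phenotypes across a population
#'
#' Assembles the per-(line, experiment) CV — or per-(line, experiment) mean —
#' from a [LineCVTable-class], attaches cytoplasm labels from the genotypes,
#' and fits the line-heritability model for every phenotype.
#'
#' @param table a [LineCVTable-class].
#' @param geno a [RILGenotypes-class] supplying cytoplasm labels.
#' @param statistic "cv" (per-experiment CV, the noise phenotype) or "mean"
#'   (per-experiment mean, the average phenotype).
#' @param includeExperiment see [fitHeritability()].
#' @return data.frame with one row per phenotype (phenotype column plus the
#'   [fitHeritability()] columns).
#' @export
heritabilityAcrossPhenotypes <- function(table, geno,
                                         statistic = c("cv", "mean"),
                                         includeExperiment = TRUE) {
  stopifnot(is(table, "LineCVTable"), is(geno, "RILGenotypes"))
  statistic <- match.arg(statistic)
  pe <- perExperimentCV(table)
  cyt <- cytoplasm(geno)
  pe <- pe[pe$line %in% names(cyt), ]
  pe$cytoplasm <- unname(cyt[pe$line])
  pe$value <- if (statistic == "cv") pe$cv else pe$mean
  pe <- pe[pe$defined & is.finite(pe$value), ]
  phens <- sort(unique(pe$phenotype))
  out <- lapply(phens, function(ph) {
    d <- pe[pe$phenotype == ph, c("line", "cytoplasm", "experiment", "value")]
    res <- tryCatch(suppressWarnings(
      fitHeritability(d, includeExperiment = includeExperiment)),
      error = function(err) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(phenotype = ph, stringsAsFactors = FALSE), res)
  })
  do.call(rbind, out)
}

#' @rdname heritabilityAcrossPhenotypes
#' @param result output of `heritabilityAcrossPhenotypes`.
#' @param path output CSV path.
#' @export
writeHeritability <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
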