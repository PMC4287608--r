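# Independent oracles shared across test files.

# expected-mean-squares solution computed from scratch (group means and
# explicit sums of squares; no lm/aov) for the balanced line-heritability
# design: 2 cytoplasm classes x equal lines x experiments x replicates
emsOracle <- function(d) {
  d$line <- as.character(d$line)
  lines <- sort(unique(d$line))
  N <- length(lines)
  exps <- sort(unique(d$experiment))
  e <- length(exps)
  r <- nrow(d) / (N * e)
  g <- N / 2
  gm <- mean(d$value)
  cytOfLine <- tapply(d$cytoplasm, d$line, function(x) x[1])
  cytMeans <- tapply(d$value, d$cytoplasm, mean)
  lineMeans <- tapply(d$value, d$line, mean)
  expMeans <- tapply(d$value, d$experiment, mean)
  ssC <- sum(r * e * g * (cytMeans - gm)^2)
  ssG <- sum(r * e * (lineMeans - cytMeans[cytOfLine[lines]])^2)
  ssE <- sum(r * N * (expMeans - gm)^2)
  ssT <- sum((d$value - gm)^2)
  ssR <- ssT - ssC - ssG - ssE
  msC <- ssC / 1; msG <- ssG / (N - 2); msE <- ssE / (e - 1)
  msR <- ssR / (N * e * r - N - e + 1)
  list(s2G = (msG - msR) / (r * e), s2C = (msC - msG) / (r * e * g),
       s2E = (msE - msR) / (r * N), s2e = msR,
       ss = c(C = ssC, G = ssG, E = ssE, R = ssR, total = ssT))
}

# simulate a balanced line-heritability dataset directly at the line level;
# cytoEffect (if given) plants a fixed reciprocal cytoplasm effect +-c whose
# realized 2-level variance component is 2 c^2
balancedData <- function(n = 40, e = 2, r = 1, s2G = 1, s2C = 0, s2e = 1,
                         cytoEffect = NULL, expEffect = 0, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%03d", 1:n)
  cyt <- rep(c("A_CYT", "B_CYT"), each = n / 2)
  u <- rnorm(n, 0, sqrt(s2G))
  cEff <- if (is.null(cytoEffect)) {
    ce <- rnorm(2, 0, sqrt(s2C)); c(A_CYT = ce[1], B_CYT = ce[2])
  } else c(A_CYT = cytoEffect, B_CYT = -cytoEffect)
  d <- expand.grid(line = lines, experiment = sprintf("E%d", 1:e),
                   rep = seq_len(r), stringsAsFactors = FALSE)
  d$cytoplasm <- cyt[match(d$line, lines)]
  d$value <- u[match(d$line, lines)] + cEff[d$cytoplasm] +
    expEffect * (d$experiment == "E1") + rnorm(nrow(d), 0, sqrt(s2e))
  d
}
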