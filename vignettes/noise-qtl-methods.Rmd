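---
title: "Mapping the genetics of stochastic phenotypic variation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the genetics of stochastic phenotypic variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiseQTL)
```

## The problem

Quantitative genetics usually treats the *mean* of a trait as the phenotype.
This package treats the *within-line stochastic variability* of a trait as a
phenotype in its own right. In a population of recombinant inbred lines
(RILs), every line is (nearly) homozygous, so replicate individuals of one
line are genetically identical; the spread among those replicates measures
stochastic noise, micro-environmental sensitivity, or both. If that spread
differs heritably between lines, there are loci controlling it — variance-QTL
("CV QTL") — which may be entirely different from the loci controlling the
trait mean.

The package implements the full analysis chain for a *reciprocal* RIL
design, in which roughly half the lines carry each parent's maternally
inherited organellar (chloroplast + mitochondrial) genome, so the cytoplasm
acts as one extra biallelic, single-locus marker:

1. per-line, per-experiment coefficient of variation (CV) from replicated
   measurements (`computeLineCV`), with population-level summaries
   (`populationGeneticCV`, `classifyPercentiles`, `cvMeanAssociation`,
   `distributionDiagnostics`);
2. nuclear vs organellar broad-sense heritability from a nested ANOVA
   (`fitHeritability`, `heritabilityAcrossPhenotypes`);
3. composite interval mapping (CIM) of any line-level phenotype — mean or CV
   — by Haley–Knott regression (`genotypeProbabilities`, `selectCofactors`,
   `cimScan`, `permutationThreshold`, `findPeaks`, `percentEffect`);
4. QTL hotspot detection by sliding-window summation with a permutation
   threshold (`windowCounts`, `hotspotThreshold`, `nameHotspots`);
5. additive and all-pairwise epistasis marker ANOVA with the cytoplasm as a
   locus (`additiveAnova`, `pairwiseEpistasisAnova`, `buildNetwork`,
   `interactionsPerLocus`);
6. a structure-preserving permutation null for the whole QTL census
   (`permuteLinks`, `nullQtlCensus`);
7. a simulator whose generating model places line means and line-level
   stochastic SDs under separate, known genetic control
   (`simulateRILGenotypes`, `simulatePhenotypes`, `randomArchitecture`), so
   every stage above is testable by parameter recovery;
8. `runPipeline`/`summarizeRun` tie the stages into one seeded, manifest-writing run.

## The generative model (and why it looks the way it does)

For line $l$ and trait $t$, with marker codes $x \in \{-1,+1\}$ ($A$ allele
$= +1$) and cytoplasm code $z \in \{-1,+1\}$:

$$\mu_{lt} = \mu_0 + \textstyle\sum_j a_j x_{lj} + c_{\mu,t} z_l +
  \sum_{jk} \gamma_{jk} x_{lj} x_{lk}, \qquad
  \log \sigma_{lt} = \log \sigma_0 + \textstyle\sum_j b_j x_{lj} +
  c_{\sigma,t} z_l.$$

An observation in experiment $e$, block $b$ is
$y = \mu_{lt} + E_e + B_b + \sigma_{lt}\,\varepsilon$, $\varepsilon \sim N(0,1)$.

Choices worth noting:

* **±1 allele coding** makes the additive effect $a$ equal half the
  difference between homozygous class means — the allelic-substitution
  convention — so simulator truth, scan effects and ANOVA effects share one
  scale.
* **Log-linear SD.** The line SD is modelled multiplicatively
  ($\sigma > 0$ guaranteed); a vQTL of effect $b$ multiplies the within-line
  SD by $e^{2b}$ between classes. This is the simplest noise model
  consistent with CV being the assayed phenotype. A guard aborts if
  $|\log\sigma|$ exceeds 25.
* **Haldane map function with RIL-by-selfing expansion.** Adjacent-marker
  switch probability $R = 2r/(1+2r)$, $r = (1-e^{-2d/100})/2$. Haldane (no
  interference) composes exactly along a Markov chain, which is what the
  genotype simulator and the flanking-marker probability calculations both
  need; Kosambi does not compose.
* **Experiments and blocks are additive shifts.** Further
  micro-environmental structure is deliberately out of the generative model:
  the assumed randomized complete block design randomizes it away, and the
  structured permutation control (below) exists precisely to detect residual
  structure.
* **Fully inbred lines** ({A,B} only): residual heterozygosity, dominance
  and segregation distortion are not modelled.
* **Observation distribution.** Replicate values default to normal with the
  line-specific SD. Metabolite abundances are arguably lognormal; since
  replicated designs of this kind rarely pin this down,
  `simulatePhenotypes(family = "lognormal")` is exposed, and the CV machinery is agnostic either way.

Default design values reflect the reciprocal-RIL metabolomics design the
package is built around: 316 lines split
158/158 between cytoplasm classes, 2 independent experiments × 2 randomized
complete blocks (every line once per block), a 5-chromosome genome of 90 cM
per chromosome with 5 cM marker spacing (450 cM, 95 markers), hundreds of
metabolite-like traits when trait panels are simulated.

## Per-line CV

CV is computed per (line, experiment, phenotype) as the sample SD
($n-1$ denominator; only duplicates are guaranteed, and the unbiased
variance matters most there) of the *absolute* replicate values divided by
their mean. The per-line noise phenotype is the arithmetic mean of the
defined per-experiment CVs — two experiments give two independent
biological replicate measures of noise, and their mean is used downstream.
Cells with fewer than `minReps` (default 2) replicates, or with
$|\text{mean}| \le$ `meanFloor` (default $10^{-12}\max|y|$ per phenotype,
guarding abundance-like signals bounded away from zero) are *flagged
undefined*, never silently zeroed.

Population-level statistics per phenotype: the genetic ("population") CV of
a line-level statistic is its SD across lines divided by its mean across
lines, computed both for the per-line mean CV and for the per-line mean.
`classifyPercentiles` labels phenotypes by tail membership
(HIGH_CV_LOW_MEAN, LOW_BOTH, HIGH_MEAN_MID_CV, NONE) with each tail holding
$\lfloor n \cdot \text{tail}\rfloor$ phenotypes and ties broken by phenotype
id for determinism. The tail defaults to 0.05 but is a parameter: both 5% and
10th-percentile conventions are common in this kind of analysis, so the
package hard-codes neither.

One intrinsic caveat documented here because it shapes test design: since
$CV = \sigma/\mu$, genetic variation in $\mu$ induces a $1/\mu$ dependence
of CV even when $\sigma$ is under independent control. The independence
properties asserted in the tests therefore use mean effects that are small
relative to the grand mean; with large mean effects a negative CV–mean
correlation is a real feature of the measure, not a bug.

## Heritability decomposition

The line-heritability model for a line-level value $y$ (CV or mean) is

$$y_{cge} = \mu + C_c + G_{g(c)} + E_e + \varepsilon$$

with cytoplasm $C$ (2 levels), line-within-cytoplasm $G(C)$, and experiment
$E$ (random). On balanced data the components are method-of-moments
solutions of the expected mean squares:
$\sigma^2_G = (MS_G - MS_{res})/(re)$,
$\sigma^2_C = (MS_C - MS_G)/(reg)$,
$\sigma^2_E = (MS_E - MS_{res})/(rN)$, $\sigma^2_\varepsilon = MS_{res}$,
where $r$ = replicates per (line, experiment) cell, $e$ = experiments,
$g$ = lines per cytoplasm class, $N$ = lines. Broad-sense heritabilities
are $H_{nuc} = \sigma^2_G/\sigma^2_P$ and $H_{org} = \sigma^2_C/\sigma^2_P$
with $\sigma^2_P$ the sum of all four components. Conventions:

* Negative method-of-moments components are truncated to zero and flagged —
  the standard convention the underlying model statement leaves implicit.
* Cytoplasm is F-tested against the line-within-cytoplasm mean square (its
  proper denominator when lines are random); line and experiment are tested
  against the residual.
* $\sigma^2_E$ is included in $\sigma^2_P$ by default ("total phenotypic
  variance" does not exclude it); `includeExperiment = FALSE` excludes it.
* Unbalanced data fall back to REML (`lme4`), which coincides with the EMS
  solution in the balanced limit (asserted in tests); p-values are not
  reported on that path.
* **Two-level factor estimand.** With one reciprocal pair of cytoplasms
  carrying fixed effects $\pm c$, the quantity the ANOVA component estimates
  is the realized 2-level variance component
  $\sum_i (c_i - \bar c)^2/(k-1) = 2c^2$, not the population variance $c^2$.
  Parameter-recovery tests and the acceptance script define generating
  heritabilities with this convention.

## Composite interval mapping

Scans use Haley–Knott regression on conditional allele probabilities rather
than an EM mixture likelihood: with fully inbred lines and near-complete
marker data the regression approximation is essentially exact, and it
admits clean brute-force oracles (at a genotyped marker the scan reduces
*exactly* to single-marker regression, asserted to $10^{-8}$).

* **Probability grid.** $P(A)$ at each pseudomarker (default step 1 cM; all
  marker positions always included) conditions on the nearest non-missing
  flanking markers through the two-point RIL switch probabilities; beyond
  terminal markers a single flank is used; a fully missing line gets 0.5
  everywhere and is flagged.
* **Cofactors.** Forward regression picks `nCofactors` (default 3)
  background markers by greatest RSS reduction; ties break to map order;
  collinear candidates are skipped and recorded.
* **Scan.** At each position, cofactors within `window` (default 10 cM) on
  the same chromosome are dropped;
  $LOD = (n/2)\log_{10}(RSS_{reduced}/RSS_{full})$, the full model adding
  the expected allele code $2P(A)-1$. The coefficient on that code is the
  additive effect $a$. Degenerate perfect fits
  ($RSS_{full} < 10^{-12} RSS_{reduced}$) are capped at LOD 300 and flagged.
* **Thresholds.** Per-trait permutation thresholds shuffle the phenotype
  across lines; cofactors are reselected inside each permutation by default
  (the statistically correct scheme; a frozen-cofactor fast mode exists).
  The threshold is the type-1 empirical quantile — the
  $\lceil(1-\alpha)B\rceil$-th order statistic — for bit-reproducibility.
  The package also supports the conservative fixed LOD ≥ 2 inclusion rule
  used downstream for census-style counting; both are options everywhere.
* **Peaks.** Local maxima above the threshold; two maxima on one chromosome
  are distinct peaks only if the curve dips ≥ 1 LOD below the smaller
  between them (our concretization of "define peak"). The one-LOD support
  interval is the widest contiguous region around the peak with
  $LOD \ge \text{peak} - 1$, clipped to the chromosome.
* **Percent effect.** Reported as $100\,|2a|/|\bar y|$ — the allelic
  substitution $2a$ relative to the trait mean across lines. Other scalings of
  "percent effect" exist; this conventional allelic-substitution scaling is
  the package's documented choice.

## Hotspots

Each phenotype's peaks are placed on the map; half-open windows
$[c - w/2, c + w/2)$ (width 5 cM, step 1 cM by default) count the number of
*distinct* phenotypes with a peak inside. The permutation null relocates
every peak to a uniform random genome position (per-phenotype peak counts
preserved); several nulls are defensible here, so this declared, seeded
scheme is the package's choice, and the threshold is the type-1
$(1-\alpha)$ quantile of the genome-wide maximum count. Windows strictly
exceeding the threshold are merged when contiguous and named
`PREFIX.CHROM.cM` (Roman-numeral chromosome, position rounded to a cM, tie
to the leftmost maximal window), e.g. `M.CV.II.16`.

Because window counts are integers, the strict-exceedance rate under the
null is conservative by the probability mass tied at the threshold; at the
study-scale configuration used in the tests (434 phenotypes × 3 peaks on a
450 cM genome) the realized rate is ≈ 0.03–0.06 at nominal 0.05. Smaller
peak sets make it markedly more conservative — worth remembering when
applying the hotspot test to small phenotype panels.

## Marker ANOVA and epistasis networks

Hotspot markers (the genotyped marker nearest each hotspot, ties leftmost)
plus `CYTOPLASM` enter a per-phenotype linear model: main effects only
(additive model) or all pairwise products (epistasis model; never three-way
terms). Markers are numerically coded ±1, which for biallelic loci *is*
the sum-to-zero contrast, so `car::Anova(type = "III")` yields the marginal
Type III sums of squares; on balanced data these coincide with sequential
sums of squares (asserted in tests). Pairs with an empty 2×2 genotype cell
are flagged untestable and skipped; identical (confounded) markers are
dropped with a warning.

Multiplicity is controlled in two declared stages: Benjamini–Hochberg FDR
*within each model* across its terms (q < 0.05), then a cross-phenotype
breadth filter — an interaction edge is kept only if significant for at
least `edgeMin` (default 10%, boundary inclusive: exactly 10% is kept) of
the phenotypes. Node breadth is the fraction of phenotypes with a
significant main effect. Networks export as SIF plus node/edge CSV for
standard viewers; `interactionsPerLocus` reports per-locus degree and the
median over loci.

## The structured permutation control

All phenotypes measured on one plant constitute one sample vector. Within
each randomized block, `permuteLinks` reassigns complete vectors to lines
uniformly at random — vectors are never split — so every per-sample
statistic, including the full phenotype–phenotype correlation matrix over
samples, is preserved *bit-identically*; only the line-to-sample (hence
genotype-to-phenotype) link is broken. `nullQtlCensus` re-runs CV
computation and the full scan per permutation and counts significant QTL
(fixed LOD ≥ 2 by default, at reduced scan settings by default; full
fidelity is a switch). A genuine genetic signal shows as an observed count
well above the null maximum; structured technical error would not.

Note that because whole vectors move together, null QTL counts are
*dependent across phenotypes*: when the permuted assignment happens to
align with some marker, many correlated phenotypes can show the same
spurious QTL at once. The null count distribution is therefore
heavy-tailed, and the census needs phenotype panels with diverse genetic
architectures (as real metabolomes have) to separate signal cleanly.

## Problem sizes used in the tests and acceptance script

Simulation-based checks use sizes chosen to give stable Monte-Carlo
estimates at desk scale: type-I error over 100–200 null traits × 100–200
scan permutations at 316 lines (grid step 2 cM); vQTL recovery over 100
traits at $b = \log 1.5$ with 2 experiments × 2 blocks; heritability
recovery over 100 balanced datasets of 316 lines; hotspot self-consistency
over 300–500 simulated peak sets of 434 phenotypes × 3 peaks; the
structured-permutation census at a 10-trait, 80-line demo scale. The
methods themselves carry no built-in limits beyond memory.

## Known limitations

* Percent effects blow up for traits with near-zero means (flagged, not
  fixed); CV phenotypes themselves are protected by the mean floor.
* The hotspot permutation null (uniform relocation) ignores marker-density
  and linkage structure; thresholds from other null schemes will differ.
* The heritability decomposition assumes one level of replication inside
  experiments; block is absorbed into the residual.
* The cytoplasm component rests on 1 degree of freedom; its per-trait
  estimates are noisy and only population-level patterns are meaningful.
* No dominance, residual heterozygosity, segregation distortion, or map
  estimation from genotypes; the map is an input.
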