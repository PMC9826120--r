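---
title: "Models and methods behind methylTSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylTSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methylTSD` analyses reduced-representation bisulphite sequencing
(RRBS) counts from hatchlings of a species with temperature-dependent
sex determination and builds sparse methylation-based predictors of
sex and past incubation temperature. This vignette explains the models
the package fits, the assumptions they make, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## The data model

Every quantity in the package derives from a locus-by-sample table of
count pairs: at CpG locus $i$ in sample $j$, $n_{ij}$ aligned reads of
which $m_{ij}$ are methylated. `MethylomeSE` stores the pair as two
integer assays over a `GRanges` of width-1 plus-strand CpG positions.
Internally all coordinates are 0-based half-open; the bismark coverage
reader converts from its 1-based inclusive convention at the boundary,
so no other code ever shifts coordinates. Reads covering the two
strands of one CpG are merged to the plus-strand C before assembly;
with a reference CpG index the assignment is exact, without one an
adjacent-position heuristic pairs $(p, p+1)$ greedily (exact whenever a
plus-strand call is present and CpGs are $\ge$ 3 bp apart, which holds
for the simulator's output).

When samples are assembled into a matrix the default locus policy is
*union*: a locus absent from a sample is a missing cell, and retention
is decided by the downstream coverage filters rather than by the
assembly step. This mirrors the `min.per.group` semantics of the
standard RRBS toolchain, and keeps assembly order-invariant.

## Site filtering

Filters run in a fixed order, each recorded in an audit log:

1. **Extreme coverage** (`topCoveragePct = 99.9`): per sample, cells
   above the sample's 99.9th coverage percentile (type-7 linear
   interpolation, the common default) become missing — very high
   coverage at reduced-representation loci is dominated by PCR
   duplicates. The threshold is a quantile of the current data, so
   this trim is a run-once operation: re-applying it would trim the
   new tail again. The remaining filters are idempotent.
2. **Group coverage** (`minCov = 5`, `minPropPerGroup = 0.5`): a locus
   is kept only if, in *every* temperature-sex cell, at least half the
   samples have $\ge 5$ reads (boundary inclusive).
3. **Normalisation**: sample coverage is scaled to the median of
   per-sample median coverages; methylated counts are scaled by the
   same factor and clamped, preserving each cell's percent methylation
   within $1/n_{ij}$.
4. **Constitutive methylation** (`hyperCut = 95`, `hypoCut = 5`,
   strict inequalities): loci >95% or <5% methylated in all samples
   carry no contrast information and inflate the test count.
5. **Near-zero variance** (`freqCut = 19`, `uniqueCut = 10`): the
   caret-style rule on percent values compared at 4-decimal precision;
   all-constant loci are removed unconditionally.

## The differential-methylation test

Counts are modelled per locus as binomial with a logit link on a
binary group indicator. With one binary covariate the maximum
likelihood estimates are the pooled per-group proportions, so the
likelihood-ratio statistic has a closed form — the implementation is a
vectorised identity, verified in the tests against a brute-force
numerical likelihood oracle. Biological replicates are overdispersed
relative to the binomial (replicate-level variation in the true
methylation proportion), so the statistic is corrected by the Pearson
dispersion of the full model, $\hat\varphi = \sum_j r_j^2/(J-2)$ over
the $J$ samples with positive coverage, applied only when
$\hat\varphi > 1$.

**Reference distribution.** The corrected statistic is referred to
$F(1, J-2)$ by default rather than $\chi^2_1$. The dispersion is a
plug-in estimate from 6–22 residual degrees of freedom; treating it as
known (the $\chi^2$ convention) makes the ratio's tails far heavier
than $\chi^2_1$ and, at this study's sample sizes, produces large
numbers of spurious BH discoveries in an all-null beta-binomial
simulation, concentrated in the 8- and 16-sample contrasts. The $F$
reference accounts for the estimate's sampling noise in exactly the
way a quasi-likelihood analysis does, and restores near-nominal
behaviour (the null-calibration test in the acceptance suite measures
this). `reference = "chisq"` keeps the other convention available.

The five study contrasts — all females vs all males, the within-34.5 °C
sex contrast, and three pairwise temperature contrasts — are each
BH-adjusted separately (plain step-up BH; the q-value/slim variants are
deliberately not used since the procedure is specified as
Benjamini–Hochberg). Classification applies *sex precedence*: loci
significant (strict $q <$ 0.1) in either sex contrast are
sex-associated (universal if significant in the all-female-vs-all-male
contrast), and only non-sex loci significant in a temperature contrast
are temperature-associated. In this design low and intermediate
temperatures produce single-sex clutches, so temperature contrasts are
confounded with sex; the precedence rule purges that confounding from
the temperature set. A consequence worth knowing: the classified DMC
set pools five separately-controlled BH families, so its union-level
false-discovery rate is intrinsically above the per-family 10% even
for a perfectly calibrated test. The acceptance suite measures both
quantities.

**Directions.** Sex DMCs are female- or male-biased by the sign of the
pooled female-minus-male difference; temperature DMCs are positive or
negative with temperature using the most significant temperature
contrast (differences are computed lower minus higher temperature, so
a negative difference means methylation rises with temperature).

## Imputation and correlation screens

Correlation and prediction analyses need a complete percent matrix.
`knnImpute` fills missing cells with the mean over the $k = 10$
nearest loci (Euclidean distance over jointly observed samples,
normalised per shared sample), falling back to the locus mean when
more than half a locus's samples are missing, matching the common KNN
imputation contract. Spearman screens use average ranks with the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; constant loci are
flagged rather than given a coefficient. Locus-set comparisons of
$|\rho|$ use the two-sided Mann–Whitney test, exact when both sets
have at most 8 values and tie-corrected normal otherwise.

## Genome annotation

CpG islands are predicted with the classic sliding-window rule: a
100-bp window every base pair, GC% $\ge$ 50 and observed/expected CpG
$\ge$ 0.6, where O/E $= N_{CG}\cdot\mathrm{len}/(N_C N_G)$ (zero when
either count is zero; N bases count as neither and break CG
dinucleotides). A position is an island candidate when at least one
covering window passes, and candidate runs of $\ge$ 200 bp are
islands. The original EMBOSS tool smooths window scores over ten
windows instead; the covering-window rule is this package's normative
definition, and an exhaustive per-position oracle in the test suite
pins it down exactly. Shores are the ±2-kb flanks of islands, shelves
the ±2-kb flanks of shores, everything else open sea; the four classes
partition each scaffold, with precedence island > shore > shelf for
loci.

Gene context uses promoter > exon > intron > intergenic precedence.
The annotation itself does not define a promoter, so the package uses
a TSS window of −1000/+200 bp (strand-aware) — a common convention,
exposed as parameters, and worth remembering when interpreting
promoter enrichment, which is sensitive to it. Nearest genes use
half-open gap distances (0 inside a gene span) with equidistant ties
resolved by lower gene start then lexicographic id. Density tiles are
non-overlapping 1-kb windows binned at 20 CpG/kb. Mean-methylation
bins are right-closed 20-point bins with 0 in the first bin.
Enrichment of a DMC set against the covered-CpG background (with the
DMCs excluded from the background, per the study's $N - n_{DMC}$
convention) uses two-sided Fisher exact tests with BH adjustment
across categories; zero-margin tables report $p = 1$ with an undefined
odds ratio.

## Hormone-response-element scanning

JASPAR count matrices become log2-odds PWMs with a total pseudocount
of 0.8 per position distributed by the background (genome base
composition by default, uniform as an option). The score threshold for
a target p-value (the study's $2\times10^{-6}$) comes from the exact
score distribution under the background model, computed by dynamic
programming over scores discretised to 0.01 log2 units and restricted
to achievable scores; the scanner evaluates windows on the same grid,
so the attained tail probability describes the scan exactly (the
random-sequence hit-count test in the suite checks this calibration).
Both strands are scanned, N-containing windows skipped, minus-strand
hits reported at plus-strand coordinates, and opposite-strand
overlapping hits both kept. Proximity analysis reports the proportion
of loci within 1, 2.5 and 5 kb of a hit (loci on hit-free scaffolds
beyond every cutoff) with Fisher comparisons against the covered-CpG
background.

## Sparse predictors

Predictors are elastic-net fits (α = 0.5) on the imputed percent
matrix over candidate loci: binomial logistic for sex, gaussian for
temperature. Candidates are the intersection of loci differentially
methylated for the target within the training samples at a stringent
FDR of 5% and loci in the corresponding full-data DMC class — the
study's two-stage screen. λ is chosen to minimise the cross-validated
mean error over 5 seeded folds (stratified by class for the binomial
model), at the minimum rather than the 1-SE rule, since the selection
rule is specified as minimising the error. For the binomial model the
CV error is the mean squared error on probabilities by default (the
stated selection criterion), with deviance as an option. Features are
standardised internally and coefficients reported back on the
percent-methylation scale, so `predictSparse` needs only the stored
coefficients. Evaluation reports accuracy at the 0.5 cutoff with
per-class mean ± SE of predicted probabilities (binomial), and MAE
plus the coefficient of determination $R^2 = 1 - SS_{res}/SS_{tot}$
(gaussian) — the latter definition so that a constant predictor scores
$\le 0$. The train/test split draws one random test sample per
temperature-sex cell (4 of 24; a half/half scheme is available), and
imputation is performed jointly on train and test by default — the
held-out samples' phenotypes are never used, only their methylation,
matching the study's workflow; callers wanting strict separation can
impute the training matrix alone and pass both matrices explicitly.

## Cross-tissue comparison and the reaction norm

The gonad data set (sex unknown at sampling) reuses the same filtering
and testing machinery with all pairwise temperature contrasts among
its temperatures. Comparisons run strictly on the loci covered in both
tissues after each tissue's own filtering: a Fisher test of DMC
proportions and per-context Fisher tests against the shared background
excluding each tissue's DMCs. The temperature-by-sex-ratio reaction
norm is a grouped-binomial logistic fit with a quadratic temperature
term; temperature is centered before fitting to stabilise the
quadratic term and the coefficients are back-transformed, with the
covariance mapped through the corresponding Jacobian. Perfect
separation (e.g. all-female data) is flagged rather than hidden.

## The synthetic-data generator

The generator emulates the study conditions so that every stage of the
pipeline can be exercised and verified: the 8F@30 °C, 8M@33.5 °C,
4F+4M@34.5 °C design over five clutches; negative-binomial coverage
with mean 30 and size 8 (zero coverage becomes a missing cell);
baseline methylation from a three-component mixture — Beta(0.5, 10)
hypomethylated, Uniform(0.2, 0.8) intermediate, Beta(10, 0.5)
hypermethylated with weights 0.25/0.25/0.5 — giving the bimodal
methylome that makes the constitutive filter meaningful; beta-binomial
counts with intra-locus correlation ρ = 0.05 (a typical replicate-level
overdispersion for RRBS); clutch random intercepts of SD 0.3 logits;
and lognormal hormones with a subtle sex offset for oestradiol
(meanlog 3.4 vs 3.2, sdlog 0.5), so that the sex difference sits near
the detection threshold as in the blood study. Planted sex effects
start from a hypermethylated baseline (0.8–0.95) and shift one sex by
−2.5 logits toward intermediate methylation — the observed pattern for
sex-associated loci — with 30% of them expressed only at 34.5 °C to
reproduce the high-temperature-specific sex DMCs; temperature effects
are ±0.6 logit/°C linear slopes. Defaults are the study conditions;
they are constructor arguments, not tuning knobs.

What the generator does **not** emulate: read-level artefacts
(bisulphite conversion error, mapping bias, strand-coverage asymmetry
beyond a symmetric binomial split), linkage between neighbouring CpGs
(loci are independent given the sample effects), genuine genomic
CpG spatial structure when run without a simulated genome, and
cell-composition heterogeneity. Passing recovery tests therefore shows
the pipeline is correct and well calibrated under the count model the
analysis itself assumes — it does not certify performance on real
blood methylomes, where effect sparsity and dependence structures
differ.

## Problem sizes and numerical notes

The test and acceptance suites run at desk scale, chosen so the whole
suite completes in a few minutes: null calibration uses 20 replicates
of 5000 loci × 24 samples, null-contaminated FDR measurement 20 × 3000
loci, recovery and prediction 4000 loci, oracle comparisons 50 loci or
≤5-kb sequences, PWM enumeration up to width 8. Degenerate inputs are
defined rather than left to chance: 0·log 0 = 0 in the likelihood,
zero-variance Pearson cells contribute zero residual, $J \le 2$
disables the dispersion estimate, empty contrast sides and all-missing
samples are errors, constant loci are flagged in correlation screens,
and zero-margin Fisher tables give $p = 1$.
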