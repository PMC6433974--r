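---
title: "Constrained PCA with gene-environment interactions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained PCA with gene-environment interactions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcage)
```

## The scientific problem

Children born very preterm (< 32 weeks gestation) accumulate early-life
stressors in the neonatal intensive care unit — repeated invasive
procedures, mechanical ventilation, infection, surgery, opioid exposure —
during a period of rapid brain development. `cpcage` implements a
constrained principal component analysis (CPCA) that asks how much of the
variance in 26 subcortical brain volumes at school age (13 structures per
hemisphere: hippocampal subfields CA1, subiculum, CA4/dentate gyrus,
CA2/CA3 and stratum; the alveus, fimbria, fornix and mammillary bodies;
amygdala; striatum, globus pallidus and thalamus) is attributable to seven
neonatal clinical factors (NCF), total brain volume and three candidate
genotypes (BDNF Val66Met, SLC6A4 5HTTLPR, COMT Val158Met), and to
clinical-factor-by-genotype interactions — and whether the resulting
components relate to cognitive, behavioral and visual-motor outcomes.

## The model

CPCA is a two-step procedure.

**External analysis.** Let $Z$ be the $N \times 26$ column-standardized
volume matrix, $X_m$ the $N \times 11$ standardized main-effect block
(7 NCF + total brain volume + 3 genotype codes) and $X_i$ the
$N \times 24$ standardized interaction block (8 predictors $\times$ 3
genotype codes; each column is the elementwise product of a standardized
predictor and a 0/1 genotype code, re-standardized). Multivariate least
squares partitions $Z$ hierarchically:

$$M_1 = P_{X_m} Z, \qquad M_2 = P_{X_i^{\perp}} (Z - M_1), \qquad
  E = Z - M_1 - M_2,$$

where $P_X$ is the orthogonal projector onto the column span of $X$ and
$X_i^{\perp}$ is the part of $X_i$ orthogonal to $X_m$. The three parts are
mutually orthogonal and sum to $Z$ exactly, so the squared Frobenius norms
partition the total variance.

The hierarchical (sequential) ordering is a deliberate design choice: it
makes the interaction space orthogonal to the main-effect space, which in
turn makes the extracted interaction component exactly uncorrelated with
the main components — the orthogonality the analysis asserts about PC1,
PC2 and PC NCFxG. Simultaneous entry (joint regression with attribution by
coefficient block) is available via `external_analysis(entry =
"simultaneous")`, but then the predicted blocks are no longer orthogonal
and the orthogonality guarantee is lost; it is provided for sensitivity
analysis only.

**Internal analysis.** Each predicted matrix is decomposed by SVD,
$M = U D V^{\top}$. By default two components are retained from $M_1$
(PC1, PC2) and one from $M_2$ (PC NCFxG); the retention counts are
configurable. Component scores are the predicted-space subject scores
$t_c = M v_c = u_c d_c$ — because these lie inside their block's span,
main and interaction scores are orthogonal to machine precision.
*Component loadings* are Pearson correlations between each standardized
region volume and each score vector; *predictor loadings* are correlations
between design columns and scores. Every component is oriented so that the
sum of its 26 region loadings is non-positive, matching the convention in
which components that track adversity load negatively on volumes.

**Variance table.** The total variance is the sum of the column variances
of $Z$ with $N-1$ accounting. For each retained component the table
reports (i) the variance of $Z$ along the component direction,
$\lVert Z v_c\rVert^2/(N-1)$, and (ii) the variance explained by the
predictors, which is the predicted-matrix eigenvalue
$d_c^2/(N-1)$ — equivalently the variance of the component's scores
attributable to the design span, since $P_{X_m} Z v_c = M_1 v_c$. Overall
rows use $\lVert M_1\rVert^2/(N-1)$ and $\lVert M_2\rVert^2/(N-1)$.
Percentages are always 100 times a variance cell divided by the total, and
"combined" cells are sums over retained components; these identities are
enforced by tests. The distinction between (i) and (ii) is what lets a
component's total variance exceed the part its predictors explain, as in
the published variance decomposition this table mirrors.

### The standardization convention

Loadings are correlations, so the scale of $Z$ is irrelevant to them, but
the variance table depends on how columns are scaled. With $p$ columns
scaled by the population (denominator-$N$) standard deviation and variance
accounted with $N-1$, the total variance is exactly $p\,N/(N-1)$ — for 26
regions and 57 subjects, $26 \times 57/56 = 26.46$, which reproduces the
published total. This is therefore the default
(`standardization_convention("population")`); sample-SD scaling (total
variance exactly $p$) is available. The convention is recorded in the fit
and reused, with the stored centers and scales, on every bootstrap
resample.

### Genotype coding

Minor alleles are coded 1 against a homozygous-major reference. Defaults
mirror the grouped presentation of the genotype distribution: carrier
coding for BDNF (Val/Met + Met/Met vs Val/Val) and SLC6A4 (S-carriers vs
L/L), recessive coding for COMT (Met/Met vs the rest, the Met/Met group
being the one the interaction findings single out). Carrier, recessive and
additive codings are selectable per gene; additive coding of a grouped
input category is refused rather than guessed.

## Bootstrap inference

Loading uncertainty comes from a case-resampling bootstrap: whole subject
rows are drawn with replacement and the entire pipeline —
re-standardization, both analyses, loadings — is re-run per resample
(default $B = 1000$). Because principal components are defined only up to
order and sign, every replicate is aligned to the point estimate by greedy
matching on absolute Tucker congruence of region-loading vectors followed
by sign flips; replicates whose best congruence is below 0.3 are counted
as alignment failures. Resamples that produce a constant design column
(e.g. a resample with no infected subjects in a genotype subgroup) are
discarded and counted; more than 20% discarded aborts inference.
Rank-deficient (but non-constant) resampled designs are projected
minimum-norm rather than discarded, matching the reference path.

Per loading the package reports the percentile confidence interval and a
two-sided p-value. Two estimators are provided:

* **percentile** (default): the sign-crossing probability with a +1
  continuity correction on both tails,
  $p = \min\!\big(1, 2\min(\#\{r \le 0\}+1, \#\{r \ge 0\}+1)/(B+1)\big)$.
  It can never be exactly zero, so vanishing p-values are reported as
  $2/(B+1)$ rather than 0.
* **normal**: $2\Phi(-|\hat\theta|/\widehat{\mathrm{sd}}(r))$ from the
  replicate standard deviation.

Validation on null-interaction cohorts shows a real difference between
them: the percentile estimator is *conservative* for loadings of a
component that is pure noise (its replicate distribution straddles zero by
construction, so small p-values are essentially never produced), while the
normal estimator is close to nominally calibrated (raw $p<0.05$ fraction
near 5%). The test suite asserts both behaviours: conservatism of the
default, calibration of the normal method. For calibrated error rates use
`p_method = "normal"`; the percentile default errs on the safe side.

Multiplicity is adjusted within each reported family separately — each
component's 26 region loadings, each component's main-effect predictor
loadings, the 24 interaction loadings — by Benjamini-Hochberg at $q =
0.05$ (flags) and Bonferroni (reported alongside), mirroring the per-table
FDR columns of the published loading tables. Seeds for replicate $b$ are
derived deterministically from the master seed and $b$, so results are
independent of execution order, and increasing $B$ never changes point
estimates.

## Brain-behavior correlations

Component scores are correlated (Pearson) with ten outcomes: WISC-IV VCI,
PRI, WMI and PSI; CBCL internalizing and externalizing T-scores; BRIEF
GEC; and the Beery VMI, Visual Perception and Motor Coordination scores.
Cells use pairwise-complete observations with the cell N disclosed;
p-values come from the t transform with $N-2$ df and are reported raw (an
optional BH column exists behind `adjust = TRUE`), matching the published
presentation. A zero-variance outcome yields `NA`, never a fabricated 0.

## The synthetic cohort generator

The study's data are not public, so `simulate_cohort()` generates cohorts
with the statistical structure the analysis assumes, at the published
summary values:

* **Clinical factors.** GA is truncated normal on 24--32 weeks (centre
  29.5, SD 3); invasive procedures and ventilation days are negative
  binomial (means 95 and 12) linked to GA through a shared-factor Gaussian
  copula with latent correlation $-0.6$; infection is Bernoulli(0.246);
  surgeries are negative binomial with about 21% of subjects having at
  least one; SNAP-II is a rounded gamma; morphine is zero-inflated
  lognormal. Families were chosen to match the published medians, IQRs and
  prevalences qualitatively — only those summaries are published, so the
  full joint distribution is the package's own choice.
* **Genotypes** are i.i.d. Hardy-Weinberg draws at minor-allele
  frequencies back-solved from the published genotype counts: BDNF Met
  0.184, 5HTTLPR S 0.504, COMT Met 0.455.
* **Volumes** follow a planted low-rank linear model on the standardized
  scale: a rank-2 main-effect coefficient matrix (component 1: more
  invasive procedures, ventilation, infection and illness severity, lower
  GA and smaller total brain volume reduce amygdala, thalamus, basal
  ganglia and tract volumes; component 2: surgeries and morphine reduce
  hippocampal subfield volumes) plus a rank-1 interaction pattern
  (invasive-procedures x COMT, GA x COMT, infection x BDNF, surgery x
  BDNF acting on right-hemisphere subfields and alveus), plus Gaussian
  noise (default SD 0.8 on the standardized scale), mapped to plausible
  mm^3 using per-structure means. The planted component scores are
  orthogonalized — the second main score against the first, the
  interaction score against the whole main-effect span — so the planted
  structure has exactly the geometry the engine estimates and is
  identifiable; the planted truth (coefficients, unit directions on the
  analysed scale, scores) is returned for recovery checks.
* **Outcomes** are linear in the planted component scores with the
  interaction component given the largest weights (working memory,
  processing speed, externalizing behavior, executive function), plus
  noise, then mapped to conventional score scales (WISC mean 100/SD 15,
  T-scores, Beery standard scores).

Two generator behaviours deserve emphasis. First, seeds: one master seed
with deterministically derived per-block child seeds, so adding a block
never perturbs earlier draws and identical parameters are bit-identical.
Second, identifiability: with a recessive COMT code, a draw with too few
Met/Met homozygotes makes the nine COMT design columns linearly dependent
(nothing can estimate an interaction in an empty cell); such draws are
rejected and regenerated under a derived child seed. Cohorts smaller than
the design width (35 columns) are exempt — they are fixtures, not
analysable designs.

What the generator does *not* emulate: MRI segmentation error, site or
scanner effects, non-linear dose-response, outcome floor/ceiling effects,
and informative missingness. Passing tests on synthetic cohorts therefore
demonstrate the correctness and calibration of the *method*, not the
reproduction of the study's substantive findings, which depend on private
data.

## Numerical choices and degenerate inputs

* Projections use pivoted QR; rank-deficient designs are projected
  minimum-norm with a warning (reference path) or silently (bootstrap
  resamples, where deficiency is routine).
* Constant columns are an error in `standardize()` (named), a
  degenerate-design error in `build_design()`, and a counted discard in
  the bootstrap.
* Component order ties and sign ties break toward a negative first
  element; monomorphic genotype samples make `hwe_chisq_test()` return
  chi-square 0, p 1 with a degeneracy flag.
* The complete-case rule governs predictors and volumes (excluded
  subjects are listed in the fit and manifest); outcome missingness is
  handled pairwise per correlation cell.
* Optional log1p transforms for skewed exposures (invasive procedures,
  morphine) exist behind `log_transform=`; the default is off, since the
  original analysis does not state any transform.

## Problem sizes used in validation

The test suite validates the pipeline at the cohort size the study used
(N = 57) for structural, orthogonality and determinism properties; at
N = 200 with noise SD 0.1 for parameter recovery (20 seeds, Tucker
congruence at least 0.95) and for bootstrap coverage (300 simulation
replicates, B = 500, against population loadings approximated once at
N = 20000); and with 500 null-interaction simulations at B = 300 for
error control. These sizes were chosen so that each property is measured
with enough replication to be stable while remaining desk-scale.

## Known limitations

* The bootstrap treats the retained component count as fixed; no
  inference is made about k itself.
* Percentile p-values are conservative for null components (see above).
* The variance attribution of a component to predictors follows the
  projected-score construction described here; other attributions (e.g.
  commonality analysis) are out of scope.
* The residual space E is emitted but not interpreted.
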