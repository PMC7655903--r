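---
title: "Genomic versus pedigree evaluation in a clonally replicated breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic versus pedigree evaluation in a clonally replicated breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgs)
```

## The problem

Tree breeding programs evaluate candidates by best linear unbiased
prediction (BLUP) of breeding values. Classically the covariance among
candidates comes from the recorded pedigree (the numerator relationship
matrix **A**); genomic evaluation replaces it with a marker-derived
relationship matrix **G**. The two agree in expectation, but **G** sees
two things **A** cannot: errors in the crossing records, and the
Mendelian-sampling differences that distinguish full sibs. This package
implements the full comparison pipeline for a clonally replicated
population -- about two dozen parents crossed in a factorial plus
pair-mating design, giving ~35 full-sib families of very unequal size
(11 to 118, ~1,000 offspring), each genotype cloned into six complete
blocks of a field trial -- together with a synthetic-data generator that
reproduces that structure so every stage can be validated against known
truth.

## Models

### Single-trait BLUP

On adjusted clonal means $y$ the models are

$$y = B\beta + Zu + \varepsilon, \qquad
  y = B\beta + Zu + Wd + \varepsilon,$$

with $u \sim N(0, K\sigma_a^2)$ for a relationship matrix $K$ (pedigree
**A** or genomic **G**), optional dominance $d \sim N(0, D\sigma_d^2)$,
and i.i.d. residuals. The fixed part is an intercept: responses are
already spatially adjusted clonal means. Heritability is reported on
that scale, $h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_d^2 +
\sigma_e^2)$, and model quality by $\mathrm{AIC} = -2\log L_{REML} +
2k$ where $k$ counts estimated (co)variance parameters, residual
included; fixed effects are not counted (a convention -- only
differences within a trait matter).

`fit_reml()` offers two algorithms. The `"eigen"` path (single random
term) profiles the restricted likelihood over the variance ratio after
one eigendecomposition; it is exact and fast, and is what the
cross-validation loops use. The `"em"` path is EM-REML on Henderson's
mixed-model equations with a guarded Aitken acceleration (accelerated
steps are only accepted when they do not decrease the restricted
likelihood, so the EM monotonicity property -- which the tests assert --
is preserved). Variances are floored at $10^{-8}\,\mathrm{var}(y)$
rather than allowed to go negative; a fit that touches the floor is
flagged. Convergence requires both a relative log-likelihood change
below `tol_logl` (default 1e-8) and relative variance changes below
`tol_var` (default 1e-6), within `max_iter` (500). When the likelihood
is flat in the additive/residual split (the degenerate $K = I$ case)
the eigen path resolves the tie toward $\sigma_a^2 = 0$, the
conservative answer.

### Relationship matrices

The genomic matrix follows VanRaden's centered cross-product with an
explicit trace normalization,

$$G = \frac{(M - P_1)W_a(M - P_1)'}{\mathrm{trace}[(M - P_1)W_a(M -
P_1)'] / n},$$

so $\mathrm{trace}(G)/n = 1$ exactly -- the scaling used for
compatibility with **A** -- and the dominance analogue uses the
heterozygosity indicator against $2p_iq_i$. Allele frequencies default
to those observed in the genotyped set; an explicit base-population
frequency vector can be supplied (the simulator records its true
sampling frequencies, and the expectation tests use them, since
frequencies re-estimated from a small, related sample bias realized
relationships downward by ~10%). Missing dosages are mean-imputed
before construction. `regularize()` shrinks any matrix toward the
identity, $(1-\epsilon)K + \epsilon I$, which is how the pipeline
guarantees invertibility before mixed-model equations or back-solving;
$\epsilon$ between 1e-8 and 1e-4 is used throughout and is far below
any biological signal.

### Weighted G-BLUP

Marker effects are recovered from GEBVs by
$\hat u_a = W_a X' G^{-1} \hat g$ (with $X$ the same centered coding
that built $G$; the reconstruction $X\hat u_a / c$, where $c$ is the
trace constant, returns $\hat g$ exactly -- a round-trip the tests
check). Weights are squared effects, $w_j = \hat u_j^2$, rescaled to
mean 1 so the trace-normalized matrices stay comparable across
iterations; the scale of the weights is otherwise arbitrary, and the
rescaling convention is this package's choice. Three iterations
(Gw1..Gw3) are run by default, starting from identity weights (so
iteration 0 *is* plain G-BLUP, another exact identity in the tests).
Dominance weights are only formed when the model includes dominance.

### Multi-trait REML

The additive multi-trait model $u \sim N(0, G_0 \otimes K)$, $e \sim
N(0, R_0 \otimes I)$ with unstructured $G_0, R_0$ is fitted by EM. For
complete trait matrices the mixed-model equations block-diagonalize in
the eigenbasis of $K$ (one $t \times t$ block per eigenvalue, bordered
by the intercepts), so an iteration costs $O(n\,t^3)$; this path is
verified in the tests against direct optimization of the dense-matrix
restricted likelihood. With per-trait missing values the general
equations are used and the residual covariance is updated trait-pairwise
over the individuals observed for both traits -- exact EM for complete
data, the standard practical approximation otherwise. Covariance
updates that leave the positive-definite cone are bent back by
eigenvalue flooring and flagged (`bent`), as is any genetic correlation
estimated at its boundary.

## Spatial adjustment

Field observations are adjusted per trait with
$y = \mu + g + s + \varepsilon$: a genetic effect with pedigree
covariance **A**, and a spatial surface $s$ expressed in a
tensor-product cubic B-spline basis (knots equally spaced per axis; $k$
knots give $k+2$ basis functions, and every basis row sums to one) with
i.i.d. random coefficients, one common variance, nested within trial.
The genetic term uses **A** alone -- a deliberate simplification of
blended pedigree/genomic single-step matrices, which are out of scope
here. Knot pairs are searched over a grid (default $\{4,6,8,10\}^2$)
and chosen by REML-based AIC; whether the original knot searches used
ML or REML likelihoods is not documented anywhere authoritative, so the
REML convention is used and stated. The fitted surface is centered
within trial before subtraction (its level is absorbed by the
intercept), and adjusted clonal means are plain means of
surface-subtracted plots over the retained blocks -- all six by
default, or a subset such as blocks 1, 3, 5 for the degraded-phenotype
comparison.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Pedigree**: any cross table; the shipped
  `poplar_family_counts.csv` encodes the published 35-family table
  (1,011 offspring, sizes 11-118) and `factorial_design()` /
  `pair_design()` build the constituent mating designs.
* **Genomes**: founders drawn in Hardy-Weinberg proportions at
  frequencies uniform on a MAF range (default 0.05-0.5) over 19
  chromosomes (the poplar karyotype) of 25 Mb; gene dropping with
  Poisson crossovers (default 0.04/Mb, i.e. a ~100 cM chromosome) and
  no interference. Mendelian consistency is exact by construction.
* **Traits**: a finite-QTL model -- QTL sampled from the panel, effects
  multivariate normal across traits so pleiotropy carries the genetic
  correlation, dominance deviations rescaled to a chosen ratio of the
  additive variance. A finite architecture (default 100 QTL;
  configurable from 10 to the panel size) is deliberate: squared-effect
  weighting needs signal to find, and the realized trait correlation has
  effective degrees of freedom set by the QTL count, not the sample
  size.
* **Field trials**: every genotype once per block on a rows x columns
  grid, blocks as contiguous bands, genotype order randomized within
  block. The residual variance is set so the broad-sense clonal-mean
  heritability hits the target, $H^2 = \sigma_g^2/(\sigma_g^2 +
  \sigma_e^2/n_\mathrm{blocks})$; the micro-environment is a low-rank
  B-spline surface draw (matching the fitting model; knot spacing =
  `spatial_range`) scaled to a chosen fraction of plot-level variance.
  Each trait gets an independent surface -- a simplification of
  trait-specific sensitivity to a shared micro-environment.
* **Pedigree errors**: wrong paternity attributed to whole or partial
  full-sib families (contiguous runs), one wrong sire per corrupted
  block, to a target fraction of offspring (the study's operating point
  is 15%).

What passing tests on these data do *not* show: real linkage
disequilibrium between base-population haplotypes (founders are
simulated unrelated, so the corrected pedigree's effective size equals
the parent count rather than the study's 12), genotyping or imputation
error (the QC filters are exercised on synthetic score tables),
selection history, or genotype-by-environment interaction. Directional
conclusions -- individual-sampling cross-validation beating
family-sampling, genomic models ranking sibs where pedigree cannot,
weighting enriching QTL-linked markers -- are structural and transfer;
absolute accuracies do not.

## Evaluation design

`make_partitions()` draws independent training/validation resamples
(10 by default; the repetition index offsets the seed) at fractions 0.5
or 0.25, sampling either individuals or whole families -- in family
mode no family ever straddles the split. Disjoint-fold partitioning is
available behind `mode = "folds"`, but resampling is the default
reading of a "10-fold scheme" whose published spread comes from
repeated draws. A TestSet of ids (e.g. the youngest families) can be
excluded from all training; `run_scenario()` asserts programmatically
that no validation or TestSet phenotype ever reaches a fit, records
per-cell failures without aborting the grid, and emits one long-format
table of (trait, matrix, scheme, fraction, repetition, population,
metric, value).

Metrics: predictive ability (Pearson of GEBV vs adjusted clonal mean),
accuracy (predictive ability divided by the square root of the A-model
reference heritability -- values above 1 are retained, as they arise by
construction), Spearman, tier-wise correlations (tiers 0-5%, 5-10%,
10-50%, 100% by quantiles of the observed values, best-first; a
`direction` argument covers traits where low is good, e.g. rust scores;
tiers under 3 members report NA rather than vanish), the bias
regression of observations on predictions (slope 1 = unbiased), and the
within-family gain: per family, Pearson(genomic, observed) minus
Pearson(pedigree, observed), averaged with family-size weights. A
pedigree prediction that is constant within a family carries no
within-family information and its correlation is defined as 0 rather
than left undefined.

## Numerical conventions

* Marker QC filters are strict inequalities ("higher than"); window
  thinning uses half-open windows anchored at bp 1, keeping the highest
  Props, then highest cProps, then lowest position.
* Opposing-homozygote parentage checks use a threshold expressed as a
  fraction of compared markers (default 0.01); reassignment is only
  among declared parents of the same sex role, and a parental roster
  can be supplied for the case where an error displaced a parent from
  every one of its recorded crosses. The correction is idempotent.
* Effective population size is the status number $N_s = 1/(2\bar f)$
  with $\bar f$ the mean coancestry ($K/2$) over all ordered pairs of
  the group, self-pairs included; the group defaults to the parental
  set.
* Spearman correlations use average ranks on ties; tier membership uses
  first-occurrence ranks so tiers have deterministic sizes.

## Problem sizes

The shipped analysis scripts and the acceptance script run the full
population (1,034 individuals) at 3,000 markers, with heavier
simulation studies at 20 replicates and spatial fits at ~1,000 plots --
sizes chosen so the whole workflow re-runs from scratch in minutes on a
laptop while leaving every estimate comfortably inside its sampling
tolerance. The same code runs unchanged at panel sizes orders of
magnitude larger; only the trace-normalized matrix constructions and
the eigendecompositions grow.

## Known limitations

Single-step blended matrices, Bayesian variable-selection models,
explicit AR1xAR1 residual structures, selection over generations, and
imputation itself are out of scope. The multi-trait fitter estimates
unstructured covariances only, and its missing-data residual updates
are pairwise rather than exact EM. Genetic correlations from shallow
pedigrees with few families are weakly identified -- the tests
deliberately use a deep factorial (64 families) for that check -- and
the A-vs-G BLUP agreement plateaus near 0.97 on realistic genomes
because G genuinely carries Mendelian-sampling information that no
pedigree can.
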