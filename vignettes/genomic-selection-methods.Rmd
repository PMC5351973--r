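---
title: "Genomic-wide selection in small breeding trials: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-wide selection in small breeding trials: models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `gwsel`, the
reasoning behind their default settings, what the synthetic-data generator
does and does not emulate, and the numerical and design decisions that are
not obvious from the function reference. It states no empirical result
beyond what the package's own tests and the `scripts/acceptance.R` driver
compute.

## 1. The setting

Perennial oil and fruit crops are bred in small trials: a few dozen
genotypes, one or two replicated blocks, long generation intervals.
Genomic-wide selection (GWS) tries to shorten the breeding cycle by
predicting genetic merit from genome-wide markers instead of waiting for
phenotypes. The package covers the full workflow for this setting:

1. quantitative-genetic analysis of the field trial (EM-REML variance
   components, heritability, coefficients of variation);
2. genomic diversity (identity-by-state distances, classical MDS, the
   VanRaden genomic relationship matrix);
3. eight whole-genome regression models compared by cross-validated
   prediction ability;
4. a marker-density study asking how few markers suffice.

## 2. Mixed models for the field designs

For a trait vector $y$ observed in blocks, the base model is

$$ y = X b + Z_g u + e, \qquad u \sim N(0, \sigma^2_g K), \quad
   e \sim N(0, \sigma^2_e I), $$

with $X$ the fixed block design, $Z_g$ the genotype incidence and $K$
either the identity (pedigree-free analysis) or a genomic relationship
matrix. Two experiment types add structure:

* **germplasm (half-sib) design**: genotypes are treated as independent
  families; the genotypic variance component estimates the family variance
  $\sigma^2_f$, which relates to the additive variance through Falconer's
  coefficient, $\sigma^2_a = k\,\sigma^2_f$ with $k = 4$ for half-sibs.
  `genetic_parameters(..., falconer_k = 4)` applies the expansion; because
  $\sigma^2_a$ is expanded while the phenotypic variance is not, the
  derived $h^2_a$ can legitimately exceed 1 when the residual is small —
  a diagnostic of the design's limits rather than an error, which is why
  `reml_fit(constrain = FALSE)` exists.
* **diallel (full-sib) design**: a family random effect is added alongside
  the within-family genotypic effect.

When only one observation exists per genotype-by-block cell the
plot-error term is not identifiable; `build_design()` drops it with a
warning instead of fitting a degenerate model.

### Estimation

`reml_fit()` runs EM-REML on Henderson's mixed-model equations. EM was
chosen over Newton-type updates because every iterate is guaranteed to
keep variances non-negative and the restricted likelihood is
non-decreasing — a property the unit tests check directly. Components are
floored at $10^{-10}\,\mathrm{var}(y)$ for numerical stability. The
unconstrained path (`constrain = FALSE`) instead estimates the residual by
difference, allowing negative values so that degenerate designs surface as
such. The restricted log-likelihood is computed from the MME factorization
and verified in the tests against the direct
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ form.

## 3. Whole-genome regression

With $W$ the column-centred dosage matrix ($w_{ij} = z_{ij} - 2p_j$), all
marker models share

$$ y = 1\mu + W\beta + e. $$

| method | prior on $\beta_j$ |
|---|---|
| `rrblup` | $N(0, \sigma^2_\beta)$, closed form |
| `gblup`  | equivalent kernel form, $u \sim N(0, \sigma^2_g G)$ |
| `brr`    | $N(0, \sigma^2_\beta)$, Gibbs |
| `bayesA` | scaled-$t$: $N(0, \sigma^2_j)$, $\sigma^2_j \sim$ scaled inv-$\chi^2$ |
| `bayesB` | spike-slab with per-marker variances |
| `bayesCpi` | spike-slab with common slab variance, $\pi$ estimated |
| `blasso` | double-exponential |
| `rkhs`   | Gaussian kernel $K_{ii'} = \exp(-h\,d^2_{ii'}/\bar{d^2})$ |

`gblup` uses the VanRaden relationship matrix
$G = W W' / c$, $c = 2\sum_j p_j(1-p_j)$; RR-BLUP and G-BLUP are the same
model in different parameterizations, and the test suite requires their
GEBVs to agree to numerical precision. Marker effects can be recovered
from a kernel fit by the standard backsolve
$\hat\beta = W'G^{-1}\hat g / c$.

Conventions shared by the samplers:

* $\pi$ is the prior probability that an effect is **zero** (spike mass);
  `bayesCpi` places a flat Beta(1, 1) prior on it.
* Default chains are 500 burn-in, 1,500 further iterations, thinning 5.
  These are deliberately modest: the models are exchangeable-prior
  regressions on small $n$, where chains mix quickly; the Monte-Carlo
  error of the posterior-mean effects is checked in the tests against the
  conjugate closed form with fixed variances.
* Hyperpriors follow the usual heritability-matching rule: the slab scale
  solves $E(\sigma^2_\beta) \cdot 2\sum p_j(1-p_j) = R^2\,\mathrm{var}(y)$
  with $R^2 = 0.5$ by default, degrees of freedom $\nu = 4$.
* All centring uses training-set allele frequencies only, so validation
  plants never leak into the model scale.

Prediction for unphenotyped plants uses marker effects where available;
kernel models predict through the fitted kernel block, and refuse plants
outside it rather than silently extrapolating.

## 4. Cross-validated prediction ability

`cross_validate()` measures prediction ability as the Pearson correlation
$r(\hat g, y)$ between predicted genetic values and observed (block-
adjusted) phenotypes in the left-out fold, with 5 folds by default —
small populations make leave-one-out tempting but fold-level correlations
need enough pairs to be meaningful, so folds below 3 plants are rejected.
Repeats re-randomize fold membership; seeds derive hierarchically from a
single master seed (`derive_seed`) so every fold and chain is reproducible
independently of execution order.

## 5. The marker-density study

`backward_elimination()` asks how prediction ability degrades as the
marker panel shrinks. Two linked computations are kept deliberately
separate:

* the **elimination path** on the full data: fit, backsolve effects,
  drop the smallest-$|\hat\beta|$ markers, repeat — yielding the retained
  panels and per-count variance components;
* the **ability curve**, measured with selection nested inside
  cross-validation: within each training fold markers are re-ranked using
  that fold's training plants only, and the top-$m$ subset is refitted
  before predicting the fold's validation plants.

The second point is a deliberate design decision. Ranking markers once on
the full data and then cross-validating the chosen subsets lets the subset
*identity* encode the validation phenotypes; with enough markers to choose
from, a trait that is pure noise can appear strongly predictable at
intermediate panel sizes. With fold-nested selection the noise curve stays
flat at zero, which the acceptance tests verify. The cost is one ranking
fit per fold; for ridge-type models the per-count refits then reuse the
fold's heritability estimate through the equivalent fixed-shrinkage ridge,
so the loop stays fast.

`curve_summary()` reads the sufficient density off the curve with a
one-standard-error rule: the smallest marker count whose mean ability is
within one SE of the curve's maximum.

## 6. The synthetic-data generator

`sim_config()` / `sim_founder_genotypes()` / `sim_diallel_progeny()` /
`sim_phenotypes()` emulate the data structures of a small perennial-crop
GWS pilot:

* founders in Hardy-Weinberg proportions with allele frequencies uniform
  on a configurable MAF window; codominant (0/1/2) and dominant (0/1)
  marker types;
* full-sib progeny by Mendelian gamete sampling from the founder genotypes;
* phenotypes from a set of causal loci with normal effects, rescaled so
  the realized additive variance hits its target *exactly* (the tests
  check this to $10^{-10}$), plus block effects and normal residuals;
  family deviations derived from a configurable dominance ratio;
* `make_study_like_dataset()` bundles a 78-plant layout: 36 germplasm
  accessions in two blocks plus 42 diallel progeny from 3 families —
  the package's reference problem size for comparisons.

Not emulated: linkage (markers are independent), genotype-by-environment
interaction, selection or drift across generations, genotyping error, and
non-normal residuals. The generator is a testbed for the estimators, not
a population-genetic simulator.

## 7. Numerical choices

* GRM inversion is stabilized by an explicit diagonal ridge
  (default $10^{-6}$) rather than a pseudo-inverse, keeping the fitted
  kernel reproducible across BLAS implementations.
* The spectral (eigendecomposition) REML path is used for single-kernel
  models, turning each likelihood evaluation into $O(n)$ after one
  $O(n^3)$ decomposition.
* Gibbs samplers are compiled (Rcpp) and draw all randomness from R's RNG
  stream, so a single `set.seed` reproduces a chain bit-for-bit.
* JSON/CSV outputs are written with full precision and the run manifest
  stores md5 checksums of every table, making complete pipeline runs
  byte-comparable; timing information is kept in a separate manifest file
  so checksums stay stable.

## 8. Limitations

* EM-REML converges slowly near variance boundaries; the iteration cap
  surfaces as `converged = FALSE` rather than an error.
* Prediction ability is a correlation: with tens of plants per fold its
  sampling error is large, and method differences smaller than roughly
  0.1 should not be over-interpreted at this scale.
* The backward-elimination path is greedy; it is the conventional
  procedure, not an optimal subset search.
* Dominant markers are handled as presence/absence dosages throughout;
  no attempt is made to model dominance variance in the marker models.
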