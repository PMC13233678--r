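---
title: "Methods and design choices in canopyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in canopyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

canopyn estimates maize canopy nitrogen content (mg/g dry weight) from
400–1000 nm reflectance. This vignette records the model, the
assumptions behind each stage, the parameters a user may want to move,
and the numerical conventions the implementation commits to.

## Data model

A `SpectraSet` extends `SummarizedExperiment`: bands are rows (with
`wavelength_nm` in `rowData`), samples are columns, and the single
assay holds reflectance. Wavelengths must be strictly increasing;
raw (underived) reflectance is validated into [0, 1.5] — values above
1 occur in practice through calibration overshoot, values outside that
window indicate unit errors. Named wavelengths used by index
definitions (e.g. R705) are resolved to the grid by `nearestBand()`,
which breaks exact ties toward the *lower* wavelength and refuses
targets farther than one grid step (both conventions are tested).

## Fractional-order differentiation

The Grünwald–Letnikov weights follow the recursion
$w_0 = 1,\; w_k = w_{k-1}(k - 1 - \alpha)/k$, equal to
$(-1)^k\binom{\alpha}{k}$. The transform is the left-sided
expanding-window sum truncated at the series start. Two conventions
required a decision because neither follows from the definitions
alone:

* **Unit-step convention.** We do not divide by (grid spacing)^α.
  Band-index units change every derivative by a constant factor per
  order, and every downstream use is a Pearson correlation, which is
  scale invariant. The convention is documented rather than hidden.
* **Edge handling.** The truncated sum makes the first few bands
  depend on an incomplete window. Instead of padding (which invents
  data), the first two bands of any α > 0 transform are flagged in
  `edgeMask()` and excluded from index searches. α = 0 is the exact
  identity and carries no mask.

Truncated operators compose exactly — applying α = 0.5 twice equals
α = 1 to rounding error, a Vandermonde identity on the weights — and
integer orders reproduce finite differences; both are tested, with the
weight recursion checked against the closed form to 1e−12 for k ≤ 50.
Orders outside the studied [0, 2] grid require an explicit override
flag.

## Wavelength selection

The GA uses binary chromosomes over bands, tournament selection (size
3), single-point crossover (p = 0.8), per-gene mutation (p = 0.01) and
2 elites. Its fitness is the negative 5-fold cross-validated RMSE of a
latent-variable linear regression (SIMPLS, components ≤ min(10, bands))
restricted to the chromosome, minus a cardinality penalty
λ·(selected/total) with λ = 0.05. The fitness model and the GA
hyperparameters are declared defaults — reasonable, conventional values
for wavelength selection, all exposed in `gaConfig()` — not claims
about any particular instrument. The penalty exists because without it
the GA drifts toward near-full-band chromosomes whose CV-RMSE is
marginally lower but which defeat the purpose of selection.

SPA is the classical deterministic forward selector: from each start
band, repeatedly add the band with the largest squared norm after
projection onto the orthogonal complement of the chosen set (ties go
to the lowest band index); the subset size within [kMin, kMax] and the
start band are then chosen by the same cross-validated inner model.
The degenerate single-band case (kMin = kMax = 1) is decided by the
projection criterion itself — the largest mean-centered column norm —
so that the selector's character does not silently change with k.
The hybrid runs SPA strictly inside the GA pool, and is tested to be
identical to SPA on the pool-restricted data.

## Vegetation-index screening and ODCA

The 24-index library is implemented *exactly as published in its
source table*, including transcription oddities (RVI1 and RVI2 share
one formula; MCARI, TVI and MCAVI carry unusual coefficient
structures; NDSI uses R756 in the numerator but R746 in the
denominator; SAVI1's "R80" is read as R800). Fidelity to the printed
table is the testable contract; `literatureForms = TRUE` substitutes
canonical literature versions of the four divergent formulas for users
who want them.

Scoring uses |r| rather than signed correlation: several indices
correlate negatively with nitrogen yet rank as important in the tree
ensembles, and absolute sensitivity is the only reading that makes the
seven criteria commensurable. Mutual information uses the
Kraskov–Stögbauer–Grassberger k-NN estimator (k = 3, max-norm, seeded
tie-breaking jitter), the standard choice for a continuous target.
Tree importances are impurity/gain based and averaged over 10 seeded
refits to damp their run-to-run variance.

ODCA normalizes each criterion's ranks to (r − 1)/(J − 1), averages
across criteria, and re-ranks ascending. The ordering is computed on
the integer rank sums (identical ordering, but exact where floating
summation could split a tie). Score ties break by the best
single-criterion rank, then input order. On the shipped published
rank table this reproduces the printed consensus for all 18 tie-free
rows and the full top-10; of the three rank-sum-tied pairs, two follow
the best-single-rank rule and one does not — no simple deterministic
rule reproduces all three printed tie orders simultaneously, so the
package documents its rule instead of fitting the table.

## Exhaustive index search

The ten index formulas are searched over every *ordered* band tuple of
the (possibly strided) grid — the correlation surfaces are genuinely
asymmetric for most formulas, so unordered search would discard
optima. Samples with |denominator| < 1e−12 are masked per tuple;
tuples with more than 5% masked samples, fewer than 3 usable samples,
or a degenerate variance are skipped, and the skip bookkeeping is
tested to conserve the total tuple count. Ties in |r| keep the
lexicographically smallest tuple. "Best" means max |r|: difference-type
indices legitimately correlate negatively.

Two published formulas needed a reading: TBI6's printed string is
mis-parenthesized and is read as the three-band fraction
(R1−R2)/((R1−R2)−(R1−R3)); the literal transcription (which collapses
to a two-band form) sits behind `literalTBI6 = TRUE`. TBI7 as printed
simplifies to R3 − R2 and is kept literal. OSI is implemented exactly
as printed (λ2 in the numerator, λ1 in the denominator).

The hot loop is compiled (Rcpp), specialised per formula so the
per-sample division is hoisted out of the innermost loop; the pure-R
nested-loop oracle lives in the test suite and the two are compared on
20-band grids for all ten formulas. Because some formulas harbour
exact algebraic |r| ties between distinct tuples (e.g. TBI2 at
(a,b,c) versus (c,b,c) when a,c swap roles in a complement identity),
equivalence is asserted on the attained optimum at 1e−12, which is the
strongest statement the argmax supports.

## Modeling

The 70/30 split is stratified by nitrogen quartile — the source
protocol asks for distributional consistency without saying how, and
quartile stratification is the weakest assumption that delivers it
(small sets fall back to a simple random split with a warning).
Grid search minimizes mean 5-fold CV-RMSE (ties: first grid row);
default grids are small, literature-standard ranges (trees 100–400,
depths 3–5, learning rates 0.05–0.1, SVR cost/γ log grids, 2–10 latent
components) exposed in `defaultGrid()`.

The stack uses XGBoost (L2 penalty, row and column subsampling), GBDT
(an unregularized gradient-boosted tree configuration of the same
library — no penalty, no subsampling, the classical algorithm) and
ridge (`glmnet`, α = 0) as bases, with a Bayesian ridge meta-learner
(conjugate linear model, MacKay evidence updates) fit on strictly
out-of-fold 5-fold base predictions. Meta-features are the raw base
predictions only — no passthrough of original features. The structural
leakage property (fold f's meta-features are unchanged when fold f's
labels are corrupted) is tested directly.

## Interpretation

Tree bases are attributed with exact tree-path Shapley values
(TreeSHAP via the boosting library's `predcontrib`); linear bases with
the exact linear decomposition coefficient × (x − mean). Additivity —
contributions plus baseline equal the prediction — is asserted at
1e−6 relative. Fusion weights default to |meta coefficient| normalized
to sum 1; the alternative (weights ∝ out-of-fold R² per base) is one
flag away, because the "weighted fusion" of the bases admits both
readings and the choice is not forced by anything observable.

## The synthetic canopy generator

The generator is phenomenological, not radiative transfer: a visible
baseline with a green peak, Gaussian chlorophyll absorptions near 470
and 670 nm whose depth *increases* with nitrogen, a logistic red edge
whose inflection shifts to longer wavelengths with nitrogen
(≈5 nm per mg/g around 712 nm), a density-scaled NIR plateau, a 930 nm
water feature, and multiplicative plus additive noise, clipped to
[0, 1]. Nitrogen comes from four treatment groups with means
17.5/18.5/19.5/20.0 mg/g and spreads 0.8/0.9/1.0/1.1 mg/g (spreads are
declared defaults; the treatment means and the 50 × 4 = 200 sample
design mirror the emulated field study), truncated at zero.

What passing tests show: every stage recovers signals this generator
plants — band selectors find planted band pairs, the search finds
planted tuples and orders, the stack predicts held-out nitrogen, the
fused attribution surfaces red-edge carriers. What they do not show:
field accuracy. The simulator has no canopy architecture, soil
background, illumination geometry, atmospheric residual, or
between-plot spatial correlation, and its noise is band-independent;
absolute R²/RMSE on it are upper bounds of convenience, not
field claims.

## Problem sizes and determinism

The shipped test and reference runs use: the default 301-band grid at
2 nm; stride-2 index search over all 9 orders (≈3.4M tuples per
three-band formula and order); GA population 30 × 30 generations
inside the pipeline (the planted-recovery tests use the full 50 × 100
default); 20-seed replication for the stochastic invariants
(noise-monotonicity, attribution-majority); oracle comparisons on
5 × 4 to 20-band grids. One global seed fans out to fixed per-stage
seeds, every stochastic component (GA, folds, tree ensembles, MI
jitter) is seeded from it, and two runs of `runPipeline()` with the
same config are tested byte-identical.

## Known limitations

* Single-date, single-variety reasoning is baked into the feature set:
  nothing here models growth-stage dynamics.
* The exhaustive 3-band search at stride 1 on the full grid
  (~27M tuples per formula/order) is feasible but slow in this
  implementation; stride 2 is the default for a reason.
* The rank-aggregation tie rule cannot reproduce every published tie
  order (see above); tie-free conclusions are unaffected.
* GBDT-vs-XGBoost is a configuration contrast within one boosting
  library, not two independent codebases.
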