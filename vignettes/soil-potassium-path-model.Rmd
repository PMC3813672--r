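---
title: "Path-coefficient analysis of soil potassium status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-coefficient analysis of soil potassium status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilKpath)
```

## The scientific problem

Plant-available potassium in soil is governed by the balance between three
pools: water-soluble K (wsK) in the soil solution, exchangeable K (eK) held
electrostatically on clay and organic exchange sites, and non-exchangeable K
(neK) fixed in the interlayers of 2:1 clay minerals. The pools interconvert
(wsK ⇌ eK ⇌ neK), and the position of that balance responds to the soil's
geochemical and biological environment: weathering state, organic-matter
fractions, pH, redox potential, associated cations. soilKpath implements a
regression-based path analysis of a 16-group survey of cotton
rhizosphere/non-rhizosphere soils that quantifies which soil properties move
the balance, how strongly, and in which direction.

The analysis unit is the sample *group* (16 printed group means), not the
underlying individual samples, which are not available. This matters for
interpretation: with n = 16 the correlation and regression estimates are
exactly reproducible but statistically fragile, and the package warns
accordingly (see *Numerical choices*).

## Weathering indices

Four geochemical indices are derived from elemental totals on a molar-oxide
basis. Moles of an oxide per 100 g soil are computed as element mass
fraction / atomic mass, halved for R2O/R2O3 oxides (Na2O, K2O, Al2O3,
Fe2O3). Total K arrives in g/kg and is divided by 10 to a mass percent
before use; the conversion is logged.

* `na_k_ratio`: Na%/K%, the sodium–potassium antagonism indicator;
* `cia`: 100·Al2O3/(Al2O3 + CaO + Na2O + K2O), the chemical index of
  alteration (uncorrected CaO — no silicate/apatite correction; that is the
  convention that reproduces the packaged survey's printed column);
* `saf`: SiO2/(Al2O3 + Fe2O3), the silica/sesquioxide leaching index;
* `ba`: (CaO + MgO + Na2O + K2O)/Al2O3, the base/alumina ratio.

All four are invariant under uniform rescaling of the elemental inputs.
The survey layout carries two columns labelled Mg; only the first (~0.39%)
reproduces the printed ba column and enters the computation, the second
(~1.49%) is preserved as data. The ICA index column is carried through
verbatim: no tested oxide convention reproduces it, so the package treats it
as data rather than guessing a formula.

**Sensitivity of CIA to input rounding.** Recomputing all 16 rows from the
2-dp-rounded survey inputs reproduces ba exactly and Na/K and saf to ±0.01,
but CIA deviates by up to ±0.12 with mixed signs. This is a propagation
effect, not a formula discrepancy: CaO contributes only ~6% of the CIA
denominator, so the ±0.005 rounding uncertainty of a Ca value near 0.37%
alone moves CIA by about ±0.06, and the worst row (Ca printed as "0.4")
carries ±0.05 of input rounding. The printed index column was evidently
computed from unrounded raw data. `compute_indices(..., compare = TRUE)`
reports the per-row deviations rather than hiding them, and the test suite
asserts the reproducible indices at ±0.01 while documenting the CIA
deviation as a known property of rounded inputs.

## Normalization and the correlation surface

`zscore_matrix()` standardizes each variable to mean 0 and sample standard
deviation 1 (n−1 denominator; the choice affects no correlation but fixes
the Z-matrix invariants). `pearson_matrix()` computes the pairwise-complete
Pearson surface with two-tailed p-values from t = r·√((n−2)/(1−r²)) on
n−2 degrees of freedom.

Design choices here:

* **Printed index columns feed the surface.** The packaged survey's
  correlation cells reproduce only when the *printed* index columns (ba,
  Na/K, ICA, saf, CIA) are used, e.g. r(CIA, neK) = 0.56 with the printed
  column versus 0.63 with recomputed CIA. The pipeline therefore correlates
  what the survey reports; recomputed indices are available separately.
* **Significance letters.** The letter map follows the published caption
  literally — `a`: p < 0.01, `b`: p < 0.05 — although that convention looks
  inverted relative to common usage. It is configurable (`alpha_map`).
* **Display threshold.** Reports mask |r| < 0.5 because the published
  surface prints no weaker cell; the full matrix is always retained. Blank
  cells mean "below display threshold", never zero, which is why the
  long-format fixture simply omits them.
* **Known irreproducible cells.** The published Na/K–CIA cell (+0.829) has
  the opposite sign of the value the data give (−0.83); the bacteria, NHA–pH
  and most PHA-row cells do not reproduce from the packaged tables under any
  growth-stage or transform we tested. `compare_correlations()` reports all
  deviations; the package treats the reproducible table cells as canonical
  and never adjusts data toward an unreproducible one.

`select_parameters()` implements the screening step (keep the k = 8
strongest significant correlates of a response), with deterministic
lexicographic tie-breaks.

## Path models

For response y and predictors x on the standardized scale, the direct path
coefficients P solve the normal equations R_xx·P = r_xy; R² = r_xy′P, and
the uncorrelated residue attached to the response is e = √(1 − R²). The
correlation between a predictor and the response decomposes as

r_jy = P_j + Σ_{k≠j} r_jk·P_k,

direct effect plus indirect effects transmitted through the other
predictors. With every predictor retained, this reconstruction is an exact
algebraic identity of least squares; the suite asserts it at 1e−8 on the
survey and on random instances, and checks the solver against an
independent ordinary-least-squares fit on the raw scale.

Backward elimination refits repeatedly and removes the predictor with the
largest coefficient p-value (t-test, df = n−p−1) while it exceeds
`alpha_remove` (default 0.05; the elimination criterion is exposed because
the source analysis states only that non-contributing variables were
removed). Ties break toward the larger p then the label, so traces are
deterministic. With n = 16 and eight predictors the fit has seven residual
degrees of freedom: feasible but fragile, so the module warns whenever
df < 10 and refuses df < 1. The predictor correlation matrix is rejected as
collinear above a condition number of 1e8 — a live concern here, since
r(neK, eK) = 0.98.

The three published coefficient tables are packaged as fixtures for
*qualitative* comparison only: their "direct correlation coefficients"
column demonstrably equals the simple correlations, so the printed column
semantics are ambiguous. `compare_path_table()` therefore sets all three
computed candidates (simple r, indirect total, direct P) against each
printed column instead of asserting any single mapping.

## Equilibrium-shift model

The balance movement of a target form (neK or eK) is described by two route
contribution functions, e.g. V_wsK→neK and V_eK→neK: linear functionals
V = Σ w_j·Z_j over the route's source variables (wsK/PHA, eK/PHA, neK/PHA).
Route weights default to the direct path coefficients of the target form's
fitted model restricted to the route sources; a source eliminated from the
model (PHA never enters the published neK/eK predictor sets) contributes
zero weight, with a warning, and explicit weights can override.

Equilibrium is declared when the standardized target-form content lies
within a tolerance (default 0.05 on the Z scale, configurable) of the
dominant route's V value — the larger |V|, ties resolving to the first
route. The functional forms behind the published analysis are not
recoverable from its text, so this dominant-route threshold is the
package's own explicit rule, chosen to be consistent with the published
per-sample values.

The two-symbol direction labels (α/β + γ/χ for the neK balance, ε/θ + λ/ω
for eK) are classified by a *calibrated* decision table. We verified that
no total function of sign/order comparisons of (V1, V2, Z) reproduces the
published labels — several published rows share identical comparison
patterns yet carry different labels — so the packaged rule stores the 16
published (V1, V2, Z) triples per target with their labels and classifies
by nearest exemplar (Euclidean distance, earliest-row tie-break). That
makes the rule total, deterministic, exact on the calibration set, and
honest about its provenance: it is a fixture regression, not a derivation.
Symbols are opaque labels; no chemical interpretation is encoded.

## Synthetic data

`generate_table()` draws multivariate Gaussian covariates with a target
correlation matrix and adds linear structural responses y = Σ β_j x_j + ε
with noise sd √(1 − β′Rβ), so responses are unit-variance on the
standardized scale; β′Rβ ≥ 1 is rejected as infeasible. The Gaussian copula
is the minimal assumption consistent with a Pearson-correlation analysis;
no spatial structure, time dynamics or non-Gaussian marginals are modelled.
`emulate_field_study()` instantiates the survey's statistical shape: the
published correlation surface completed with zeros (a blank cell means
|true r| < 0.5, and 0 is the least-informative completion), repaired to
positive definiteness by eigenvalue clipping at 1e−8 with re-normalization
to unit diagonal, then back-transformed to the survey's means and sds. Na
and S, which feed the path models but are absent from the published
surface, are appended as uncorrelated columns.

What passing tests on such data do and do not show: they demonstrate that
the estimators recover known standardized coefficients (mean absolute error
below 0.05 at n = 10,000 across 5 seeds) and that empirical correlations
converge to the repaired target (within 0.03 at n = 10,000) — properties of
the *method*. They do not validate the Gaussian assumption for real soils,
where variables like water-soluble K are right-skewed and strictly
positive; back-transformed draws can stray below zero, which the generator
deliberately does not clip, since clipping would distort the correlation
structure the tests rely on.

## Numerical choices and problem sizes

* Sample standard deviation (n−1) throughout; Z-matrix invariants are
  |mean| < 1e−10 and |sd − 1| < 1e−10.
* Normal equations solved by LU (`solve`); condition bound 1e8.
* Decomposition identity asserted at 1e−8; residue identity
  e² + R² = 1 at 1e−12; permutation invariance at 1e−12.
* Recovery experiments use n = 10,000 with 5 fixed seeds; convergence
  checks at n ∈ {100, 1,000, 10,000}. These sizes give Monte-Carlo error
  comfortably below the asserted tolerances while keeping the default test
  run fast.
* All stochastic tests fix explicit seeds; generation is bit-identical
  under a fixed spec + seed.

## Known limitations

* n = 16 group means bound what any refit can claim; the package
  reproduces the published surface but the fragile-df warning is not
  decoration.
* The ICA index and the analytic form of the equilibrium/direction rules
  are not recoverable; both are handled as data (pass-through column,
  calibrated exemplar table) rather than invented algebra.
* A handful of published correlation cells and the path-table column
  semantics cannot be reproduced from the published data; all comparison
  functions report deviations instead of suppressing them.
* CIA recomputed from rounded inputs carries ±0.1-scale rounding noise, as
  quantified above.
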