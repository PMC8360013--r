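---
title: "Ensemble distribution and richness models for riverine EPT insects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble distribution and richness models for riverine EPT insects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Ephemeroptera, Plecoptera and Trichoptera (EPT) are the classic
bioindicator insect orders of running waters; their local species richness
(EPTr) is widely used as a proxy for ecological status. This package
implements a complete pipeline for predicting EPT occurrence and richness
in a river network under climate-change forcing, combining two
complementary community-modelling strategies:

* **SDMs, stacked (S-SDM)** — "predict first, assemble later": one
  ensemble distribution model per species, with community richness
  obtained by summing the per-species occurrence probabilities at each
  reach.
* **MEM** — "assemble first, predict later": a macroecological model that
  regresses observed richness directly on the environmental predictors.

Because the monitoring data such pipelines are trained on are typically
restricted, the package ships a synthetic riverscape and virtual-species
generator that reproduces the statistical structure the models assume, so
every stage — from survey quality filtering to scenario projection — is
testable against a known ground truth.

## Ensemble members and weighting

Each species model has two members trained on identical predictors:

* member A: a binomial GLM with degree-2 orthogonal polynomial terms on
  the eight environmental predictors and linear terms on the spatial
  eigenvectors. The quadratic terms allow the unimodal (niche-shaped)
  responses that dominate in thermal gradients; the degree is a
  configurable argument.
* member B: a random forest classifier (500 trees by default, seeded per
  split, via the randomForest package).

Evaluation uses *community cross-validation*: the same repeated random
80/20 site splits (50 by default) are reused for every species and for the
richness models, so community-level metrics are comparable across taxa.
The ensemble prediction is the weight-normalised convex combination

\[ p = \frac{w_A p_A + w_B p_B}{w_A + w_B}, \]

where a member's weight is its mean test-fold AUC transformed to a skill
score, \(w = \max(\mathrm{AUC} - 0.5,\, 0)\). The raw-AUC alternative
(`weighting = "raw"`) is retained behind a flag; the skill transform is
the default because a no-skill member (AUC 0.5) then receives zero weight
instead of nearly half of it. Final projection members are refit on all
sites; cross-validation supplies only the weights and the evaluation
records. The richness ensemble (Poisson GLM + random-forest regressor)
uses the same construction with mean test-fold Spearman correlation,
floored at zero, as the weight.

AUC is computed in the Mann–Whitney form (ties counted one half). TSS is
maximised over candidate thresholds (midpoints of sorted unique scores
plus both endpoints); a fixed 0.5 threshold was the plausible alternative,
but threshold maximisation is the convention of the standard
presence–absence evaluation toolchain and is what the performance bands
below presume. Median per-species values over the splits are banded:
AUC > 0.90 excellent, 0.80–0.90 good, 0.70–0.80 fair, at or below 0.70
poor; TSS > 0.75 excellent, 0.40–0.75 good, below 0.40 poor.

## Stacked richness and its exact distribution

If species occur independently with probabilities \(p_1,\dots,p_S\) at a
site, the site's richness follows the Poisson-binomial distribution: mean
\(\sum_i p_i\) (exactly the stacked-SDM expected richness) and variance
\(\sum_i p_i (1 - p_i)\). `poisson_binomial_pmf()` computes the exact pmf
by iterative convolution (dynamic programming), and
`richness_site_test()` turns it into an exact two-sided test of an
observed richness. Two-sided exactness requires an ordering convention;
the default ("mass") sums the probabilities of all outcomes no more likely
than the observed one, with a central (tail-doubling) alternative behind a
flag. The mass convention is the common choice for exact goodness tests on
unimodal discrete distributions; being exact and discrete it is
conservative, which the type-I simulations in the test suite confirm.

Overall calibration of richness predictions is tested by regressing
observations on predictions and jointly testing intercept 0, slope 1 with
a 2-df F test. The regression direction (observed ~ predicted) follows the
phrasing "testing the linear relationship with observations"; the reverse
direction would conflate calibration with the regression-dilution effect
of prediction error in the regressor. Standardised richness errors are
\((\hat r_i - r_i) / \bar r\).

## Environmental predictors

Eight environmental predictors are derived per reach: mean and coefficient
of variation (sample SD divided by the mean, \(n-1\) denominator) of
monthly water temperature; log-transformed mean and CV of monthly
discharge; slope; and urban, forest and agriculture cover. Per-year values
are computed from 12-month windows — for model training, the 12 months
strictly preceding the survey month, matching the at-most-annual life
cycles of the modelled taxa — and averaged arithmetically across the years
of a projection period. For the hydrological log-mean the log is taken per
year and the period average is formed on the log scale; the alternative
(log of the averaged means) differs only by a Jensen term that is
negligible at these variances, but the order is fixed and documented here.
Two climate simulations are combined by month-wise arithmetic averaging of
the forcings (not of derived predictors); averaging forcings keeps every
derived quantity consistent with a single physical series.

Water temperature at unmonitored reaches is predicted from a linear mixed
model: monthly water temperature on monthly air temperature and its
interaction with the catchment's glacier-or-lake cover (glaciated and
lake-buffered catchments damp the air-to-water transfer), with a
station-level random intercept and random air-temperature slope for the
repeated measures. Marginal and conditional R² follow the Nakagawa
variance decomposition, with the random-slope contribution averaged over
the observed design. Projections use fixed effects only, since random
effects are station-specific; predicted monthly water temperatures are
floored at 0.2 °C (streams under ice hover just above freezing).

Glacier retreat under a scenario removes the fraction *q* of
lowest-elevation glacier cells ("replaced by bare rock"): 45 % / 50 %
(RCP2.6 / RCP8.5) by 2055–2065 and 60 % / 90 % by 2080–2090, with the
2015–2025 baseline untouched. The removal count is `round(q * n)` with
half rounded up, ties at the cutoff broken by elevation then cell id, so
retreat is deterministic and monotone in *q*.

Collinearity screens (pairwise Pearson |r| < 0.7, VIF < 4 with VIF
\(= 1/(1-R^2_j)\)) are applied to the assembled predictor matrix; the
synthetic generator's default configuration passes them, as the real
predictor set did.

## Spatial eigenvector covariates

Large-scale geographic structure enters the models as the first five
eigenvectors of a doubly centered Euclidean distance matrix over reach
coordinates. Two centering variants are implemented. The
principal-coordinate convention (`centering = "pcoa"`, the package
default for the function) double-centers the *squared* distances; it is
the textbook reading of "doubly centered distance matrix", but for planar
coordinates it has exactly two positive eigenvalues — the configuration is
two-dimensional — so five eigenvectors cannot exist. The distance-based
eigenvector-mapping literature therefore centers the distance matrix
itself, which yields a full spectrum of large-scale trend patterns; the
pipeline uses this `centering = "raw"` variant whenever five vectors are
required, and the tests exercise both. Eigenvector columns are unit-norm,
orthogonal, centered, and sign-fixed (first non-negligible loading
positive).

For large networks the exact eigendecomposition is replaced by a
Nyström-style approximation: k-means cluster centres of the coordinates
(fixed seed) serve as anchors, all points are projected through the
anchors' eigenpairs with Gower cross-centering, and the projected scores
are re-centered and orthonormalised by SVD. The projection deliberately
carries more anchor components than requested (k + 15) before truncating
to k, which sharpens the leading subspace; with 100 anchors on 1,000
points the approximate columns correlate with the exact ones above 0.999.
With anchors at every point the approximation reproduces the exact
decomposition up to sign.

## Survey data-quality rules

Monitoring records mix species-, genus- and family-level identifications.
A survey's *minimum potential richness* is the number of identified
species, plus genus-level records whose genus contains no identified
species, plus family-level records whose family contains neither a
genus-level record nor the genus of an identified species. Surveys whose
identified species count is below 70 % of that minimum are discarded
(kept at exactly 70 %, reading "less than 70 % … were discarded"
literally). Duplicate surveys of a site resolve to the highest
completeness, ties to the most recent date, then lexicographic survey key
— the source rule is silent beyond completeness, so the tie-break is
chosen to be deterministic and auditable. Sites snap to their nearest
reach within 30 m (inclusive at the tolerance). Species occurrence is
counted per site after deduplication, and species with fewer than 25
presences are dropped.

## The synthetic generator

`generate_riverscape()` emulates a temperate-alpine river network at desk
scale: elevations uniform over 200–3,000 m drive mean air temperature
through a −6 °C/km lapse rate; seasonal water-temperature amplitude
*increases with the thermal level* of the reach (warm lowland rivers swing
widely, cold alpine streams are buffered near freezing by ice cover, snow
melt and groundwater), which keeps the temperature mean and CV from being
mechanically collinear; discharge is lognormal with a snowmelt-driven
summer peak that strengthens with elevation and glacier cover; urban and
agricultural cover decline with elevation while forest peaks at montane
elevations; glacier cover above ~2,200 m is represented as explicit
elevation-banded cells so the retreat heuristic operates on the same
objects as the real pipeline. Default desk-scale sizes are 500 reaches, 30
species and 300 survey sites.

Virtual species have Gaussian niches on the probability scale,
\(p(x) = p_{\max} \exp(-\sum_j (x_j - \mu_j)^2 / 2\sigma_j^2)\), the
standard virtual-species construction; it gives closed-form worked
examples and a well-defined recoverable optimum. Optima are drawn inside
the central predictor range, breadths between 15 % and 40 % of each
predictor's range, \(p_{\max}\) between 0.5 and 0.95 — values that produce
the mix of common and restricted species (prevalences roughly 0.1–0.7)
that the prevalence filter and the models expect. Surveys draw presences
as independent Bernoulli trials and record each detection at species,
genus or family rank with configurable probabilities (default
0.8/0.15/0.05), independently across records, partial identifications
inheriting the true lineage.

Scenario perturbations are uniform air-temperature offsets, discharge
multipliers and the glacier-replacement fractions above. The default
offsets (+1.0/+1.1 °C for RCP2.6, +2.6/+4.6 °C for RCP8.5 by mid- and
end-century) and multipliers (0.97/0.95 and 0.93/0.88) are desk-scale
stand-ins of the right order for Swiss end-of-century projections; they
are inputs, not estimates, and are fully overridable.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: river-network topology and flow connectivity
(reaches are points, distances Euclidean); residual spatial
autocorrelation beyond smooth trends; species interactions and dispersal
limits; non-stationary niches; observation errors other than rank-coarsened
identification (no misidentification, no abundance effects on
detectability); and the real covariance structure of climate forcings
(offsets are spatially uniform).

## Numerical conventions and degenerate inputs

* Relative changes are `100 * (future - base) / base`, rounded half away
  from zero to one decimal — the convention of the published projection
  tables (base R `round()` is half-even and would differ at exact ties).
* Regional means are unweighted across reaches; reach-length weighting is
  a documented alternative.
* Ensemble weights: if both members come out at zero skill the ensemble
  falls back to equal weights with a warning rather than dividing by zero.
* Constant test-fold richness makes Spearman undefined; it counts as zero
  weight with a warning.
* A singular mixed-model fit (variance component on the boundary) is
  reported via a flag and warning, never silently absorbed.
* Exact-test p-values compare pmf masses with a 1e-10 relative guard so
  floating-point ties do not drop outcomes from the two-sided sum.
* Permutation importance is \(\max(0, 1 - \bar r)\) over `n_perm = 10`
  permutations; response curves hold non-focal predictors at training
  medians (means behind a flag).

## Problem sizes used by the tests and the acceptance script

The packaged checks run at desk scale, chosen to finish comfortably on a
single CPU: the community fixtures use 300–500 reaches, 15–30 species,
220–300 survey sites and 10–15 cross-validation splits; the
warming-direction check fits 2 designed species across 20 generator seeds
at 250 reaches; calibration simulations use 10,000 (exact site test) and
5,000 (linear hypothesis) replicates; eigenvector fidelity is checked at
1,000 points with 100 anchors. Published-scale quantities (median AUC
0.86, TSS 0.68 across 41 real species, the regional richness tables)
depend on the restricted national monitoring data and are treated as
qualitative references: the packaged worked examples reproduce the
published tables' arithmetic exactly, while the statistical contracts are
verified on synthetic data with known truth.

## Known limitations

The pipeline assumes independent species (the Poisson-binomial stacking
ignores co-occurrence dependence); the exact site test is conservative;
fixed-effects-only water-temperature projection understates between-station
heterogeneity; the Nyström eigenvectors are approximations whose quality
depends on anchor coverage; and projections inherit every caveat of
correlative niche models — stable realized niches, no dispersal
constraints beyond the spatial filters, no biotic interactions.
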