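---
title: "Modelling urban heat island clines in snail shell morphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling urban heat island clines in snail shell morphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailcline)
```

## The problem

The grove snail *Cepaea nemoralis* is polymorphic for shell ground colour
(yellow, pink, brown) and for up to five dark spiral bands; both are
genetically determined. Because darker shells absorb more solar radiation,
morph frequencies are expected to respond to thermal selection, and cities —
which run warmer than their surroundings by an urban heat island (UHI) excess
of up to a few degrees — are a natural large-scale experiment. snailcline
implements the full analysis chain for testing this on georeferenced,
crowd-sourced morph records: data cleaning, habitat stratification,
multinomial morph-frequency regression against UHI and climate covariates,
a morph darkness score, residual spatial autocorrelation (RSA) diagnostics
with a penalized-spline correction, and the analyses of the two field
experiments that probe how trustworthy crowd-sourced morph records are.

Every stage runs on synthetic data from the package's own generator, so the
whole pipeline is testable without downloading any external raster or
observation archive.

## Record cleaning

A record is one photographed snail: coordinates, date (stored as day number,
1 = 1 April, the season start), reported colour, a five-slot banding code,
the camera angle, and whether the dark aperture lip — the character that
separates adult *C. nemoralis* from the white-lipped *C. hortensis* — is
visible. `filter_records()` applies, in order:

1. duplicate record ids collapse to the first occurrence;
2. records after the season end (default day 198 = 15 October, when the
   snails start hibernating) are dropped;
3. records *without* a visible dark lip are dropped only inside three regions
   where *C. hortensis* is common (southern Limburg, latitude < 51.2;
   north-east Groningen, latitude > 53 and longitude > 6.5; the Nijmegen
   area, 51.8 < latitude < 52 and longitude > 5.75). The inequalities are
   strict; boundary records are retained.

Survivors form the *colour set*. The *banding set* additionally requires a
lateral view (apical photographs hide bands 4 and 5), a parseable banding
code, and one of the four main banding types: unbanded `00000`, mid-banded
`00300`, three-banded `00345`, five-banded `12345` (parentheses mark fused
adjacent bands, e.g. `123(45)`). Every rejection is logged with its rule, so
stage-to-stage attrition always reconciles exactly.

## The morph-frequency model

The core estimator is a baseline-category multinomial logit fitted by
maximum likelihood, written for this package (`multinom_ml()`). With outcome
categories $k = 0, 1, \dots, K-1$ and reference $k = 0$ (yellow for colour
models, unbanded for banding models),

$$\log \frac{P(y_i = k)}{P(y_i = 0)} = x_i^\top \beta_k, \qquad k \ge 1.$$

The default design follows the standard morph-cline specification: day
number, UHI (°C), mean annual temperature (°C) and mean annual dry days,
with all two- and three-way interactions among the three climate variables.
Predictors are centred around the mean of the fitted subset *before* the
design matrix is built, so interaction columns are products of centred
variables; centring is recomputed for each model and the stored centres are
re-applied by `predict()`. Centring does not change slopes or fitted
probabilities — only the intercept parameterisation — but makes main effects
interpretable at average conditions in the presence of interactions.

Numerics: full Newton iteration on the exact log-likelihood with analytic
gradient and observed information, step-halving so the objective never
decreases, and a $10^{-8}$ ridge only if the information matrix is
numerically singular. Convergence requires the largest absolute score entry
below $10^{-8}$ or a relative log-likelihood change below $10^{-12}$
(iteration cap 200). Coefficients with $|\hat\beta| > 15$ trigger a
perfect-separation warning naming the diverging term. Inference is Wald:
standard errors from the inverse observed information, two-sided normal
p-values matching the reported z-values, odds ratios as
$\exp(\hat\beta)$, and the conventional star labels ($p<0.05$, $<0.01$,
$<0.001$, else NS, each threshold strict).

Habitat comparisons (agricultural, nature, urban green, urban grey — a
nearest-cell lookup of the categorical land-use grid) use Pearson
chi-squared tests without continuity correction.

## Darkness score and the thermal-sum curve

A morph's darkness score is its expected internal-temperature excess over a
yellow unbanded shell, assembled from measured increments: 0.3 °C for pink
and 0.6 °C for brown ground colour, 0.07 °C per band and 0.03 °C per band
fusion. So a pink five-banded shell with two fusions scores
$0.3 + 5 \times 0.07 + 2 \times 0.03 = 0.71$ °C.

`bin_mean_darkness()` bins records by thermal sum (temperature + UHI) into
half-open intervals $[l, u)$ of 0.25 °C starting at 9.25 °C, with the last
three unit bins merged into one 0.75 °C tail so the tail keeps a comparable
sample size; records below the start go to an explicit underflow bucket.
`fit_log_darkness()` then regresses the per-bin *mean* darkness on the log
of the bin centre by unweighted ordinary least squares, reporting the slope,
intercept, the 1-and-$(k-2)$-df F statistic and $R^2$. The fit is on bin
means, not raw records, because the curve describes the binned summary; it
is unweighted because the tail merge is designed to equalise bin sizes. Both
choices are deliberate and the main open alternatives (raw-record fit,
n-weighted fit) would change the printed statistics.

Proportion curves against UHI split the data at the median temperature
(records equal to the median go to the "cold" half), bin UHI into half-open
0.2 °C categories from 0, and attach 95% Wilson score intervals — the
score-test inversion, which stays inside $[0,1]$ and behaves sensibly at
small counts, unlike the Wald interval.

## Spatial diagnostics and the smoothed refit

Model residuals are examined through the reference-category residual
$r_i = \mathbf 1(y_i = \text{ref}) - \hat P_i(\text{ref})$. Global Moran's I
uses raw (un-row-standardised) inverse-distance weights over haversine
distances on a 6,378,137 m sphere, with zero diagonal; coincident points
(repeated GPS fixes) get weight zero by default since $1/d$ is undefined
there (a "max finite weight" policy is available). The expectation is
$-1/(n-1)$; the variance is available under both the normality null
(default) and the kurtosis-corrected randomisation null, which is what the
permutation distribution realises exactly. Distance-class correlograms use
binary within-class weights and seeded permutation tests. Note that when
near classes are strongly positive, far classes must drift negative —
centred residuals sum to zero — so "correlation has died out by distance d"
should be read as absence of *positive* similarity, not a p-value above
0.05 in a two-sided test.

Because RSA deflates standard errors, `fit_smoothed_multinomial()` refits
the multinomial logit with penalized B-spline smooths added to each linear
predictor: marginal smooths of latitude, longitude and day number, and a
latitude x longitude tensor product. Each smooth carries a difference
roughness penalty on its coefficients. The penalty order defaults to 1, a
deliberate choice: the null space of a first-difference penalty is the
constant function, so an infinitely penalized smooth degenerates to a
constant absorbed by the intercept and the smoothed model *nests* the plain
parametric fit exactly (order 2, which leaves linear trends unpenalized, is
available). Smoothing parameters are calibrated so each term's
Gaussian-analogue effective degrees of freedom
$\mathrm{tr}\{(B^\top B + \lambda S)^{-1} B^\top B\}$ match a configured
target (defaults: 4 per marginal, 9 for the tensor); sum-to-zero
constraints keep the smooths identifiable next to the intercept. The tensor
basis contains the marginal spaces, so individual smooth coefficients are
only penalty-identified — fitted probabilities and the parametric Wald
table, which are what the diagnostics use, are unaffected. Parametric terms
keep their odds-ratio/z interpretation, with standard errors from the
inverse penalized information.

This smoothed refit is a generic penalized basis-expansion multinomial
logit, not a re-implementation of any particular additive-model package;
its job here is behavioural — absorb broad spatial structure, reduce
residual Moran's I, and show whether the UHI effect survives — not to
reproduce another smoother's coefficients.

## The synthetic-data generator

`generate_landscape()` builds a Netherlands-like study region (lon 3.3-7.2,
lat 50.75-53.55, 0.01° cells): UHI as Gaussian kernels around eight city
centres (peaks 1.1-2.0 °C, scale 4-6 km), temperature linear in latitude
(11.2 °C at the southern edge, -0.55 °C per degree northward, smooth noise
sd 0.15 °C, median near 10 °C), dry days linear in longitude (160 at the
west coast, +7 per degree eastward, noise sd 1.5), and land use as
urban-grey cores, urban-green rings and a random coarse tiling of
nature/agricultural elsewhere. An optional multiplicative street-scale
(~2 km) UHI texture emulates the within-city variation a fine-resolution
UHI raster shows; it defaults to 0 so the kernel-peak arithmetic stays
exact.

`generate_observations()` then emulates the observation process: locations
cluster around observer centres (citizen scientists sample where people
are), day numbers are uniform over the season, covariates are read from the
layers, latent colour is drawn from the multinomial truth model at the
centred covariates, banding conditional on colour (brown shells are
unbanded with probability 0.96), reported colour passes through a 3x3
confusion matrix (default 94% diagonal, matching photograph-vs-specimen
agreement), and a configurable fraction of records inherit the previous
record's coordinates, reproducing the failed-GPS-fix duplication artifact.
The default truth-model coefficients are field-realistic urban-grey
odds ratios (e.g. UHI 0.719 per °C for pink vs yellow), so parameter
recovery is checked against effect sizes of the magnitude field surveys
report.

An optional short-range spatially correlated logit perturbation induces RSA:
a Gaussian field with exponential covariance, sd 0.5 and range 500 m by
default (the range is a modelling choice; only "below ~500 m" is
constrained by the phenomenon being emulated). It is drawn exactly via
Cholesky factorisation at the record locations, which is $O(n^3)$ — the
package's spatial-noise study conditions therefore use 2,000-5,000 records,
and the pipeline caps Moran's I at a seeded subsample (default 2,000)
because the weight matrix is $O(n^2)$ memory.

What the generator does *not* emulate: validator disagreement structure
beyond an exchangeable confusion matrix, non-uniform seasonal effort, real
raster autocorrelation structure, and any genetic/demographic process —
morphs are sampled phenotypically from the logit truth. Passing tests
therefore demonstrate that the estimators recover the data-generating
process they assume, not that the field data satisfy those assumptions.

`generate_detectability_experiment()` models shell discovery as exponential
times (constant search hazard per colour) censored at the 600 s search
limit — the simplest hazard consistent with a product-limit analysis.
Kaplan-Meier curves use the simultaneous-death convention for ties;
checkpoint compositions default to 150/300/450/600 s.

## Exact multinomial test

Classification agreement between photographs and specimens is tested with
an exact multinomial goodness-of-fit test: all compositions of $n$ counts
into $k$ cells are enumerated (Monte Carlo beyond $n = 200$), and two
p-values are always reported because two orderings are in common use:
`p_prob` (total probability of outcomes no more probable than the observed
one, the classical ordering, which reduces to the exact binomial test at
$k = 2$) and `p_distance` (total probability of outcomes at least as far
from expectation in Euclidean distance on proportions). The distance metric
is a documented choice — reporting both makes the ambiguity visible rather
than hiding it. Ties are resolved with a $10^{-12}$ relative tolerance.

## Simulation sizes used by the test suite

The package's own verification experiments (chosen once, as study
conditions): parameter recovery uses 20 replicates of n = 8,000 clean
records with every coefficient checked against ±3 SE; the
spatial-correction experiment uses 20 replicates of n = 5,000 records with
street-scale UHI texture (sd 0.40), neighbourhood-scale observer clusters
(sd 1 km, five centres per city plus a rural lattice), spatial noise sd
0.5, and smooths of 6/6/4 marginal and 30 tensor effective df, asserting
that the refit strictly reduces residual global Moran's I while the UHI
term stays significant; Moran's I is verified against brute-force double
loops and its permutation null; Wilson coverage is checked on 2,000
simulated binomials.

## Known limitations

* The smoothed refit's Wald p-values ignore smoothing-parameter uncertainty
  (the EDF targets are fixed by configuration, so this is the usual
  fixed-df caveat).
* `predict()` on new data is provided for the parametric model only; the
  smoothed model predicts on its training records.
* Moran's I and the exact MVN noise field hold dense matrices; both are
  intended for the low-thousands scale, with seeded subsampling above it.
* The banding-code dialect (positional digits plus parenthesised fusion
  runs) is one convention; codes from other dialects must be translated
  before import.
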