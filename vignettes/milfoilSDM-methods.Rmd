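---
title: "Methods: occurrence, pseudoabsence and abundance SDMs for Eurasian watermilfoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence, pseudoabsence and abundance SDMs for Eurasian watermilfoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Species distribution models (SDMs) for invasive species are usually judged by
*discrimination accuracy* — how well predicted suitability separates presences
from (pseudo)absences, summarised by AUC, the true skill statistic (TSS) and
Cohen's kappa. When true absences are unavailable, unsampled locations are
substituted as *pseudoabsences*, and discrimination metrics can then reward a
model for learning where sampling happened rather than where the species can
live. An alternative yardstick is *functional accuracy*: the correlation
between predicted suitability and independently observed local abundance. This
package implements, end to end, the comparison of both yardsticks across five
response-data constructions for Eurasian watermilfoil (*Myriophyllum
spicatum*, EWM) in a lake-rich landscape:

* **PA** — presence–absence over surveyed lakes (true absences),
* **PO_random / PO_distant / PO_proximal** — the 184 presences plus 284
  pseudoabsences drawn from unsurveyed lakes: uniformly at random, only from
  outside the convex hull of invaded lakes, or only from inside it,
* **ABUNDANCE** — frequency of occurrence (the fraction of within-lake
  point-intercept sample points with a detection, in [0, 1]) over the
  surveyed lakes.

Each dataset is modelled by a random forest (classification for occurrence,
regression for abundance; 500 trees, `sqrt(p)` or `p/3` features per split),
with and without an inverse-distance-weighted spatial autocovariate — ten
model variants in all.

## The simulated landscape

All of this is exercised on seeded virtual landscapes rather than the
original survey data, so every stage is testable. `simulation_config()`
defaults reproduce the study design: 184 + 284 surveyed and 801 unsurveyed
lakes over a 600 × 560 km planar extent, with 11 environmental covariates
whose means, SDs and ranges match the published summary table (CDOM,
chlorophyll-a, conductance, growing degree days from water temperature, lake
depth, lake size, pH, phosphorus, road density, Secchi depth, stream
density).

Covariate surfaces are distance-decay kernel mixtures of white noise
(150 random knots, Gaussian kernel at each covariate's `range_km`), rescaled
to the target moments and clipped to the observed ranges. Two spatial-scale
choices matter and are deliberate:

* **Growing degree days carry a deterministic north–south gradient**
  (`ns_gradient = 0.98`), because thermal habitat across a five-degree
  latitude span is dominated by latitude. This is what gives the species a
  geographically compact southern range, which in turn is what makes the
  *distant* and *proximal* pseudoabsence strategies genuinely different.
* **The water-chemistry covariates get short correlation ranges (25–30 km).**
  If inert covariates are generated as very smooth fields they become
  latitude surrogates: a random forest will use them as stand-ins for
  geography and variable-importance rankings lose their meaning. Lake
  chemistry varying at the scale of a few tens of kilometres is both
  realistic and keeps the importance analysis interpretable.

True suitability uses saturating-ramp transforms with plateaus mirroring the
fitted response shapes of the original models — growing degree days
plateauing near 1,750 degree-days, lake depth near 30 m, road density near
75 m/ha — combined through a logistic link. The thermal ramp (weight 20) acts
as a *gate* that multiplies the depth and road contributions rather than
adding to them. We first implemented the plain additive combination and found
it structurally unworkable at the study's sample sizes: rare
high-depth/high-road lakes north of the thermal band become presences, the
presence convex hull then inflates until almost every unsurveyed lake is
inside it, and a draw of 284 distant pseudoabsences is impossible for most
seeds. With the gate, thermally unsuitable lakes stay unsuitable, the
presence hull is a stable southern band, and both hull cells hold well over
284 candidate lakes for almost every seed (the proximal cell can still fall
short on roughly 1 in 30 seeds, in which case the draw fails loudly rather
than topping up from the other cell). `gate = NULL` restores the additive
link.

Occurrence is Bernoulli in true suitability, redrawn (up to
`resample_budget` times) until at least 184 successes and 284 failures exist;
surveyed lakes are then sampled at random from each class, so by default
there is no survey bias (a `survey_bias` knob exists but is off). Abundance
for presences is `0.8 * s * u` with `u ~ Beta(1.3, 2.2)` — a right-skewed
multiplier with mean below one half — observed through a binomial
point-intercept sample of 100 points. Suitability therefore *bounds*
abundance from above without determining it, which is exactly the
wedge-shaped abundance–suitability pattern the evaluation module measures;
the 0.8 cap matches the observed upper end of frequency of occurrence. A
presence whose binomial draw is zero is redrawn once and floored at one
detection so that presence always implies positive frequency.

Lake placement is uniform by default, with a Thomas-process option
(`placement = "clustered"`, 10 km cluster scale — the same scale used for
spatial blocking, adopted as the default in the absence of a stated lake
clustering intensity).

## Spatial statistics

* **Weights**: distance-band neighbourhoods with inverse-distance weights,
  row-standardised; `radius = "auto"` is the maximum nearest-neighbour
  distance (the smallest band leaving nobody neighbourless). Duplicate
  coordinates are refused with advice to jitter.
* **Autocovariate**: the row-standardised spatial lag of the response,
  computed *once on the full dataset before any train/test split* — it is
  treated as just another predictor, as in the original analysis. The
  information leakage this implies for held-out evaluation is intentional
  and is announced via a message whenever the column is added.
* **Moran's I**: the standard cross-product statistic with one-sided
  significance from value permutations (999 by default,
  `p = (1 + #[I_perm >= I_obs]) / (1 + n_perm)`); permutation rather than the
  normal approximation because residual diagnostics are run at a few hundred
  lakes.
* **Pair correlation function**: ring-count estimator against the CSR
  expectation at the window's intensity, with no edge correction — it is
  used to choose a block scale, where modest boundary bias cannot change the
  answer materially. Tests accordingly read it at radii small relative to
  the window.
* **Spatial blocks**: square tessellation; whole blocks are allocated to
  folds by randomised greedy balancing of per-fold lake counts, so fold
  sizes differ by at most one block's occupancy. Defaults: 10 km blocks
  (5 km for PO_proximal, whose pseudoabsences are spatially restricted) and
  5 folds.

## Evaluation

Discrimination accuracy is computed under three schemes: *nonindependent*
(random stratified 5-fold CV, repeated — 50 iterations by default — and
averaged over all fold-level estimates), *quasi-independent* (one stratified
70/30 split) and *spatially blocked* (folds from the block tessellation).
TSS and kappa need a threshold: we use the sensitivity–specificity equality
rule, selected among midpoints of consecutive sorted unique scores with
guards beyond both ends, ties broken by larger sensitivity + specificity and
then by the lower threshold. The threshold is always estimated on the
*training* fold's out-of-bag predictions and applied to the held-out fold:
estimating it on test data would bias TSS upward even for uninformative
models, and in-sample (non-OOB) forest predictions are too close to the
labels to calibrate a cutoff. Folds whose held-out part is single-class are
skipped with a warning; an evaluation where at least half the folds are
skipped fails. The "combined average" is the arithmetic mean of the three
schemes' values.

Functional accuracy correlates predicted suitability with observed frequency
of occurrence over surveyed lakes — Pearson and Spearman, once including
zero-abundance lakes (`r_all`, `rho_all`) and once excluding them
(`r_nonzero`, `rho_nonzero`), since zeros reward mere discrimination and
inflate the correlation. Predictions come from the final full-data model,
using out-of-bag votes for lakes in its training data and ordinary
predictions elsewhere (e.g. true absences under a presence-only model, whose
spatial lag is computed against the model's own lakes and responses).

The wedge is quantified by linear quantile regression of frequency of
occurrence on suitability at the 50th, 75th and 90th percentiles;
`wedge_strength` is the 90th-minus-50th slope difference. The check-loss
minimiser is computed by iteratively reweighted least squares on a smoothed
check loss followed by a Nelder–Mead polish of the exact loss, keeping
whichever candidate (including the least-squares start) attains the lowest
exact check loss; on `y ~ U(0, x)` data the fitted slope at level tau
recovers the closed-form value tau.

## Sizes used by the tests and the acceptance script

Pipeline-level unit tests run a reduced landscape (60/80/300 lakes, 80-tree
forests, one CV iteration); the acceptance suite and `scripts/acceptance.R`
run the full 184/284/801 design with 300-tree forests and 2 CV iterations
for the replicated-seed contrasts, and 500 trees elsewhere. Replicates (20
in the acceptance tests, 12 in the script) are medians over consecutive
seeds; these sizes are the package's reporting choices and are stated in the
outputs' `n` fields.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes — spatially
autocorrelated covariates, a compact invaded range inside a broader survey
frame, right-skewed wedge-shaped abundance, optional residual spatial
structure (`latent_spatial_sd`, used at 6 logits / 100 km range as the
"strong residual structure" condition in tests) — but not the original
data: real surveys are biased, covariates are cross-correlated, and
detection is imperfect within lakes. Numerical agreement with the published
real-data table is therefore out of reach by design; what the tests
establish is the qualitative behaviour of the method — that distant
pseudoabsences maximise discrimination accuracy while presence–absence data
maximise functional accuracy, that zeros inflate abundance–suitability
correlations, that the autocovariate dominates importance when residual
spatial structure exists, and that the wedge's upper quantile slopes exceed
its median slope.

## Known limitations

* Planar coordinates only; no geodesic distances or CRS handling.
* The pair correlation estimator is uncorrected at the boundary.
* Quantile fits are single-predictor lines, as in the original analysis.
* The proximal pseudoabsence draw can be infeasible on rare seeds (above).
* Importance is held-out permutation importance; out-of-bag importance from
  the forest itself will differ in scale, though rarely in ranking.
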