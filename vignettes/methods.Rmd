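---
title: "Methods: normative w-scores, spatial surrogate nulls, and gene–atrophy inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative w-scores, spatial surrogate nulls, and gene–atrophy inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imtx)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
the acceptance script does not itself compute.

# The scientific problem

Neurodegenerative disease does not atrophy the brain uniformly: some regions
lose grey matter early and severely, others are spared. One candidate
explanation is molecular: regions that normatively express more of the genes
involved in producing or clearing the relevant pathological proteins may be
more vulnerable. Testing this requires relating two maps over the same
parcellation — a regional atrophy map derived from patient MRI, and
normative regional expression profiles derived from post-mortem donor
microarrays — while respecting the fact that both maps are spatially smooth,
so regions are not independent observations.

# Normative w-score model

For each region $r$, volumes of healthy controls are modelled as

$$ v_{ir} = \beta_{0r} + \beta_{1r}\,\mathrm{TIV}_i + \beta_{2r}\,\mathrm{age}_i
   + \beta_{3r}\,\mathrm{sex}_i + \varepsilon_{ir},\qquad
   \varepsilon_{ir} \sim N(0, \sigma_r^2), $$

fitted by OLS (`fit_normative()`). A patient's w-score is the covariate-
adjusted deviation in control residual-SD units:

$$ w_{ir} = \frac{v_{ir} - \hat v_{ir}(\mathrm{TIV}, \mathrm{age},
   \mathrm{sex})}{\hat\sigma_r}. $$

Choices worth stating:

* **Residual SD denominator is $n - 4$** (intercept + 3 covariates). The
  convention is not dictated by the model description; $n-4$ makes
  $\hat\sigma_r^2$ unbiased and matches `summary.lm`'s sigma, which the
  tests assert.
* **Sex is coded F = 1, M = 0** throughout package and simulator; any fixed
  numeric coding gives identical w-scores, but the two must agree.
* **Atrophy tests are one-sample t-tests of patient w-scores against 0**, on
  the argument that the w-score definition already absorbs the control
  distribution (controls scored under their own model have mean exactly 0).
  A Welch two-sample test on raw volumes is provided as
  `region_atrophy_tests_volumes()` for sensitivity analysis.
* w-scores are invariant to affine rescaling of volume units applied jointly
  to controls and patients (tested), so ml vs cm³ conventions are harmless.

# Expression processing

`process_donor_expression()` follows the standard donor-microarray reduction
chain: intensity-based probe filtering (discard when below background in
≥ 50% of samples pooled across donors — *pooled* rather than per-donor, a
genuinely open reading; pooling uses all evidence and is flagged for
sensitivity testing), differential-stability probe selection (mean pairwise
Spearman correlation of region-averaged profiles across donor pairs; Spearman
is the documented default of the toolbox this emulates), inclusive 2-mm
nearest-centroid sample assignment (a parcel-level proxy for voxel
membership; ties broken toward the lower region index), nearest-sample
interpolation for empty regions, scaled robust sigmoid normalization

$$ y = \frac{1}{1 + \exp\!\big(-(x - \mathrm{med}(x)) / (\mathrm{IQR}(x)/1.35)\big)} $$

min-max rescaled to $[0,1]$ (the 1.35 makes IQR a consistent SD estimator
under normality; quartiles use linear interpolation, R type 7), applied
first to each sample across genes and then to each gene across samples, and
finally unweighted donor averaging.

One property deserves emphasis because it constrains testing: with a small
gene panel, the per-sample cross-gene normalization is close to a rank
transform of a handful of values, and it **does not preserve each gene's
ranking across samples**. A noise-free single-gene donor set passes through
with Spearman correlation exactly 1 (tested); a noise-free multi-gene set
does not, and this is a property of the stated processing order, not an
implementation artifact. On realistic panels the distortion is mild, and
the end-to-end pipeline invariants (no missing cells, $[0,1]$ bounds, exact
donor-mean aggregation) always hold.

Probe reannotation against array manifests is out of scope; the probe→gene
map is an input.

# Spatially constrained surrogate maps

Regression of one brain map on another across $n$ regions with i.i.d.
assumptions overstates evidence, because spatial autocorrelation reduces the
effective sample size. The package's null model generates surrogate maps
that preserve the empirical variogram of the predictor map while
randomizing its arrangement (`generate_surrogates()`):

1. randomly permute the map values;
2. smooth the permutation with an exponential-decay kernel over the $k$
   nearest neighbours, for each $k$ in {3, 5, 8, 12, 20, 30, $n-1$};
3. regress the empirical variogram on the smoothed map's variogram,
   $\gamma_{emp} \approx \beta\,\gamma_{smooth} + \alpha$;
4. keep the $k$ minimizing the SSE;
5. form $\sqrt{|\beta|}\,\mathrm{smoothed} + \sqrt{|\alpha|}\,z$ with
   $z \sim N(0, I)$;
6. (resample mode, default) rank-remap onto the original value multiset, so
   every surrogate has exactly the observed values.

Numerical choices:

* **Variogram**: $\gamma(h) = \frac{1}{2N_h}\sum_{(i,j)\in h}(x_i - x_j)^2$
  over 25 equal-count distance bins — quantile bins keep per-bin pair counts
  stable for a 58-region parcellation (1653 pairs, ~66 per bin).
* **Fit range**: the $\alpha, \beta, k$ fit is evaluated over the shortest
  32% of pair distances, on a finer 10-bin equal-count binning of those
  pairs (`fit_fraction = 0.32`). Autocorrelation lives at short range;
  fitting the full distance range lets the many long-distance pairs swamp
  it, producing under-smoothed surrogates, while fitting only the shortest
  quarter over-smooths. The default is fixed at the centre of the region
  where the package's own calibration suite holds: when the "observed"
  atrophy map is itself one surrogate draw, the spatial p rejects at
  0.05 ± 0.02, both for the per-gene regression (500 draws) and for the
  random-forest global fit (200 repetitions), while naive parametric OLS
  p-values on the same draws reject at an inflated rate (~0.10 in this
  geometry).
* **Add-one p-values**, $p = (1 + \#\{|t_{null}| \ge |t_{obs}|\})/(1 + N)$,
  never return 0 at finite $N$. Two-sided by default for regressions (the
  slope sign is not pre-specified); one-sided (greater) for forest fit and
  importances, which are only meaningful in one direction.
* Surrogates are generated **for the predictor (gene) maps**, not for the
  atrophy outcome; the forest module reuses the same cached ensembles. An
  outcome-surrogate mode exists behind a flag for sensitivity analysis.

# Per-gene association and FDR

`fit_gene_regression()` is simple OLS of mean w-scores on one gene's
expression across regions ($df = n - 2$); expression enters on its
post-normalization $[0,1]$ scale, so a slope of −0.5 means half a w-score
unit between the least- and most-expressing region (a z-scored mode exists
behind a flag). `bh_fdr()` implements the Benjamini–Hochberg step-up rule
directly and is cross-checked against `p.adjust(..., "BH")` and a hand-worked
list. FDR control on null panels is verified over 500 simulated 12-gene
panels.

# Random-forest regression

No random-forest package is assumed; `src/forest.cpp` implements bagged CART
regression trees with the conventions the field's reference implementation
popularized: `ntree = 500`, `mtry = floor(p/3)` (4 for 12 genes),
`nodesize = 2` (nodes at or below this size are not split), variance-
reduction splits at midpoints between distinct sorted values, out-of-bag
(OOB) prediction, and permutation importance (mean increase in a tree's OOB
MSE when one predictor's OOB values are permuted, averaged over trees,
reported raw and as % of OOB MSE; significance is computed on the raw
scale). Two global-fit summaries are reported because they answer slightly
different questions and differ in published tables: `pct_var`
$= 100\,(1 - \mathrm{OOB\ MSE}/\mathrm{Var}(y))$ with the **population**
variance (denominator $n$, the reference convention; asserted to 1e-6 in
tests), and `r2_oob`, the squared correlation between OOB predictions and
the outcome. All randomness flows through R's RNG, so a seed makes fits
bit-reproducible; null iteration $i$ refits with seed $\mathrm{master} + i$
(a documented counter scheme).

The forest null replaces **every** gene's map with an independently drawn
surrogate of that gene while the atrophy map stays fixed. Note a structural
property verified by the calibration suite: this null compounds the
surrogate approximation across all 12 predictors, so its calibration is a
much stricter test of surrogate fidelity than the single-gene regression
null.

# The synthetic world

`make_atlas()` places 41 cortical centroids on a 70-mm left-hemisphere
shell (Fibonacci lattice + 2-mm jitter, classified into frontal / temporal /
parietal / occipital by position), 6 subcortical centroids within 25 mm of
centre, 9 cerebellar centroids in a posterior-inferior cluster, and 2
brainstem centroids on the inferior midline — reproducing the
cortex-vs-subcortex contrasts that drive real expression gradients without
using real coordinates.

`simulate_sa_map()` draws zero-mean unit-variance Gaussian fields with
covariance $\exp(-d/\ell)$; $\ell = 40$ mm is the reference length scale
throughout. `simulate_expression()` min-max rescales such maps to $[0,1]$
per gene.

`simulate_cohort()` draws age $\sim N(69, 8.6^2)$ years, TIV
$\sim N(1550, 150^2)$ ml and sex F with probability 0.274 — the demographic
profile of the cohorts this design emulates. Control volumes follow
per-region baselines of 6–12 ml scaling proportionally with TIV, declining
~0.2% per year of age, with i.i.d. Gaussian noise of SD 0.5 ml (the
per-region control variance is not observable from published tables; these
are free parameters fixed once and recorded in `default_covariate_model()`).
Patient volumes are additionally shifted by
$\sum_g \beta_g\, e_g(r)\, \sigma_r$ — effects are injected in residual-SD
units so recovered w-score slopes are directly comparable to the ground
truth — plus one independent spatially autocorrelated noise map per patient
(SD 0.2 w-units, length scale 40 mm), representing disease heterogeneity
that is spatially structured rather than white.

`simulate_donors()` scatters samples around centroids (SD 0.8 mm; ~15% of
regions unsampled per donor by default, and a configurable fraction of
samples displaced 5–9 mm so assignment and interpolation are exercised),
builds probe intensities as shared gene signal (mean 7, SD 1,
log2-intensity-like) + per-probe offset + noise over a background of mean 4,
and generates a requested fraction of probes below background.

What a green test does **not** establish: the generator has linear covariate
effects, Gaussian noise and a single length scale; real MRI volumes have
scanner effects, non-Gaussian tails and heteroscedastic regions, and real
expression maps have gradients not captured by a stationary field. Tests on
this world validate the statistical machinery (calibration, recovery,
control), not published cohort effect sizes.

# Tolerances and degenerate inputs

* Zero-IQR normalization slices fall back to rank scaling with a message;
  fully constant slices are an error.
* Constant maps cannot be surrogate-matched (error); constant predictors
  are a regression error; constant gene columns yield flagged `NA`
  correlations.
* Zero-variance regions in the t-test table are flagged `NA` with a warning.
* Exact ties in sample assignment go to the lower region index; rank-remap
  ties use first-occurrence order — both deterministic.
* Singular normative designs abort naming the offending covariate.

Recovery tolerances in the test suite account for Monte-Carlo error
explicitly: with 300–500 patients the per-region mean-w SD is ~0.05–0.06
(patient noise $\sqrt{(1 + 0.2^2)/n_p}$ plus normative-model error
$\approx \sqrt{1/n_c}$ in w-units), so band checks of ±0.1 / ±0.15 are
asserted for ≥ 90–95% of regions plus an RMS bound, rather than for the
maximum over 58 simultaneous estimates, and the null-cohort check also
bounds the grand mean (±0.03).

# Scaling of the test suite

The suite's stated Monte-Carlo draw counts are kept (500 calibration draws, 200 forest
repetitions, 100 recovery replicates, 500 FDR panels); per-draw null
ensemble sizes — not pinned anywhere — are 199 surrogates for regression and
FDR checks and 99 for forest calibration (with `ntree = 100` there), which
keeps the whole suite inside a laptop-scale time budget while leaving the
achievable rejection levels exact (add-one p at 99 nulls has an atom exactly
at 0.05). Production defaults remain 10000 surrogates per gene and 1000
forest nulls (`analysis_config()`).

# Known limitations

* Nearest-centroid assignment is a proxy for voxel-level parcel membership;
  small or oddly shaped parcels are treated as spheres.
* Surrogate fidelity is approximate at the shortest distances; the forest
  null inherits a compounded version of that approximation (calibrated here,
  but worth re-checking for very different geometries or length scales).
* The donor-normalization order makes multi-gene rank preservation
  approximate by construction (see above).
* No centre-harmonization covariates, no longitudinal w-scores, no
  voxel-space simulation, no spin-based nulls.
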