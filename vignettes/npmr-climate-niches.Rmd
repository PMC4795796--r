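---
title: "Climate niche modelling with nonparametric multiplicative regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate niche modelling with nonparametric multiplicative regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinyon)
library(dplyr)
```

## The model

`pinyon` models the probability that a species (or an intraspecific
lineage, such as a mitochondrial haplotype) occurs at a location as a
smooth, non-parametric function of climate. The estimator is
nonparametric multiplicative regression (NPMR): the response at a target
point $t$ is the kernel-weighted local mean of the observed binary
occurrences,

$$\hat p(t) \;=\; \frac{\sum_i w_i(t)\, y_i}{\sum_i w_i(t)},
\qquad
w_i(t) \;=\; \prod_{j=1}^{k} \exp\!\left(-\frac{(x_{ij}-t_j)^2}{2\sigma_j^2}\right),$$

where $j$ indexes the model's predictors and $\sigma_j$ (the
*tolerance*, in the predictor's own units) controls how quickly an
observation's influence decays along axis $j$. The multiplicative form
means a point is a strong neighbor only if it is close on *every*
predictor — interactions are automatic rather than parameterised. The
local mean guarantees $\hat p$ never leaves the observed response range.

Model quality is measured by **logB**, the log10 likelihood ratio of the
model's *leave-one-out* (LOO) estimates against the naive model that
predicts the average occurrence frequency $\bar y$ everywhere:

$$\log B \;=\; \log_{10} L(\hat p^{\mathrm{LOO}}) - \log_{10} L(\bar y).$$

Because every estimate entering the likelihood excludes the target's own
observation, logB already penalises overfitting: a wiggly model that
chases individual points scores poorly. logB is reported raw (it grows
with sample size; models on different $N$ are not comparable), with the
per-sample-unit variant available as `logB_per_n` in `glance()`.

Two guard rails keep local means meaningful:

* **minimum average neighborhood size** — the mean over points of the
  summed LOO kernel weights ($N^*$, an effective local sample size) must
  be at least 5% of $N$ (1% during aggressive fine-tuning);
* **minimum local weight** — a single estimate is only valid when its
  neighborhood holds at least one expected-observation equivalent
  ($\sum_i w_i \ge 1$); otherwise the point is *unestimable* and, by
  convention, contributes the naive probability to the likelihood so
  that model and naive likelihoods stay on the same $N$. The likelihood
  clamp is $\varepsilon = 10^{-6}$, and kernel weights below $10^{-12}$
  are truncated to zero so neighborhood counts are stable across
  platforms.

## Model selection

`free_search()` adds predictors forward-stepwise. At each step every
unused candidate is tried at every tolerance on a range-relative grid
(default 5%, 10%, ..., 100% of the candidate's observed range — a
scale-free default, since tolerances have predictor units), with the
tolerances of already-accepted terms frozen. The improvement rule uses a
percent threshold (2% for data-rich models, 5% as the conservative
small-sample rule):

* step 1: the best one-term model is accepted only if its logB reaches
  the threshold percentage *of the naive log-likelihood magnitude*.
  A percent improvement over the zero baseline is otherwise undefined,
  and requiring merely logB > 0 is measurably under-calibrated: across
  many (candidate × tolerance) evaluations the maximum LOO logB of pure
  noise fluctuates above zero frequently, while expressing the same
  percent rule against $|\log_{10} L(\bar y)|$ restores the intended
  null behaviour (see the calibration test);
* step $k{+}1$: the best extension must improve logB by at least the
  threshold percent over the incumbent model.

The search also refuses to grow past a data-to-predictor floor of 10
sample units per term, counted against total $N$ — a presence-based
count would be inconsistent with fitted two-predictor models on as few
as three presences, which the haplotype-style datasets require. Ties are
broken deterministically (higher logB, then candidate order, then the
smaller tolerance).

`fine_tune()` then re-optimises all tolerances jointly on a refined grid
(2.5% steps) with the neighborhood floor relaxed to 1% of $N$. A full
joint grid is exponential in the number of terms, so the implementation
uses cyclic coordinate descent, sweeping terms until no single-tolerance
move improves logB; this satisfies the required contracts (the result
never has lower logB than the input, and a model already at its optimum
is returned unchanged). `select_with_topography()` applies the guarded
comparison for elevation/terrain predictors: the topography-inclusive
search must beat the climate-only model's logB by at least 5%, otherwise
the climate-only model stands.

## Evaluation

`evaluate_npmr()` and `external_validate()` report:

* **AUC** (Mann–Whitney form, half-credit for ties): probability a
  random presence outscores a random absence;
* **xR²** $= 1 - \sum(y-\hat p)^2 / \sum(y-\bar y)^2$ from LOO
  estimates: at most 1, no lower bound, 0 for the naive predictor;
* **sensitivity Q**: each term is nudged by ±5% of its range and the
  mean absolute change in the (non-LOO, un-tuned) estimates, relative to
  the response range, is divided by the nudge fraction — so $Q = 1$
  means the response moves one-for-one with the predictor in
  range-relative units. The un-normalised variant is exposed as `q_raw`;
  published Q tables (values roughly 0.01–0.62) match the normalised
  scale. Predictors not in the model have $Q = 0$ by construction.
* **mean residuals by class** ($y - \hat p$, presences and absences
  separately): sparse presences with low estimates give large positive
  presence residuals and slightly negative absence residuals — the
  signature of rare-event local-mean models.

## Bioclimatic predictors

`derive_predictors()` computes the candidate variables from monthly
normals (temperatures in °C, precipitation in mm):
annual/growing-season log precipitation (`LogMAP`, `LogGSP`; log10),
coldest/warmest month means (`MTCM`, `MTWM`), seasonal precipitation
sums (`SUMP` Jul–Aug, `WINP` Nov–Feb), the growing-season precipitation
ratio `PRATIO` = GSP/MAP, the summer balance `SMRPB` =
(Jul+Aug+Sep)/(Apr+May+Jun), the summer moisture index `SDI` =
√GSDD5/GSP, the summer heat:moisture index `SHMI` = MTWM/log10(Jul–Sep
precipitation), and the temperature-differential index `TDIFF_LogGSP` =
(MTWM−MTCM)/LogGSP.

Degree-day and freeze-date surfaces are normally distributed as
pre-computed products; when only monthly normals are available the
package approximates them, and pre-computed columns always take
precedence when present:

* `DD5` and `MMINDD0` by month-length accumulation
  ($\sum_m d_m \max(0, \bar T_m - 5)$ and
  $\sum_m d_m \max(0, -T^{\min}_m)$, on a 365-day year);
* `SDAY` as the Julian day on which daily minimum temperature —
  linearly interpolated between mid-month anchors — last rises through
  0 °C during January–July (1 if it never freezes; missing if frozen
  through July);
* `GSDD5` as DD5 restricted to the frost-free window from SDAY to the
  first interpolated autumn freeze, with partial months prorated by the
  fraction of their days inside the window.

Ratios and logs never emit infinities: non-positive denominators flag
the field missing with a warning, and the SHMI log argument is floored
at 1.0001 mm. `TRIX` multiplies the terrain ruggedness index by a
"converted longitude" that rescales longitude linearly to [1, 2] across
the configured study extent (west → east). The exact transform behind
the published eastward-weighting is not stated anywhere we could find;
the linear [1, 2] rescale is an explicit, configurable convention that
reproduces the described qualitative effect, and out-of-extent
longitudes are clamped with a warning. Temperature seasonality follows
the WorldClim bio4 convention — 100 × the standard deviation of the 12
monthly means in its population form (divide by 12, so an alternating
−10/+10 year gives exactly 1000); the sample-SD variant is available via
`sample_sd = TRUE`.

## Dataset construction

Occurrence datasets for the variety- and haplotype-style analyses are
assembled from point samples with great-circle geometry throughout
(haversine, 6371 km radius — a degree-space threshold would distort
with latitude):

* `sample_background()` places uniform random points on a mask with a
  minimum pairwise separation (default 1 km), seeded and reproducible;
* `label_by_mask_agreement()` accepts a presence only where two
  independent vegetation layers agree it is inside the mapped
  distribution, an absence only where both agree it is outside, and
  drops disagreements — the two layers are supplied as plain binary
  masks, since the overlay logic rather than any particular GIS product
  is what matters;
* `thin_points()` enforces the 1 km separation greedily in record
  order. Exact maximum-cardinality thinning is NP-hard; the greedy kept
  set is maximal (no dropped point is separated from all kept points)
  and deterministic, which makes published counts reproducible;
* `assign_variety()` labels each presence with the variety of its
  nearest sampled haplotype location (haplotypes 1, 5, 8, 9, 10 →
  Pacific; 2, 3, 4, 6, 7 → Rocky Mountain), exact ties resolved to
  Pacific and logged;
* `build_haplotype_dataset()` implements the haplotype model design:
  presences are the (thinned) locations of the focal haplotype,
  absences are the other variety's haplotype locations — excluding
  records whose `Exclude` field names the focal haplotype (shared
  populations) — plus a seeded random draw of non-ponderosa background
  absences (default 3000). The randomisation scheme behind the
  published "3000 randomly selected" absences is unprinted; a seeded
  uniform draw without replacement is used.

Readers and writers for the supplementary CSV schemas preserve the
published conventions (variety codes `P`/`S`/`-`; haplotype 0 for
non-ponderosa locations; semicolon-separated `Exclude` lists; the
post-10,000th-record block of extra absences reserved for glacial
reconstruction, exposed via the `lgm_only` flag). Coordinates are
written at fixed 6-decimal precision (~0.1 m) so that emitted files are
byte-stable under read/write round trips.

## Mapping and hindcasting

`predict_grid()` evaluates a fitted model at every cell of a predictor
grid (non-LOO, against the full training data); cells missing a
predictor or falling outside every training neighborhood are NODATA.
`apply_display_floor()` blanks cells below a display threshold (the
published maps use 0.135), and `bin_probabilities()` classifies into
equal intervals over [0, max] — bins are left-closed with the top bin
closed, and the maximum is reported alongside, matching the published
map legends. Grids move through ESRI ASCII (`.asc`) files via
`read_ascii_grid()`/`write_ascii_grid()`; no binary raster formats are
required anywhere in the pipeline.

`response_curve()` fits a fresh one-term model on a single predictor
(its tolerance found by the same free search) and evaluates it across
the predictor's range — the single-variable response presentation used
for the published variety and haplotype curves. A partial-dependence
mode (`partial = TRUE`) instead slices an existing multi-term fit with
the other predictors held at their training means; whether the
published curves were refits or slices is not stated, so the refit is
the default and both are available.

For glacial-maximum hindcasting, `substitute_predictor()` removes the
elevation term — contemporary elevation–climate relationships do not
transfer across glacial cycles — and replaces it with a
temperature-based variable derivable in both periods (warmest-month
temperature, or bio4 temperature seasonality), re-searching only the
replacement's tolerance with all retained tolerances frozen;
re-searching is the only self-consistent option since the replacement
has different units and range than the removed term. The refitted
model's contemporary diagnostics come back with it for revalidation.
`augment_absences()` appends extra absence blocks (the published
Rocky-Mountain hindcast added 1605 eastern points), and `project_lgm()`
applies the model to paleoclimate grids with identical estimator
semantics — the model stays fitted on contemporary climate; only the
cell predictor values change.

## The virtual-species generator

`generate_climate_surface()` builds a deterministic synthetic scene:
smooth seeded Gaussian-bump fields shape elevation, terrain ruggedness
and month-by-month temperature (seasonal cycle + latitudinal gradient +
6.5 °C/km lapse) and precipitation. Precipitation interpolates from a
winter-dominated profile at the western edge to a summer-dominated
profile at the eastern edge, so `PRATIO` climbs west → east — the
steep seasonal precipitation cline that separates the two varieties'
climate niches in the real landscape. The default scene is 100 × 100
cells at 0.01° (~1 km) spacing, which keeps the full end-to-end
recovery study at desk scale.

`virtual_niche()` defines a known truth in the same
multiplicative-Gaussian family the estimator assumes — deliberately, so
parameter recovery is a meaningful oracle — and
`sample_occurrences()` draws labelled points with the true probability
stored alongside. `bimodal_niche()` provides a deliberately
misspecified two-optimum truth for qualitative stress-testing (the
response curve of such data shows both modes). What the generator does
*not* emulate: spatial autocorrelation of the residual (occurrences are
independent Bernoulli draws given climate), observation error in the
predictor surfaces, and dispersal limitation — so green recovery tests
demonstrate estimator correctness, not field-data performance.

The reference ("flagship") study conditions, fixed once: a two-term
niche on `PRATIO` and `MTWM` with optima at the scene's 35% and 60%
quantiles, widths of 10% of each predictor's range, peak probability
0.8, 1000 training and 500 holdout points. At these widths the *true*
probability surface separates presence from absence with AUC ≈ 0.93 and
prevalence ≈ 5% — a strong but realistically sparse signal comparable
to the deposited datasets. The candidate set offered to the search is
the two true predictors plus five decoys screened to pairwise
|r| < 0.75 against the truth (`SMRPB`, `WINP`, `LogMAP`, `TRI`,
`TRIX`); on these synthetic surfaces, as with real bioclimatic
variables, several candidates (`LogGSP`, degree-day sums, `SDAY`) are
near-duplicates of the true predictors (|r| > 0.97), and "selected the
true predictor rather than its 0.99-correlated alias" is not a
well-posed recovery question.

Two measurement-resolution points about the recovery checks. The
tolerance grid steps at 5% of a predictor's range, so a recovered
tolerance is only resolvable to one grid step; the factor-of-2 recovery
band is therefore measured against the grid value nearest the true
width — the closest tolerance the search could possibly have expressed.
(The cross-validation-optimal bandwidth of a local-mean estimator sits
genuinely below the niche width, typically around half of it here, so
this lower edge of the band is exercised routinely.) Similarly the peak
of a response curve estimated from ~55 presences cannot be located to
0.5% of the predictor's range, so the peak-recovery check evaluates the
curve on a grid whose step (2.5% of range) matches the tolerance-search
resolution rather than the 200-point display default.

The null-calibration study shuffles the flagship responses and requires
the search to return the empty model in at least 95 of 100 replicates.
Calibration is assessed at the full flagship size (n = 1000): local-mean
models on very sparse shuffled presences (e.g. 14 presences in a 250-row
subsample) can exploit chance clumps of presences in predictor space,
and guarding that regime is exactly what the conservative 5% rule and
parsimony controls are for.

## A worked example

```{r example, eval = FALSE}
scene <- generate_climate_surface(seed = 101) # 100 x 100 cells, derived
niche <- default_virtual_niche(scene)
train <- sample_occurrences(scene, niche, 1000, seed = 102)

search <- free_search(
  train,
  c("PRATIO", "MTWM", "SMRPB", "WINP", "LogMAP", "TRI", "TRIX"),
  threshold = 2
)
tidy(search$fit)
glance(search$fit)
evaluate_npmr(search$fit)

prob <- predict_grid(search$fit, scene)
autoplot(apply_display_floor(prob, 0.135))
autoplot(response_curve(train, "PRATIO", threshold = 2))
```

## Numerical choices and limitations

* All randomness flows through explicit `seed` arguments
  (`withr::with_seed`), so every generator and sampler is a pure
  function of its inputs.
* The kernel weight floor ($10^{-12}$), likelihood clamp ($10^{-6}$),
  and the local-mean bound enforcement (estimates clamped to the
  observed response range to absorb summation-order rounding) are fixed
  numerical conventions, not tunables.
* Free search drops rows with missing values on any candidate before
  searching, so all evaluated models share one sample and their logB
  values are comparable; per-model exclusion would silently change $N$
  between candidates.
* Problem sizes in the test and acceptance studies (scene 100 × 100,
  n = 1000 flagship, 100 null replicates at n = 1000, 25 brute-force
  oracle datasets at N ≤ 50) were chosen to complete comfortably on a
  single CPU while leaving the statistical conclusions stable across
  seeds.
* logB values from datasets of different sizes are not comparable, and
  xR² for binary responses rarely approaches 1 even for good models;
  both behaviours are inherited from the method, not defects.
* The estimator supports only binary responses with the local-mean
  kernel; quantitative responses and local-linear estimators are out of
  scope.
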