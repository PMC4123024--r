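---
title: "Multi-area land use regression: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-area land use regression: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multilur)
```

## The modeling problem

Land use regression (LUR) explains spatial variation in measured air
pollutant concentrations (NO2, PM2.5, PM2.5 absorbance) with GIS-derived
predictors — traffic load and road length in circular buffers, land-use
areas, nearest-road traffic intensity — and then predicts concentrations at
unmeasured locations such as cohort addresses. Classical LUR is built per
city from a small purpose-designed campaign. `multilur` implements the
*combined* (multi-area) variant: one model over many standardized study
areas, with an area-level **regional background concentration** — the mean
of measured concentrations at each area's regional background sites — forced
into the model first to absorb between-area differences, and the remaining
variation explained by local traffic and land-use predictors.

The fitted model is ordinary least squares

$$ y_i = \beta_0 + \beta_{bg}\, z_{a(i)} + \sum_j \beta_j x_{ij} + \varepsilon_i, $$

where $z_{a}$ is the regional background of area $a$ and the $x_{ij}$ are
buffer variables. What distinguishes LUR from a generic regression is the
*supervised* selection procedure and the evaluation layers around it, both
implemented here exactly as used for combined multi-area campaigns:

1. **Forced first step.** The regional background variable always enters
   (and is exempt from all later removals). City-specific models without a
   forced term are available via `lur_options(force_background = FALSE)`.
2. **Sign-constrained greedy selection.** Each remaining candidate is added
   alone to the current model; a candidate is eligible only if its fitted
   coefficient matches its a-priori direction of effect (e.g. positive for
   traffic intensity, negative for green space) *and* it flips no
   already-entered term's required sign. The eligible candidate with the
   largest adjusted-$R^2$ gain enters if the gain is at least 1 percentage
   point (`gain = 0.01`); otherwise selection stops.
3. **Backward pruning.** Non-forced terms with $p > 0.1$ are removed
   iteratively (largest first, refitting after each removal).
4. **Collinearity control.** While the largest variance inflation factor is
   at least 3, the worst non-forced term is dropped and pruning is re-run.

A note on step 2: the published procedure states the sign condition for the
*entering* variable; we additionally require that previously entered terms
keep their required signs, because a final model with a wrong-signed
traffic term is uninterpretable no matter when the sign flipped. For the
same reason the builder re-checks directions once more after pruning and
VIF removal and drops any violating non-forced term (removals can flip a
surviving term's sign). Every emitted model therefore satisfies its
constraints, which the test suite asserts on every build.

Ties in the gain are broken by lexicographic variable name, making the
selection path fully deterministic. Constant or rank-deficient candidates
are silently ineligible. Whether the 1% gain is measured on adjusted or raw
$R^2$ is genuinely ambiguous in the field; we use adjusted $R^2$, matching
the "highest adjusted $R^2$" selection rule, and we apply the $p$-value
screen only once after selection finishes rather than mid-path.

## Buffer variables

Road variables are exact line-in-disc computations: the length of a segment
inside the closed disc of radius $r$ solves
$\lVert A + t(B-A) - c\rVert^2 = r^2$ for $t$ clipped to $[0,1]$ — no
discretization. Traffic load is intensity-weighted length
(vehicles·m/day). Ring variables (e.g. traffic load between 50 m and
1,000 m) are computed as outer disc minus inner disc, which makes the
additivity identity *ring + inner = outer* hold exactly rather than to
rounding. Land-use areas use a cell-center inclusion test on the raster
(a cell counts iff its center is inside the disc), with bias bounded by one
cell ring, i.e. vanishing as `cell_size / radius`; at the default 100 m
cells and the 5,000 m green-space buffer the relative bias is below ~1%.
Nearest-road intensity breaks exact distance ties by smallest segment id.
The boundary of a disc counts as inside everywhere — a measure-zero
convention fixed for reproducibility.

## Temporal adjustment

Campaigns measure each site in three 2-week windows (cold, warm,
intermediate season) while a continuous reference site runs all year. The
annual average at a site is estimated by the *difference method*:

$$ \hat y_i = \frac{1}{3}\sum_{p} \left[ s_{ip} - (r_{a,p} - \bar r_a) \right], $$

each sample corrected by the concurrent deviation of the reference from its
own annual mean. When a site shares the reference's temporal deviations the
truth is recovered exactly; with a constant reference the estimator reduces
to the plain mean. We implement the signed difference (not an absolute
value, which cannot de-trend) and no ratio variant. Sites with fewer than
three valid samples are adjusted on what is available, with a warning.

## Evaluation layers

All validation $R^2$ values are **squared Pearson correlations** between
predictions and observations — the convention of this literature — which is
sign-blind and insensitive to calibration bias; reports therefore also carry
the MSE-based $1 - SSE/SST$ as a secondary diagnostic, and per-area
regression *slopes* of predictions on observations, so that a slope below 1
reads as compression of predicted contrasts.

- **Model_intra $R^2$**: the combined model applied to each area's own
  training sites; the per-area $R^2$, summarized by median and IQR
  (75th − 25th percentile, linear-interpolation quantiles), is what a
  within-city study experiences.
- **Leave-one-area-out CV** (`loaocv()`): refit excluding a whole area,
  predict it, pool; exactly M refits for M areas.
- **Hold-out validation** (`holdout_validate()`): fit on training sites
  only (area-stratified random split, or a designated split), evaluate at
  withheld sites.
- **Transferability** (`transfer_excluding_each_area()`): the TRANS_intra
  $R^2$ is the per-area squared correlation in an area completely excluded
  from model building.

Out-of-sample prediction **truncates** each predictor to the model's stored
training range by default, preventing extrapolation; a flag disables it.
Two conventions deserve note. First, the excluded area's regional
background value is computed from its *own* regional background sites: that
is the minimal measurement a "new" area must supply for the forced term to
be defined at all, and because the background variable is per-area by
construction, the same code path serves training and transfer without
leakage. Second, in the exact noiseless limit the package verifies that
every evaluation layer returns $R^2 = 1$ to $10^{-8}$ *with truncation
disabled*: clamping necessarily perturbs predictions whenever a test-site
predictor falls outside the training hull, so the algebraic identity is a
property of the untruncated predictor, while truncation is tested by its
own clamp semantics.

For hold-out splits within modeled areas, the background variable is
carried from the full campaign: it is an area-level covariate measured by
the campaign's background sites, not something the site split redefines.

## The synthetic campaign generator

No multi-area measurement set with ground truth exists, so the generator
builds one: areas on a widely separated planar grid (planar meters
throughout — buffers are metric and curvature is irrelevant at city
scale), each with a radial city road network (a few high-intensity
arterials through the center, many low-intensity locals, log-normal
intensities — reproducing the skewed traffic-load distributions LUR
assumes), a land-use raster with a residential core and green outskirts,
and sites placed by type: street sites within 50 m of a road carrying at
least 10,000 vehicles/day, regional background sites at least 1,000 m from
any major road, urban background in between. Area backgrounds are Gaussian
on the log scale by default (concentrations stay positive), switchable to
linear-Gaussian. Seasonality is an area-shared sinusoid over 26 biweekly
periods plus independent per-sample noise — the simplest structure that
exercises the reference-site adjustment. All randomness flows from one seed
through named substreams, so sites, roads and noise can be regenerated
independently and the whole study is byte-identical across runs.

A faster **tabular mode** draws predictors from log-normal marginals
coupled by a Gaussian copula with a target Spearman matrix, then scales
traffic-category variables by site type (street 1, urban background 0.3,
regional background 0). The zero at regional background sites encodes what
those sites *are* — locations not influenced by local sources — and has a
useful algebraic consequence: the measured regional background variable
then equals the area background term exactly, so the noiseless-recovery
identities hold to machine precision.

Two noise controls matter. `target_within_r2` sets the site-level noise so
local predictors explain a chosen share of within-area variance;
`variance_ratio` rescales the area-background spread so the between:within
variance ratio of the generated annual means hits a chosen value. The
presets encode the two regimes of interest: `pm25_like_config()`
(between-dominated: ratio 3, within share 0.5, 17 areas × 20 sites) and
`no2_like_config()` (within-dominated: ratio 0.3, within share 0.7,
23 areas × 40 sites). These are the regimes in which a combined model's
overall $R^2$ far exceeds its median Model_intra $R^2$ (PM2.5-like) or
nearly equals it (NO2-like), and the test suite checks exactly those
contrasts.

What the generator does **not** emulate: real geography, meteorology or
chemistry-transport; within-area spatial autocorrelation of residuals
(noise is independent across sites — a known simplification, so tests that
pass here do not establish behavior under spatially structured residuals);
multi-pollutant correlation beyond shared predictors; and missing or failed
campaigns. Passing recovery tests on this world demonstrates algorithmic
correctness, not real-world predictive skill.

## Numerical choices and problem sizes

OLS is solved by QR (`lm.fit`); a fit is declared numerically perfect when
$SSE \le 10^{-12}\,SST$, in which case all $p$-values are 0 (the $t$
statistics diverge). A predictor regressed on the others with
$1 - R^2_j \le 10^{-12}$ reports VIF $= \infty$. Degenerate inputs follow
fixed rules: empty buffers are 0; an empty road set is a data error for
nearest-road intensity and 0 for buffer sums; constant response errors;
areas with fewer than 3 sites get `NA` per-area metrics with a warning
rather than silent omission.

The validation experiments in the test suite use: 200 instances of
60 sites × 8 candidates for selection-path equivalence against an
exhaustive greedy oracle; 100 seeds of 20 areas × 20 sites with 4 true
predictors and 12 decoys for recovery; 20 seeds each of the two variance
regimes at 12 areas × 20 sites; and the homogeneous-transfer check at the
full campaign scale of 23 areas × 40 sites, because the close agreement of
leave-one-area-out CV with the training fit is a large-campaign property —
with few sites per area, the excluded area's background estimate (from its
1–2 background sites) is noisy enough to open a visible gap, which is a
real small-campaign phenomenon and not a defect.

## Limitations

- Squared-Pearson validation hides additive and multiplicative bias; use
  the reported slopes and the MSE-based diagnostic together with it.
- The raster cell-center rule under-resolves land-use buffers whose radius
  is within an order of magnitude of the cell size.
- The stepwise procedure inherits the instabilities of greedy selection:
  correlated candidates can swap places across seeds even when the fitted
  surface barely changes. The greedy path is guaranteed to match an
  exhaustive greedy oracle, not to be globally optimal.
- No kriging of residuals, no alternative learners, and no hierarchical
  clustering of areas into regions: regions are taken as given labels.
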