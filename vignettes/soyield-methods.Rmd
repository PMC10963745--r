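---
title: "Methods: county-level soybean yield estimation with a GOA-tuned CNN-BiGRU-attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county-level soybean yield estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyield)
```

## The estimation problem

County-level soybean yield in the US Midwest can be estimated before
harvest from satellite-derived predictors observed during the May--August
growing season. `soyield` works from 21 monthly county-level variables in
three groups:

* **SV** — seven MODIS surface-reflectance bands (`Sur_Refl_b01` ..
  `Sur_Refl_b07`) plus the NDVI and EVI vegetation indices (9 variables);
* **ED** — day and night land-surface temperature and five TerraClimate
  variables: Palmer drought severity index, precipitation, soil moisture,
  vapor pressure and vapor-pressure deficit (7 variables);
* **PP** — five photosynthesis-related parameters: solar-induced
  chlorophyll fluorescence (SIF), FPAR, LAI, gross primary productivity and
  net photosynthesis (5 variables).

Yields are in bushels per acre (1 bu/ac of soybean corresponds to 67.25
kg/ha). Each record is a county-year: a 4 (months) x k (variables) block
plus a scalar yield. The temporal protocol trains on 2008--2018 and tests
on 2019 and 2020, with no county-year in both.

## The regression network

The core model is a CNN-BiGRU regressor with additive attention:

1. **Convolution block.** A 1-D convolution runs along the month axis with
   the k variables as input channels, 256 output channels, kernel 3 and
   length-preserving padding; then size-2 max pooling over the month axis
   (4 -> 2 steps), batch normalization, ReLU and dropout 0.2. We read the
   published "input dimensions align with the number of features" as
   channels-of-a-1-D-convolution; a 2-D image reading of the 4 x 21 block
   was considered and rejected because the variable axis has no meaningful
   locality (neighbouring registry variables are not related in any
   spatial sense). The "2 x 2" pooling is realized as size-2 pooling over
   the only axis available after a 1-D convolution, the month axis, which
   also preserves the 1024-unit entry of the head. Max pooling is used:
   with the order pool -> batch norm -> ReLU, the signs of the
   convolution outputs are informative and max pooling keeps the stronger
   response; the choice is isolated in one internal layer so a mean
   variant is a one-line change.
2. **Bidirectional GRU.** Three stacked bidirectional GRU layers with 512
   hidden units per direction. A reading of "512 hidden units distributed
   evenly across three layers" as ~170 per layer would contradict the
   1024-unit fully connected entry, since the attention context has
   dimension 2 x hidden; 2 x 512 = 1024 is the only consistent reading.
3. **Additive attention.** Each pooled time step's 1024-dim hidden state
   h_t is scored `e_t = v' tanh(Wa' h_t + ba)`; softmax over the two steps
   gives weights that always sum to one; the context is the weighted sum.
   The published description does not say whether the attention is
   additive, multiplicative or dot-product; additive scoring is the
   default reading of an attention layer that "calculates significance
   weights relative to the output" and is isolated behind
   `attention_pool()` so it can be swapped. The projection width (128) is
   a free parameter with no published value; it only affects the scoring
   capacity, not the context dimension.
4. **Head.** Fully connected 1024 -> 256 (ReLU) -> 256 (ReLU) -> 256 -> 1,
   producing the bu/ac estimate.

Training uses Huber loss (delta = 1 bu/ac; the transition point has no
published value and 1.0 is the conventional default), Adam with learning
rate 1e-4, 200 epochs, batch size 64, computed on raw bu/ac targets --
features are min-max normalized, targets are not, so reported losses and
errors stay in field units. All of this is implemented from scratch on
base-R matrix algebra with hand-written backward passes; the test suite
verifies every layer's gradient against central finite differences. The
Adam update runs in compiled code because it touches every one of the
~12M parameters each minibatch.

**Output-bias initialization.** The final layer's bias is initialized to
the mean training yield. With Adam the per-parameter step is bounded by
the learning rate, so with lr = 1e-4 a zero-centred output would need
hundreds of thousands of steps merely to drift to the ~50 bu/ac scale of
the targets. Centering the output lets the same published recipe behave
identically in spirit at any data scale; it changes nothing asymptotically
and is switchable (`init_output_bias`).

**Deterministic inference.** Dropout is active only during training;
batch normalization uses running statistics at inference. Two prediction
passes on the same input are bit-identical, and training is reproducible
from the control seed.

## Comparison models

Five reference models are built behind the same interface: support-vector
regression (RBF kernel, C = 100, gamma = 0.1, the values selected upstream
by fivefold cross-validation) and random-forest regression (200 trees,
minimum leaf size 4), both consuming the flattened 4k-vector; and three
deep baselines (CNN with two convolution layers, stacked unidirectional
GRU, and CNN-GRU with pooling and batch normalization) sharing the
network hyperparameters and training recipe. SVR and RFR dispatch to
`e1071` and `randomForest`; the deep baselines share the hand-written
layer toolkit.

## Hyperparameter search

The Grasshopper Optimization Algorithm is implemented from its canonical
formulation, since the source names the method without printing its
equations: social force `s(r) = f exp(-r/l) - exp(-r)` with f = 0.5,
l = 1.5; a comfort-zone coefficient decaying linearly from 1 to 1e-5; and
the position update that sums comfort-scaled pairwise forces and adds the
incumbent best. Pairwise distances are mapped into [1, 4) by
`1 + (d mod 3)` before the kernel so the swarm cannot stall in the
kernel's flat tail (the canonical reference implementation uses the same
modulo trick on [2, 4)); coincident pairs are skipped rather than divided
by zero. Integer dimensions are rounded after every update; learning-rate
style dimensions are searched in log10 space.

The tuning search space (learning rate 1e-5..1e-2 log-scaled, dropout
0..0.5, batch size 16..128, convolution channels 64..256) covers the
knobs the training description names; the published work does not
enumerate its space. The objective is validation RMSE with the last
training year (2018) held out. Population 30 and 50 iterations are
defaults with no published counterpart; both are configuration fields.

## The synthetic-data generator

No dataset accompanies the source study, so the package ships a
calibrated generator instead of fixtures. It emulates:

* the *pooled variable-yield correlation structure*: a single latent
  productivity factor Z per county-year; each variable's season mean is
  `a_v Z + sqrt(1 - a_v^2) e_v` with unit variance, yield is an affine map
  of `Z + e_y` (noise variance tau^2, default 1) onto a bu/ac scale with
  mean 50 and SD 8 truncated at zero (plausible magnitudes for US county
  soybean yield; the source prints no marginal moments). The closed form
  `a_v = r_v sqrt(1 + tau^2)` makes the population correlation between
  each season mean and yield hit its target exactly
  (`calibrate_loadings()`). Default targets are the published pooled
  correlations (Sif 0.1854, EVI 0.1570, Pr 0.1429, Gpp 0.1285, PsnNet
  0.1181, Vpd -0.1642, LST_Day -0.0678, LST_Night -0.0029; Vap/Lai/Soil
  spread across the reported 0.0799--0.0982 weak-positive band; 0.05 for
  variables with no published value);
* the *within-season accumulation* of the photosynthesis-yield
  relationship: monthly values are the season mean scaled by a per-group
  ramp plus 10% month noise; the PP ramp (0.4, 0.7, 1.0, 1.0) is
  nondecreasing May -> August, so PP monthly correlations with yield
  strengthen toward August and peak there, the qualitative pattern the
  monthly correlation table `monthly_pp_correlation()` reproduces;
* optionally, an *extreme-drought year*: `drought_year` shrinks the PP
  loadings in one year, reproducing the reported 2020-style decoupling of
  photosynthesis signals from yield.

What it does **not** emulate: the full inter-variable correlation
heatmap (off-diagonals follow `a_u a_v` from the single factor rather
than being matched), spatial autocorrelation between neighbouring
counties, non-Gaussian tails, and trend/technology drift across years.
Passing tests therefore demonstrate that the pipeline recovers structure
it is calibrated to generate -- not that the models attain the published
accuracy on real USDA/MODIS data, which would require the external
sources and is out of scope. Whether the published pooled correlations
were computed on season means or monthly records is not stated; the
generator calibrates season means and documents that choice.

## Preprocessing decisions

* **Yield quality filter** (`filter_yields()`): combined multi-county
  records are dropped; a county is dropped when its series has fewer
  than 3 usable years or a gap of more than one consecutive year
  (isolated one-year gaps routinely arise from survey skips and from the
  outlier rule, and discarding an otherwise complete county for one
  missing year would be wasteful); records beyond two standard deviations
  from the county's own mean are dropped, with mean and SD per county
  over its full series -- per county, not pooled, because the stated aim
  is catching deviations from a county's own average. With sample SD, a
  county needs at least six years before any point *can* exceed two SDs
  (the maximum attainable z-score in a sample of n is (n-1)/sqrt(n)), so
  short series are effectively protected. The filter is a single pass;
  re-applying it to typical filtered data removes nothing.
* **Scaler** (`fit_scaler()`): per-variable min-max learned from training
  years only and reused on test years, so no test information leaks;
  test-year values may fall outside [0, 1] and are not clipped. Features
  are normalized, targets are not.
* **Missing monthly values**: a hard error by default; optional linear
  interpolation across the four-month window (`policy = "interpolate"`)
  for lenient ingestion. The upstream gap-handling rule is unstated.

## Evaluation

`compute_metrics()` implements R2, RMSE, MAE and MAPE exactly as defined
(MAPE in percent, an error on zero observations rather than a skip --
synthetic yields are truncated above zero, so a zero can only signal
malformed input). The ablation harness retrains one model per variable
combination (SV, ED, PP, SV+ED, SV+PP, ED+PP) from the same seed rather
than reusing weights. Per-variable importance uses model-agnostic sampled
Shapley values: a variable's whole four-month block is toggled between
the instance and the training-mean background, 128 permutations by
default; permutation importance is available as a cheaper alternative.
Training metrics, when reported, come from the final epoch (the
alternative, best-epoch, is not used; the choice is logged with the run).

## Problem sizes used by the shipped checks

The test suite and the acceptance script choose sizes so the whole run
stays desk-scale: correlation recovery uses 100,000 county-years
(10,000 counties x 10 years); learning checks train the full-size
network on a 60-county panel (~650 training records) for 40 epochs at a
desk-scale learning rate of 1e-3 -- with a few hundred optimizer steps
the published 1e-4 would leave the network far from convergence, and the
learning rate is exactly what the tuning stage exists to adapt -- while
the architecture checks, gradient checks and the overfit smoke use the
published recipe unchanged. Reduced-width configurations of the same
layer graph are used where only mechanics are under test.

## Known limitations

* The generator's single-factor dependence cannot represent variables
  that are informative about yield *conditionally* but uncorrelated
  marginally; importance rankings on synthetic data reflect the injected
  loadings only.
* The GOA implementation evaluates candidates serially; tuning the full
  network at realistic sizes is expensive and meant for occasional use.
* MAPE is undefined at zero yield by construction.
* County identifiers are opaque strings; no geometry, spatial masking or
  raster handling is included.
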