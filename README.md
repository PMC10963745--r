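# soyield

County-level soybean yield estimation from multi-source remote-sensing
data, for agroecologists and remote-sensing scientists who want a fully
reproducible, self-contained implementation of a modern deep-learning
yield pipeline.

The package estimates county-year soybean yield (bushels/acre) from 21
monthly May–August predictors in three groups — surface reflectance and
vegetation indices (**SV**: `Sur_Refl_b01`…`b07`, NDVI, EVI),
environmental data (**ED**: day/night land-surface temperature, Pdsi, Pr,
Soil, Vap, Vpd) and photosynthesis-related parameters (**PP**: Sif, Fpar,
Lai, Gpp, PsnNet). At its core is a CNN–BiGRU–attention regressor
("GCBA"): a 1-D convolution over the month axis (k input variables as
channels, 256 output channels, kernel 3), max pooling 4→2, batch norm,
ReLU, dropout 0.2; a 3-layer bidirectional GRU (512 hidden units per
direction); additive attention over the two pooled time steps,

&nbsp;&nbsp;&nbsp;&nbsp;*e*<sub>t</sub> = **v**ᵀ tanh(**W** **h**<sub>t</sub> + **b**), &nbsp;
α = softmax(*e*), &nbsp; **c** = Σ<sub>t</sub> α<sub>t</sub> **h**<sub>t</sub>,

and a fully connected head 1024→256→256→1, trained with Huber loss and
Adam (lr = 1e-4, 200 epochs) on raw bu/ac targets. Hyperparameters
(learning rate, dropout, batch size, convolution channels) can be tuned
by a from-scratch Grasshopper Optimization Algorithm with the canonical
social-force kernel *s*(*r*) = *f* e^(−*r*/*l*) − e^(−*r*). Five
comparison models (SVR, RFR, CNN, GRU, CNN-GRU), the metrics R², RMSE,
MAE, MAPE, a 2008–2018 / 2019–2020 temporal protocol, a variable-group
ablation and sampled-Shapley per-variable importance round out the
pipeline. The neural network, backpropagation and Adam are implemented
in the package itself (base-R matrix algebra plus one compiled inner
loop) and verified against finite differences in the test suite.

Because the original data sources (USDA NASS, MODIS, TerraClimate,
RTSIF) require large external downloads, the package ships a calibrated
synthetic-data generator: a single-latent-factor model whose loadings
are solved in closed form so each variable's season-mean correlation
with yield matches published pooled values (e.g. Sif 0.1854, EVI 0.1570,
Pr 0.1429, Vpd −0.1642), with a nondecreasing within-season ramp on the
photosynthesis group and an optional drought-year decoupling switch.

## Worked example

```r
library(soyield)

cfg <- generator_config(n_counties = 40, years = 2008:2020, seed = 7)
d   <- generate_dataset(cfg)

fil <- filter_yields(d$yields)
fil$report
#> yield filter report
#>   input records:   520
#>   removed combined:0
#>   removed missing: 0
#>   removed outlier: 17
#>   kept:            503

rep <- run_ablation(d$panel, fil$yields,
  function(k) build_baseline("RFR", gcba_config(in_variables = k)),
  combos = list("PP", c("ED", "PP"), c("SV", "ED", "PP")),
  control = train_control(seed = 1))
rep
#>      combo test_year  k    r2 rmse  mae mape
#> 1       PP      2019  5 0.100 7.71 5.91 11.8
#> 2       PP      2020  5 0.172 6.89 5.02 11.2
#> 3    ED+PP      2019 12 0.247 7.05 5.28 10.7
#> 4    ED+PP      2020 12 0.251 6.56 5.12 11.0
#> 5 SV+ED+PP      2019 21 0.135 7.56 5.85 11.8
#> 6 SV+ED+PP      2020 21 0.243 6.59 4.94 10.7
```

Each row is one variable combination evaluated on one held-out test
year: `k` is the number of input variables, `r2` the coefficient of
determination, `rmse`/`mae` are in bu/ac and `mape` in percent. On this
synthetic panel the 17 outlier records are the ~2.5% of county-years
farther than two standard deviations from their county mean, and the
environment + photosynthesis combination (`ED+PP`) outperforms the
photosynthesis group alone, mirroring the intended calibration.

The sample correlation structure the generator was calibrated to can be
inspected directly:

```r
s <- summarize_correlations(d$panel, d$yields)
head(s[order(-abs(s$r)), ], 5)
#>    variable      r   n
#> 21   PsnNet  0.174 520
#> 20      Gpp  0.172 520
#> 9       EVI  0.169 520
#> 16      Vpd -0.154 520
#> 13       Pr  0.150 520
```

At n = 520 these are within sampling error of the configured targets; at
n = 100,000 they match to the third decimal.

To train the full-size GCBA network instead of the RFR baseline, pass
`function(k) build_gcba(gcba_config(in_variables = k))` as the model
builder (minutes of CPU per combination rather than seconds).

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "soyield", package = "soyield")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","soyield",package="soyield"))')" \
  simulate --out run1 simulate.n_counties=20 seed=3
```

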