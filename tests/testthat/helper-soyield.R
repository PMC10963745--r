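# Shared fixtures, all generated in code.

# small architecture for fast unit tests; same layer graph as the default
tiny_gcba_config <- function(k = 4, seed = 7) {
  gcba_config(in_variables = k, conv_channels = 6, gru_hidden = 5,
              gru_layers = 2, attn_dim = 4, fc_hidden = c(8), dropout = 0.2,
              seed = seed)
}

# generator configuration with strong, feasible signal used by the learning
# and importance tests: photosynthesis and vegetation variables carry most of
# the latent factor, yield noise is small
strong_signal_config <- function(n_counties = 25, seed = 11) {
  tc <- default_target_correlations()
  tc[group_variables("PP")] <- c(0.55, 0.45, 0.40, 0.45, 0.40)
  tc["EVI"] <- 0.45
  tc["NDVI"] <- 0.40
  tc["Pr"] <- 0.35
  tc["Vpd"] <- -0.40
  generator_config(n_counties = n_counties, years = 2008:2020,
                   target_corr = tc, noise_var = 0.2, seed = seed)
}

# deterministic toy panel: 2 counties x 2 years, values filled from a seed
toy_panel <- function(seed = 3) {
  reg <- yield_registry()
  grid <- expand.grid(month = 5:8, year = 2019:2020,
                      county_id = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[c("county_id", "year", "month")]
  withr::with_seed(seed, {
    vals <- matrix(rnorm(nrow(grid) * nrow(reg)), nrow(grid))
  })
  colnames(vals) <- reg$name
  as_feature_panel(cbind(grid, vals))
}

toy_yields <- function() {
  as_yield_table(data.frame(
    county_id = rep(c("A", "B"), each = 2), year = rep(2019:2020, 2),
    yield_bu_ac = c(48, 52, 39, 61), combined_flag = FALSE
  ))
}
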