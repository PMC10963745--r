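#' Default variable-yield correlation targets
#'
#' Pooled 2008--2020 Pearson correlations between each predictor's season mean
#' and county yield, as reported for the US soybean panel the generator
#' emulates: Sif 0.1854, EVI 0.1570, Pr 0.1429, Gpp 0.1285, PsnNet 0.1181,
#' Vpd -0.1642, LST_Day -0.0678, LST_Night -0.0029; Vap, Lai and Soil fall in
#' the reported weak-positive band 0.0799--0.0982; variables with no reported
#' coefficient default to 0.05.
#'
#' @return Named numeric vector over the 21 registry variables.
#' @export
default_target_correlations <- function() {
  reg <- yield_registry()
  r <- stats::setNames(rep(0.05, nrow(reg)), reg$name)
  r["Sif"] <- 0.1854
  r["EVI"] <- 0.1570
  r["Pr"] <- 0.1429
  r["Gpp"] <- 0.1285
  r["PsnNet"] <- 0.1181
  r["Vpd"] <- -0.1642
  r["LST_Day"] <- -0.0678
  r["LST_Night"] <- -0.0029
  # weak-positive band, spread across its reported endpoints
  r["Vap"] <- 0.0982
  r["Lai"] <- 0.0885
  r["Soil"] <- 0.0799
  r
}

#' Configuration of the synthetic county-yield generator
#'
#' The generator draws one latent productivity factor Z per county-year and
#' lets every predictor and the yield load on it: the season mean of variable
#' v is `a_v * Z + sqrt(1 - a_v^2) * noise` (unit variance), and yield is an
#' affine map of `Z + e_y` with `Var(e_y) = noise_var` onto a bushels/acre
#' scale. Loadings are calibrated so the population correlation between each
#' season mean and yield equals its target exactly. Monthly values modulate
#' the season mean by a per-group seasonal ramp plus small month noise; the
#' photosynthesis (PP) ramp is nondecreasing May to August so PP-yield
#' correlation strengthens over the season.
#'
#' @param n_counties Number of counties (>= 2).
#' @param years Integer vector of years (default 2008:2020).
#' @param target_corr Named numeric vector of population season-mean-vs-yield
#'   correlations; defaults to [default_target_correlations()].
#' @param noise_var Variance of the yield noise on the latent scale
#'   (tau^2 > 0). Default 1: yield is half latent signal, half noise.
#' @param seasonal_ramp List with one numeric 4-vector per group giving the
#'   May..August multipliers of the season mean. Default: flat for SV and ED,
#'   `(0.4, 0.7, 1.0, 1.0)` for PP.
#' @param month_noise_sd SD of independent month-level noise (default 0.1,
#'   i.e. 10% of the unit variable SD).
#' @param yield_mean,yield_sd Marginal moments of the bu/ac yield scale
#'   (default 50 and 8; yields are truncated at zero).
#' @param drought_year Optional single year for which PP loadings are shrunk
#'   by `drought_shrink`, emulating an extreme-weather season in which
#'   photosynthesis signals decouple from yield.
#' @param drought_shrink Multiplier applied to PP loadings in `drought_year`
#'   (default 0.1).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_counties = 50L,
                             years = 2008:2020,
                             target_corr = default_target_correlations(),
                             noise_var = 1,
                             seasonal_ramp = NULL,
                             month_noise_sd = 0.1,
                             yield_mean = 50,
                             yield_sd = 8,
                             drought_year = NULL,
                             drought_shrink = 0.1,
                             seed = 1L) {
  if (n_counties < 2) stop("n_counties must be >= 2", call. = FALSE)
  if (!length(years)) stop("year range must be nonempty", call. = FALSE)
  if (noise_var <= 0) stop("noise_var must be positive", call. = FALSE)
  reg <- yield_registry()
  if (is.null(names(target_corr)) || !all(reg$name %in% names(target_corr))) {
    stop("target_corr must be named and cover all 21 registry variables",
         call. = FALSE)
  }
  target_corr <- target_corr[reg$name]
  if (any(abs(target_corr) >= 1)) {
    stop("target correlations must lie in (-1, 1)", call. = FALSE)
  }
  if (is.null(seasonal_ramp)) {
    seasonal_ramp <- list(SV = rep(1, 4), ED = rep(1, 4),
                          PP = c(0.4, 0.7, 1.0, 1.0))
  }
  stopifnot(all(c("SV", "ED", "PP") %in% names(seasonal_ramp)),
            all(vapply(seasonal_ramp, length, 1L) == 4L))
  if (is.unsorted(seasonal_ramp$PP)) {
    stop("PP seasonal ramp must be nondecreasing May..August", call. = FALSE)
  }
  # loading feasibility is checked for real in calibrate_loadings()
  calibrate_loadings(target_corr, noise_var)
  structure(list(
    n_counties = as.integer(n_counties), years = as.integer(years),
    target_corr = target_corr, noise_var = noise_var,
    seasonal_ramp = seasonal_ramp, month_noise_sd = month_noise_sd,
    yield_mean = yield_mean, yield_sd = yield_sd,
    drought_year = drought_year, drought_shrink = drought_shrink,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Closed-form loadings for the single-latent-factor generator
#'
#' In the model `x_v = a_v Z + e_v` (unit variances) with
#' `yield ~ Z + e_y`, `Var(e_y) = tau^2`, the population correlation between
#' `x_v` and yield is `a_v / sqrt(1 + tau^2)`; inverting gives
#' `a_v = r_v * sqrt(1 + tau^2)`.
#'
#' @param target_corr Named numeric vector of target correlations `r_v`.
#' @param noise_var Yield noise variance `tau^2` (> 0).
#' @return Named numeric vector of loadings `a_v`, each in \[-1, 1\].
#' @examples
#' calibrate_loadings(c(Sif = 0.1854), noise_var = 1)  # 0.1854 * sqrt(2)
#' @export
calibrate_loadings <- function(target_corr, noise_var) {
  if (noise_var <= 0) stop("noise_var must be positive", call. = FALSE)
  a <- target_corr * sqrt(1 + noise_var)
  bad <- which(abs(a) > 1)
  if (length(bad)) {
    nm <- names(target_corr)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("infeasible correlation target for variable(s) ",
         paste(nm, collapse = ", "),
         ": |r|*sqrt(1 + noise_var) exceeds 1", call. = FALSE)
  }
  a
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic feature panel and yield table
#'
#' See [generator_config()] for the data-generating model. County identifiers
#' are zero-padded FIPS-like strings; all county-years share the configured
#' year range, so the panel is balanced.
#'
#' @param config A [generator_config()].
#' @return List with elements `panel` (a `feature_panel`), `yields` (a
#'   `yield_table`) and `latent` (data frame with the latent factor per
#'   county-year, useful for diagnostics).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  reg <- yield_registry()
  vars <- reg$name
  p <- length(vars)
  a <- calibrate_loadings(config$target_corr, config$noise_var)
  counties <- sprintf("C%05d", seq_len(config$n_counties))
  grid <- expand.grid(year = config$years, county_id = counties,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("county_id", "year")]
  n <- nrow(grid)

  with_seed(config$seed, {
    z <- stats::rnorm(n)
    # loadings per record x variable; drought year shrinks PP loadings
    A <- matrix(a, n, p, byrow = TRUE, dimnames = list(NULL, vars))
    if (!is.null(config$drought_year)) {
      hit <- grid$year %in% config$drought_year
      pp <- reg$group == "PP"
      A[hit, pp] <- A[hit, pp] * config$drought_shrink
    }
    eps <- matrix(stats::rnorm(n * p), n, p)
    xbar <- A * z + sqrt(1 - A^2) * eps  # season means, unit variance
    ey <- stats::rnorm(n, sd = sqrt(config$noise_var))
    yscore <- (z + ey) / sqrt(1 + config$noise_var)
    yield <- pmax(0, config$yield_mean + config$yield_sd * yscore)

    ramp <- sapply(reg$group, function(g) config$seasonal_ramp[[g]])  # 4 x p
    monthly <- vector("list", 4L)
    for (m in 1:4) {
      noise <- matrix(stats::rnorm(n * p, sd = config$month_noise_sd), n, p)
      monthly[[m]] <- xbar * matrix(ramp[m, ], n, p, byrow = TRUE) + noise
    }
  })

  panel <- do.call(rbind, lapply(1:4, function(m) {
    cbind(grid, month = m + 4L, as.data.frame(monthly[[m]]))
  }))
  names(panel)[-(1:3)] <- vars
  panel <- as_feature_panel(panel)
  yields <- as_yield_table(data.frame(
    county_id = grid$county_id, year = grid$year, yield_bu_ac = yield,
    combined_flag = FALSE, stringsAsFactors = FALSE
  ))
  latent <- cbind(grid, z = z)
  list(panel = panel, yields = yields, latent = latent)
}

#' Sample correlations between season-mean predictors and yield
#'
#' @param panel A `feature_panel`.
#' @param yields A `yield_table` sharing county-years with the panel.
#' @return Data frame with columns `variable`, `r` (Pearson correlation of the
#'   variable's season mean with yield; `NA` with a warning for zero-variance
#'   variables) and `n`.
#' @export
summarize_correlations <- function(panel, yields) {
  sm <- season_means(panel)
  yields <- as_yield_table(yields)
  merged <- merge(sm, yields[c("county_id", "year", "yield_bu_ac")],
                  by = c("county_id", "year"))
  if (nrow(merged) < 3) {
    stop("need at least 3 matching county-year records", call. = FALSE)
  }
  vars <- setdiff(names(sm), c("county_id", "year"))
  r <- vapply(vars, function(v) {
    x <- merged[[v]]
    if (stats::sd(x) == 0 || stats::sd(merged$yield_bu_ac) == 0) {
      warning("zero-variance variable '", v, "': correlation undefined",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(x, merged$yield_bu_ac)
  }, numeric(1))
  data.frame(variable = vars, r = unname(r), n = nrow(merged),
             stringsAsFactors = FALSE)
}
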