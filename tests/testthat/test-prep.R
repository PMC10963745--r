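make_yields <- function(df) as_yield_table(df)

test_that("combined-county records are removed and counted", {
  df <- data.frame(
    county_id = rep(c("A", "OTHER"), each = 13), year = rep(2008:2020, 2),
    yield_bu_ac = 50, combined_flag = rep(c(FALSE, TRUE), each = 13)
  )
  fr <- filter_yields(make_yields(df))
  expect_equal(fr$report$n_removed_combined, 13L)
  expect_false(any(fr$yields$combined_flag))
  expect_true(all(fr$yields$county_id == "A"))
})

test_that("counties with discontinuous series are removed", {
  # B misses 2013-2014 (two-year gap -> removed); C misses only 2014
  # (isolated survey skip -> kept)
  df <- data.frame(
    county_id = c(rep("A", 13), rep("B", 11), rep("C", 12)),
    year = c(2008:2020, setdiff(2008:2020, 2013:2014),
             setdiff(2008:2020, 2014)),
    yield_bu_ac = 50, combined_flag = FALSE
  )
  fr <- filter_yields(make_yields(df))
  expect_equal(fr$report$n_removed_missing, 11L)
  expect_setequal(unique(fr$yields$county_id), c("A", "C"))
  # a county with < 3 usable years goes the same way
  df2 <- data.frame(county_id = c("A", "A"), year = 2019:2020,
                    yield_bu_ac = 50, combined_flag = FALSE)
  fr2 <- filter_yields(make_yields(df2), year_range = 2019:2020)
  expect_equal(fr2$report$n_removed_missing, 2L)
  expect_equal(fr2$report$n_kept, 0L)
})

test_that("two-sigma outlier rule removes a hand-checkable excursion", {
  # 12 stable years around 50 plus one excursion at 90:
  # mean = 53.0, sd = 11.2; |90 - 53.0| = 37.0 > 2 sd = 22.4
  y <- c(49, 51, 50, 52, 48, 50, 51, 49, 50, 52, 48, 49, 90)
  expect_gt(abs(90 - mean(y)), 2 * sd(y))            # oracle by hand
  df <- data.frame(county_id = "A", year = 2008:2020, yield_bu_ac = y,
                   combined_flag = FALSE)
  fr <- filter_yields(make_yields(df))
  expect_equal(fr$report$n_removed_outlier, 1L)
  expect_identical(fr$report$removed_ids$outlier, "A:2020")
  expect_false(90 %in% fr$yields$yield_bu_ac)
})

test_that("constant-yield county triggers no outlier removal", {
  df <- data.frame(county_id = "A", year = 2008:2020, yield_bu_ac = 50,
                   combined_flag = FALSE)
  fr <- filter_yields(make_yields(df))
  expect_equal(fr$report$n_removed_outlier, 0L)
  expect_equal(fr$report$n_kept, 13L)
})

test_that("filter report accounting balances and a second pass is near-idempotent", {
  d <- generate_dataset(generator_config(n_counties = 120, seed = 31))
  fr <- filter_yields(d$yields)
  r <- fr$report
  expect_equal(r$n_input - r$n_removed_combined - r$n_removed_missing -
                 r$n_removed_outlier, r$n_kept)
  # a second application drops no county and no combined record; the only
  # possible further removals come from re-estimated two-sigma trimming,
  # whose marginal rate on Gaussian yields is bounded by the shrinkage of
  # the trimmed SD (well under 2%) -- exact idempotence is unattainable for
  # any mean +/- 2 SD rule that re-estimates its statistics
  fr2 <- filter_yields(fr$yields)
  expect_equal(fr2$report$n_removed_combined, 0L)
  expect_equal(fr2$report$n_removed_missing, 0L)
  expect_lt(fr2$report$n_removed_outlier / r$n_kept, 0.02)
})

test_that("monthly aggregation averages observations and enforces coverage", {
  obs <- data.frame(
    month = c(5, 5, 6, 6, 6, 7, 8),
    variable = "Sif",
    value = c(7, 7, 2, 4, 6, 1, 3)
  )
  out <- aggregate_to_monthly(obs, "A", 2019)
  expect_equal(out$Sif, c(7, 4, 1, 3))
  # constant series
  flat <- data.frame(month = rep(5:8, each = 3), variable = "Lai", value = 7)
  expect_equal(aggregate_to_monthly(flat, "A", 2019)$Lai, rep(7, 4))
  # missing month: named error in strict mode, interpolation in lenient
  gap <- obs[obs$month != 7, ]
  expect_error(aggregate_to_monthly(gap, "A", 2019),
               "county A year 2019 variable Sif in month\\(s\\) 7")
  len <- aggregate_to_monthly(gap, "A", 2019, policy = "interpolate")
  expect_equal(len$Sif, c(7, 4, 3.5, 3))  # linear between June and August
})

test_that("scaler maps training extremes to 0/1, preserves out-of-range test values, and inverts", {
  d <- generate_dataset(generator_config(n_counties = 30, seed = 13))
  sc <- fit_scaler(d$panel, 2008:2018)
  scaled <- apply_scaler(d$panel, sc)
  tr <- scaled[scaled$year <= 2018, ]
  vars <- setdiff(names(tr), c("county_id", "year", "month"))
  expect_equal(min(as.matrix(tr[vars])), 0)
  expect_equal(max(as.matrix(tr[vars])), 1)
  # test years may exceed [0,1] and are not clipped
  te <- scaled[scaled$year > 2018, ]
  expect_true(any(as.matrix(te[vars]) > 1 | as.matrix(te[vars]) < 0))
  # hand-checked transform
  v <- vars[1]
  x0 <- d$panel[[v]][1]
  expect_equal(scaled[[v]][1], (x0 - sc$min[[v]]) / (sc$max[[v]] - sc$min[[v]]))
  # round trip
  back <- apply_scaler(scaled, sc, invert = TRUE)
  expect_equal(back[[v]], d$panel[[v]], tolerance = 1e-12)
})

test_that("constant training variable scales to zero with a warning", {
  p <- as.data.frame(toy_panel())
  p$Lai <- 5
  p <- as_feature_panel(p)
  sc <- fit_scaler(p, 2019)
  expect_warning(out <- apply_scaler(p, sc), "constant in training")
  expect_true(all(out$Lai == 0))
})

test_that("tensor assembly selects groups in registry order with aligned targets", {
  d <- generate_dataset(generator_config(n_counties = 10, seed = 17))
  for (case in list(list(g = c("SV", "ED", "PP"), k = 21),
                    list(g = "PP", k = 5),
                    list(g = "SV", k = 9),
                    list(g = c("ED", "PP"), k = 12),
                    list(g = c("SV", "PP"), k = 14),
                    list(g = c("SV", "ED"), k = 16))) {
    ai <- assemble_inputs(d$panel, d$yields, case$g)
    expect_equal(dim(ai$x)[3], case$k)
    expect_equal(dim(ai$x)[1], length(ai$y))
    expect_identical(ai$variables, group_variables(case$g))
  }
  # monthly values land in the right cells
  ai <- assemble_inputs(d$panel, d$yields)
  i <- 7
  cid <- ai$manifest$county_id[i]
  yr <- ai$manifest$year[i]
  expect_equal(
    ai$x[i, , "Sif"],
    d$panel$Sif[d$panel$county_id == cid & d$panel$year == yr],
    ignore_attr = TRUE
  )
  expect_equal(ai$y[i],
               d$yields$yield_bu_ac[d$yields$county_id == cid &
                                      d$yields$year == yr])
})

test_that("assembly drops panel records without yields and rejects empty intersections", {
  d <- generate_dataset(generator_config(n_counties = 5, seed = 19))
  part <- d$yields[d$yields$year != 2020, ]
  expect_message(ai <- assemble_inputs(d$panel, part), "dropped")
  expect_equal(dim(ai$x)[1], nrow(part))
  none <- d$yields[0, ]
  expect_error(suppressMessages(assemble_inputs(d$panel, none)))
  expect_error(assemble_inputs(d$panel, d$yields, character(0)), "nonempty")
})
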