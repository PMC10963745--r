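# Independent brute-force metric implementation used as the oracle: plain
# loops over the defining sums, no shared code with compute_metrics().
brute_metrics <- function(y, y_hat) {
  n <- length(y)
  sse <- 0
  sst <- 0
  sae <- 0
  spe <- 0
  ybar <- sum(y) / n
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - y_hat[i])^2
    sst <- sst + (y[i] - ybar)^2
    sae <- sae + abs(y[i] - y_hat[i])
    spe <- spe + abs((y_hat[i] - y[i]) / y[i])
  }
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / n), mae = sae / n,
       mape = 100 * spe / n)
}

test_that("metrics agree with the brute-force oracle on 100 random vectors", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(3:40, 1)
      y <- runif(n, 20, 80)
      y_hat <- y + rnorm(n, 0, 5)
      got <- compute_metrics(y, y_hat)
      want <- brute_metrics(y, y_hat)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("hand-worked metric example is reproduced exactly", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$mape, 100 / 9)
  expect_equal(m$mape, 11.11, tolerance = 1e-3)
  expect_equal(m$r2, 0.5)
})

test_that("metric identities and error cases hold", {
  y <- c(40, 50, 60, 55)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect, list(r2 = 1, rmse = 0, mae = 0, mape = 0))
  # predicting the mean gives R2 = 0
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(compute_metrics(c(1), c(1)), "at least 2")
  expect_error(compute_metrics(c(0, 1), c(1, 1)), "zeros")
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "length")
  # MAPE can be skipped to allow zero observations
  expect_true(is.na(compute_metrics(c(0, 1), c(1, 1), mape = FALSE)$mape))
})

test_that("RMSE dominates MAE and R2 is invariant to common shifts", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      y <- runif(15, 30, 70)
      y_hat <- y + rnorm(15, 0, 4)
      m <- compute_metrics(y, y_hat)
      expect_gte(m$rmse, m$mae)
      shifted <- compute_metrics(y + 11, y_hat + 11)
      expect_equal(shifted$r2, m$r2, tolerance = 1e-12)
    }
  })
})

test_that("temporal split partitions by year with no overlap", {
  d <- generate_dataset(generator_config(n_counties = 4, seed = 2))
  sp <- temporal_split(d$yields)
  expect_setequal(unique(sp$train$year), 2008:2018)
  expect_setequal(unique(sp$test$year), 2019:2020)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d$yields))
  expect_equal(length(intersect(
    paste(sp$train$county_id, sp$train$year),
    paste(sp$test$county_id, sp$test$year))), 0L)
  # boundaries
  expect_true(2018 %in% sp$train$year && !2018 %in% sp$test$year)
  expect_true(2019 %in% sp$test$year && !2019 %in% sp$train$year)
  expect_error(temporal_split(d$yields, 2008:2019, 2019:2020), "overlap")
})

test_that("ablation covers the six combinations and PP-rich combos win on PP-loaded data", {
  cfg <- strong_signal_config(n_counties = 40, seed = 23)
  d <- generate_dataset(cfg)
  yields <- filter_yields(d$yields)$yields
  rfr_builder <- function(k) {
    build_baseline("RFR", gcba_config(in_variables = k),
                   rfr = list(n_estimators = 60))
  }
  rep <- run_ablation(d$panel, yields, rfr_builder,
                      control = train_control(seed = 4))
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep), 12L)  # 6 combos x 2 test years
  expect_setequal(unique(rep$combo),
                  c("SV", "ED", "PP", "SV+ED", "SV+PP", "ED+PP"))
  expect_equal(unique(rep$k[rep$combo == "PP"]), 5L)
  expect_equal(unique(rep$k[rep$combo == "ED+PP"]), 12L)
  # the generator loads PP variables heavily: ED+PP should beat SV alone
  mean_r2 <- tapply(rep$r2, rep$combo, mean)
  expect_gt(mean_r2[["ED+PP"]], mean_r2[["SV"]])
  expect_error(run_ablation(d$panel, yields, rfr_builder, combos = list()),
               "no variable combinations")
})

test_that("full-group ablation row equals a direct 21-variable evaluation", {
  cfg <- strong_signal_config(n_counties = 20, seed = 29)
  d <- generate_dataset(cfg)
  yields <- filter_yields(d$yields)$yields
  builder <- function(k) {
    build_baseline("RFR", gcba_config(in_variables = k),
                   rfr = list(n_estimators = 40))
  }
  ctl <- train_control(seed = 6)
  rep <- run_ablation(d$panel, yields, builder,
                      combos = list(c("SV", "ED", "PP")), control = ctl)
  direct <- evaluate_combo(d$panel, yields, builder,
                           groups = c("SV", "ED", "PP"), control = ctl)
  expect_equal(rep$r2, direct$metrics$r2, tolerance = 1e-12)
  expect_equal(rep$rmse, direct$metrics$rmse, tolerance = 1e-12)
})

test_that("sampled Shapley is exact on a linear model and zero for a null feature", {
  # f(x) = 3 * mean of variable 1 over months; variable 2 ignored
  f <- function(x) 3 * apply(x[, , 1, drop = FALSE], 1, mean)
  withr::with_seed(11, x <- array(rnorm(30 * 4 * 2), c(30, 4, 2)))
  imp <- feature_importance(f, x, n_samples = 16, seed = 2,
                            variables = c("x1", "x2"))
  expect_identical(imp$variable[1], "x1")
  expect_equal(imp$score[imp$variable == "x2"], 0)
  expect_true(all(imp$score >= 0))
  # exact Shapley for a linear model: |3 * (x1bar - background x1bar)|
  bg <- apply(x, c(2, 3), mean)
  want <- mean(abs(3 * (apply(x[, , 1], 1, mean) - mean(bg[, 1]))))
  expect_equal(imp$score[imp$variable == "x1"], want, tolerance = 1e-10)
  expect_error(feature_importance(f, x, n_samples = 0), ">= 1")
})

test_that("permutation importance ranks the informative variable first", {
  withr::with_seed(13, {
    x <- array(rnorm(60 * 4 * 3), c(60, 4, 3))
    y <- 5 * x[, 1, 2] + rnorm(60, 0, 0.1)
  })
  f <- function(x) 5 * x[, 1, 2]
  imp <- feature_importance(f, x, n_samples = 8, seed = 3,
                            method = "permutation", y = y,
                            variables = c("a", "b", "c"))
  expect_identical(imp$variable[1], "b")
  expect_equal(imp$score[imp$variable %in% c("a", "c")], c(0, 0))
})

test_that("monthly photosynthesis correlations match hand cases", {
  p <- toy_panel()
  y <- toy_yields()
  p2 <- as.data.frame(p)
  yy <- as.data.frame(y)
  key <- match(paste(p2$county_id, p2$year), paste(yy$county_id, yy$year))
  p2$Sif <- yy$yield_bu_ac[key] * 2 + 1   # proportional every month
  p2$Gpp <- -p2$Sif                       # anti-proportional
  tab <- monthly_pp_correlation(as_feature_panel(p2), y)
  expect_equal(tab$Sif, rep(1, 4))
  expect_equal(tab$Gpp, rep(-1, 4))
  p3 <- p2
  p3$Lai <- 2
  expect_warning(tab3 <- monthly_pp_correlation(as_feature_panel(p3), y),
                 "zero-variance")
  expect_true(all(is.na(tab3$Lai)))
  # per-year layout
  taby <- monthly_pp_correlation(as_feature_panel(p2), y, by_year = TRUE)
  expect_equal(nrow(taby), 8L)  # 4 months x 2 years
})
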