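test_that("configuration invariants are enforced at construction", {
  expect_error(gcba_config(kernel = 5), "shorter than kernel")
  expect_error(gcba_config(pool = 3), "divide")
  expect_error(gcba_config(in_variables = 0), "at least one")
  cfg <- gcba_config()
  expect_equal(cfg$conv_channels, 256L)
  expect_equal(cfg$gru_hidden, 512L)
  expect_equal(cfg$gru_layers, 3L)
  expect_equal(cfg$dropout, 0.2)
})

test_that("full-size network has the published architecture", {
  m <- build_gcba(gcba_config())
  types <- vapply(m$layers, `[[`, "", "type")
  expect_identical(types, c("conv1d", "pool", "batchnorm", "relu", "dropout",
                            "gru", "attention", "dense", "dense", "dense"))
  # fully connected head: 1024 -> 256 -> 256 -> 1
  dense <- m$layers[types == "dense"]
  expect_equal(vapply(dense, `[[`, 0L, "in_size"), c(1024L, 256L, 256L))
  expect_equal(vapply(dense, `[[`, 0L, "out_size"), c(256L, 256L, 1L))
  # head entry = 2 x 512 bidirectional hidden
  expect_equal(dense[[1]]$in_size, 2L * m$config$gru_hidden)
  # forward contract on a batch of 8
  withr::with_seed(2, x <- array(rnorm(8 * 4 * 21), c(8, 4, 21)))
  p <- predict(m, x)
  expect_length(p, 8L)
  a <- gcba_attention(m, x)
  expect_equal(dim(a), c(8L, 2L))
  expect_equal(rowSums(a), rep(1, 8))
  expect_true(all(a >= 0))
})

test_that("two inference passes are identical (dropout only during training)", {
  m <- build_gcba(tiny_gcba_config())
  withr::with_seed(3, {
    x <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
    y <- rnorm(6, 50, 8)
  })
  m <- fit_model(m, x, y, train_control(epochs = 3, batch_size = 3,
                                        seed = 1))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("training is deterministic given the seed", {
  withr::with_seed(4, {
    x <- array(rnorm(10 * 4 * 4), c(10, 4, 4))
    y <- rnorm(10, 50, 8)
  })
  ctl <- train_control(epochs = 4, batch_size = 5, seed = 9)
  m1 <- fit_model(build_gcba(tiny_gcba_config()), x, y, ctl)
  m2 <- fit_model(build_gcba(tiny_gcba_config()), x, y, ctl)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, x), predict(m2, x))
  # default recipe carries the published settings
  ctl0 <- train_control()
  expect_equal(ctl0$lr, 1e-4)
  expect_equal(ctl0$epochs, 200L)
  expect_identical(ctl0$loss, "huber")
})

test_that("a reduced network overfits a small sample", {
  withr::with_seed(6, {
    x <- array(rnorm(16 * 4 * 4), c(16, 4, 4))
    y <- 50 + 8 * tanh(rowMeans(x[, , 1]))
  })
  m <- fit_model(build_gcba(tiny_gcba_config()), x, y,
                 train_control(epochs = 150, batch_size = 8, seed = 2,
                               lr = 3e-3))
  expect_lt(tail(m$history, 1), 0.2 * m$history[1])
})

test_that("baseline zoo builds the five comparison models with printed settings", {
  expect_error(build_baseline("XGB"), "SVR, RFR, CNN, GRU, CNN-GRU")
  svr <- build_baseline("SVR")
  expect_identical(svr$control[c("kernel", "cost", "gamma", "cv_folds")],
                   list(kernel = "radial", cost = 100, gamma = 0.1,
                        cv_folds = 5))
  rfr <- build_baseline("RFR")
  expect_identical(rfr$control[c("n_estimators", "min_samples_leaf")],
                   list(n_estimators = 200, min_samples_leaf = 4))
  cfg <- tiny_gcba_config()
  for (nm in c("CNN", "GRU", "CNN-GRU")) {
    m <- build_baseline(nm, cfg)
    expect_s3_class(m, "deep_model")
  }
})

test_that("every model produces aligned predictions on a toy problem", {
  withr::with_seed(8, {
    x <- array(rnorm(40 * 4 * 4), c(40, 4, 4))
    y <- 50 + 5 * x[, 2, 1] + rnorm(40, 0, 0.5)
  })
  cfg <- tiny_gcba_config()
  ctl <- train_control(epochs = 5, batch_size = 8, seed = 3)
  for (nm in c("SVR", "RFR", "CNN", "GRU", "CNN-GRU")) {
    m <- fit_model(build_baseline(nm, cfg), x, y, ctl)
    p <- predict(m, x)
    expect_length(p, 40L)
    expect_true(all(is.finite(p)))
  }
  # SVR and RFR actually track a strong linear signal in-sample
  svr <- fit_model(build_baseline("SVR", cfg), x, y, ctl)
  expect_gt(compute_metrics(y, predict(svr, x))$r2, 0.5)
  rfr <- fit_model(build_baseline("RFR", cfg), x, y, ctl)
  expect_gt(compute_metrics(y, predict(rfr, x))$r2, 0.5)
})

test_that("input validation catches misaligned tensors", {
  m <- build_gcba(tiny_gcba_config())
  x <- array(0, c(4, 4, 4))
  expect_error(fit_model(m, x, 1:3, train_control(epochs = 1)),
               "not aligned")
  expect_error(predict(m, array(0, c(2, 4, 7))), "expects 4 variables")
  bad <- matrix(0, 4, 4)
  expect_error(fit_model(m, bad, 1:4, train_control(epochs = 1)), "array")
})
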