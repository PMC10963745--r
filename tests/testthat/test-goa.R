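sphere_config <- function(seed, iterations = 200) {
  goa_config(data.frame(lo = c(-5, -5), hi = c(5, 5)), n_pop = 30,
             iterations = iterations, seed = seed)
}

test_that("social force matches its closed form", {
  expect_equal(social_force(0), 0.5 * 1 - 1)          # -0.5
  expect_lt(abs(social_force(50)), 1e-10)             # vanishes at range
  # comfort distance: the root of s sits near 2.079 for f=0.5, l=1.5
  root <- uniroot(social_force, c(1, 4))$root
  expect_equal(root, 2.079, tolerance = 1e-3)
  expect_lt(social_force(1.5), 0)                     # repulsion inside
  expect_gt(social_force(3), 0)                       # attraction outside
  expect_error(social_force(-1), "nonnegative")
})

test_that("comfort coefficient decays linearly between its endpoints", {
  cfg <- sphere_config(1, iterations = 100)
  expect_equal(comfort_coefficient(0, cfg), 1)
  expect_equal(comfort_coefficient(100, cfg), 1e-5)
  expect_equal(comfort_coefficient(50, cfg), 1 - 50 * (1 - 1e-5) / 100)
  expect_equal(comfort_coefficient(50, cfg), 0.500005, tolerance = 1e-9)
  expect_error(comfort_coefficient(101, cfg), "\\[0, L\\]")
  tvals <- comfort_coefficient(0:100, cfg)
  expect_true(all(diff(tvals) < 0))
})

test_that("position updates stay in bounds and are deterministic", {
  cfg <- goa_config(data.frame(lo = c(-2, 0), hi = c(3, 1)), n_pop = 12,
                    iterations = 10, seed = 4)
  obj <- function(x) sum((x - 0.5)^2)
  s0 <- goa_init_swarm(obj, cfg)
  expect_true(all(s0$positions >= matrix(c(-2, 0), 12, 2, byrow = TRUE)))
  s1a <- update_positions(s0, 0.7, cfg, obj)
  s1b <- update_positions(s0, 0.7, cfg, obj)
  expect_identical(s1a$positions, s1b$positions)
  for (i in 1:5) s0 <- update_positions(s0, comfort_coefficient(i, cfg),
                                        cfg, obj)
  expect_true(all(s0$positions[, 1] >= -2 & s0$positions[, 1] <= 3))
  expect_true(all(s0$positions[, 2] >= 0 & s0$positions[, 2] <= 1))
})

test_that("coincident grasshoppers do not produce NaN positions", {
  cfg <- goa_config(data.frame(lo = -1, hi = 1), n_pop = 3, iterations = 5,
                    seed = 2)
  obj <- function(x) x^2
  s <- goa_init_swarm(obj, cfg)
  s$positions[] <- 0.5   # all coincident
  s2 <- update_positions(s, 0.5, cfg, obj)
  expect_true(all(is.finite(s2$positions)))
})

test_that("best-so-far trace is monotone nonincreasing on every run", {
  for (seed in 1:5) {
    res <- goa_optimize(function(x) sum(x^2) + sin(5 * x[1]),
                        sphere_config(seed, iterations = 40))
    expect_true(all(diff(res$trace) <= 0))
  }
})

test_that("sphere objective is minimized well below the acceptance level", {
  vals <- vapply(1:5, function(seed) {
    goa_optimize(function(x) sum(x^2), sphere_config(seed))$value
  }, numeric(1))
  expect_lt(median(vals), 1e-2)
})

test_that("integer dimension recovers the exhaustive-search optimum", {
  # oracle: enumerate all integer candidates
  oracle <- function(f, lo, hi) {
    cand <- lo:hi
    cand[which.min(vapply(cand, f, numeric(1)))]
  }
  f <- function(x) abs(x - 3)
  expect_equal(oracle(f, 0, 10), 3)
  cfg <- goa_config(data.frame(lo = 0, hi = 10, kind = "integer"),
                    n_pop = 12, iterations = 30, seed = 6)
  res <- goa_optimize(f, cfg)
  expect_equal(unname(res$par), 3)
  # 2-D discrete problem against brute force over the grid
  g <- function(x) (x[1] - 7)^2 + 2 * (x[2] + 4)^2
  grid <- expand.grid(a = 0:15, b = -10:0)
  brute <- grid[which.min(apply(grid, 1, g)), ]
  cfg2 <- goa_config(data.frame(lo = c(0, -10), hi = c(15, 0),
                                kind = "integer"),
                     n_pop = 20, iterations = 60, seed = 3)
  res2 <- goa_optimize(g, cfg2)
  expect_equal(unname(res2$par), unname(unlist(brute)))
})

test_that("log-scaled dimensions search in log space and decode to user scale", {
  cfg <- goa_config(data.frame(lo = 1e-5, hi = 1e-1, kind = "log"),
                    n_pop = 15, iterations = 60, seed = 5)
  res <- goa_optimize(function(x) (log10(x) + 3)^2, cfg)  # optimum at 1e-3
  expect_equal(unname(log10(res$par)), -3, tolerance = 0.05)
})

test_that("non-finite objective values are discarded with a warning", {
  cfg <- goa_config(data.frame(lo = -1, hi = 1), n_pop = 6, iterations = 3,
                    seed = 7)
  expect_warning(
    res <- goa_optimize(function(x) if (x[1] < 0) NaN else x[1]^2, cfg),
    "non-finite"
  )
  expect_true(is.finite(res$value))
})

test_that("longer runs do not hurt convergence on a convex objective", {
  short <- vapply(1:6, function(s) {
    goa_optimize(function(x) sum(x^2), sphere_config(s, iterations = 10))$value
  }, numeric(1))
  long <- vapply(1:6, function(s) {
    goa_optimize(function(x) sum(x^2), sphere_config(s, iterations = 80))$value
  }, numeric(1))
  expect_lte(median(long), median(short))
})

test_that("search-space template exposes the four tuning dimensions", {
  sp <- gcba_search_space()
  expect_identical(rownames(sp),
                   c("lr", "dropout", "batch_size", "conv_channels"))
  expect_identical(sp$kind, c("log", "continuous", "integer", "integer"))
})
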