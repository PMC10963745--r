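#' Regression metrics for yield estimation
#'
#' Computes the four standard metrics over an observed/estimated pair:
#' \deqn{R^2 = 1 - \sum_i (Y_i - \hat Y_i)^2 / \sum_i (Y_i - \bar Y)^2}
#' \deqn{RMSE = \sqrt{\frac{1}{n} \sum_i (Y_i - \hat Y_i)^2}}
#' \deqn{MAE = \frac{1}{n} \sum_i |Y_i - \hat Y_i|}
#' \deqn{MAPE = \frac{100}{n} \sum_i |(\hat Y_i - Y_i) / Y_i|}
#' RMSE and MAE are in bu/ac; MAPE is a percentage and requires strictly
#' nonzero observations.
#'
#' @param y Observed yields (bu/ac), length >= 2.
#' @param y_hat Estimated yields, same length.
#' @param mape If `FALSE`, skip MAPE (allows zero observations).
#' @return Named list with `r2`, `rmse`, `mae`, `mape`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
compute_metrics <- function(y, y_hat, mape = TRUE) {
  n <- length(y)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(y_hat) != n) {
    stop("observed and estimated vectors differ in length", call. = FALSE)
  }
  if (anyNA(y) || anyNA(y_hat)) stop("metrics on missing values",
                                     call. = FALSE)
  e <- y - y_hat
  out <- list(
    r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e))
  )
  if (mape) {
    if (any(y == 0)) {
      stop("MAPE undefined: observed yields contain zeros", call. = FALSE)
    }
    out$mape <- 100 * mean(abs(e / y))
  } else {
    out$mape <- NA_real_
  }
  out
}

#' Split records by year into training and test sets
#'
#' @param records Data frame with a `year` column (panel, yield table, or
#'   any aligned record set).
#' @param train_years Training years (default 2008:2018).
#' @param test_years Test years (default 2019:2020).
#' @return List with `train` and `test` subsets; years outside both sets are
#'   dropped. Overlapping year ranges are an error.
#' @export
temporal_split <- function(records, train_years = 2008:2018,
                           test_years = 2019:2020) {
  if (length(intersect(train_years, test_years))) {
    stop("training and test years overlap", call. = FALSE)
  }
  stopifnot("year" %in% names(records))
  list(train = records[records$year %in% train_years, , drop = FALSE],
       test = records[records$year %in% test_years, , drop = FALSE])
}

default_ablation_combos <- function() {
  list("SV", "ED", "PP", c("SV", "ED"), c("SV", "PP"), c("ED", "PP"))
}

combo_label <- function(combo) paste(combo, collapse = "+")

#' Train/test pipeline for one variable subset
#'
#' Fits the scaler on training years, trains the model on scaled training
#' tensors, and evaluates per test year. Used by [run_ablation()] and the
#' pipeline stages.
#'
#' @param panel,yields Unscaled panel and (filtered) yield table.
#' @param model_builder Function `(k) ->` untrained model for `k` input
#'   variables.
#' @param groups Variable groups to include.
#' @param control A [train_control()] for deep models.
#' @param train_years,test_years Temporal protocol years.
#' @return List with `model`, `scaler`, and `metrics` (data frame with one
#'   row per test year), plus `predictions` per test year.
#' @export
evaluate_combo <- function(panel, yields, model_builder,
                           groups = c("SV", "ED", "PP"),
                           control = train_control(),
                           train_years = 2008:2018,
                           test_years = 2019:2020) {
  if (!length(groups)) stop("variable combination is empty", call. = FALSE)
  scaler <- fit_scaler(panel[panel$year %in% train_years, ], train_years)
  scaled <- apply_scaler(panel, scaler)
  ai <- assemble_inputs(scaled, yields, groups)
  idx <- temporal_split(cbind(ai$manifest, row = seq_len(nrow(ai$manifest))),
                        train_years, test_years)
  if (!nrow(idx$train) || !nrow(idx$test)) {
    stop("temporal split leaves an empty training or test set",
         call. = FALSE)
  }
  k <- length(ai$variables)
  model <- model_builder(k)
  model <- fit_model(model,
                     ai$x[idx$train$row, , , drop = FALSE],
                     ai$y[idx$train$row], control)
  rows <- list()
  preds <- list()
  for (yr in sort(unique(idx$test$year))) {
    sel <- idx$test$row[idx$test$year == yr]
    p <- predict(model, ai$x[sel, , , drop = FALSE])
    m <- compute_metrics(ai$y[sel], p)
    rows[[as.character(yr)]] <- data.frame(
      combo = combo_label(groups), test_year = yr, k = k,
      r2 = m$r2, rmse = m$rmse, mae = m$mae, mape = m$mape
    )
    preds[[as.character(yr)]] <- data.frame(
      county_id = idx$test$county_id[idx$test$year == yr], year = yr,
      observed = ai$y[sel], predicted = p
    )
  }
  list(model = model, scaler = scaler,
       metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
       predictions = do.call(rbind, c(preds, make.row.names = FALSE)))
}

#' Variable-group ablation
#'
#' Trains one model per variable combination under the temporal protocol and
#' tabulates its test metrics, mirroring the single-group and pairwise-group
#' comparison of the source study (SV, ED, PP, SV+ED, SV+PP, ED+PP). Each
#' combination is retrained from the same seed rather than reusing weights.
#'
#' @inheritParams evaluate_combo
#' @param combos List of group vectors; default the six standard ones.
#' @return Data frame of class `eval_report`: one row per combination and
#'   test year with `r2`, `rmse`, `mae`, `mape`.
#' @export
run_ablation <- function(panel, yields, model_builder,
                         combos = default_ablation_combos(),
                         control = train_control(),
                         train_years = 2008:2018,
                         test_years = 2019:2020) {
  if (!length(combos)) stop("no variable combinations given", call. = FALSE)
  out <- lapply(combos, function(g) {
    evaluate_combo(panel, yields, model_builder, g, control,
                   train_years, test_years)$metrics
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("eval_report", "data.frame")
  res
}

resolve_predict_fn <- function(model) {
  if (is.function(model)) return(model)
  function(x) stats::predict(model, x)
}

#' Per-variable importance by sampled Shapley values
#'
#' Model-agnostic attribution over the 21 (or k) variables: a variable's
#' four-month block is toggled between the evaluated instance and a
#' background (training-mean) instance. For each sampled permutation the
#' variables are switched on in order and the marginal change in prediction
#' is credited to the variable just added; a variable's Shapley value per
#' instance is its mean marginal contribution, and the reported score is the
#' mean absolute Shapley value across instances. A variable the model is
#' insensitive to receives an exact zero. A faster permutation-importance
#' alternative (increase in RMSE when the variable's block is shuffled
#' across records) is available.
#'
#' @param model A fitted model, or a prediction function `(x array) ->`
#'   numeric.
#' @param x Input array `(records, months, variables)` (scaled as for
#'   training).
#' @param n_samples Number of sampled permutations (Shapley) or shuffles
#'   (permutation method); must be >= 1.
#' @param seed RNG seed.
#' @param method `"shapley"` (default) or `"permutation"`.
#' @param background Background instance for Shapley: `(months, variables)`
#'   matrix; defaults to the mean over records of `x`.
#' @param y Observed targets; required for `method = "permutation"`.
#' @param variables Optional variable names for the output.
#' @return Data frame with `variable` and nonnegative `score`, sorted
#'   decreasing.
#' @export
feature_importance <- function(model, x, n_samples = 128L, seed = 1L,
                               method = c("shapley", "permutation"),
                               background = NULL, y = NULL,
                               variables = NULL) {
  method <- match.arg(method)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  stopifnot(length(dim(x)) == 3)
  f <- resolve_predict_fn(model)
  n <- dim(x)[1]
  k <- dim(x)[3]
  if (is.null(variables)) {
    variables <- dimnames(x)[[3]]
    if (is.null(variables)) variables <- paste0("V", seq_len(k))
  }

  if (method == "shapley") {
    if (is.null(background)) {
      background <- apply(x, c(2, 3), mean)
    }
    bg <- array(rep(background, each = n), dim(x))
    phi <- matrix(0, n, k)
    with_seed(seed, {
      for (s in seq_len(n_samples)) {
        ord <- sample.int(k)
        cur <- bg
        prev <- f(cur)
        for (v in ord) {
          cur[, , v] <- x[, , v]
          now <- f(cur)
          phi[, v] <- phi[, v] + (now - prev)
          prev <- now
        }
      }
    })
    phi <- phi / n_samples
    score <- colMeans(abs(phi))
  } else {
    if (is.null(y)) stop("permutation importance needs y", call. = FALSE)
    base_rmse <- sqrt(mean((f(x) - y)^2))
    score <- numeric(k)
    with_seed(seed, {
      for (v in seq_len(k)) {
        acc <- 0
        for (s in seq_len(n_samples)) {
          xp <- x
          xp[, , v] <- xp[sample.int(n), , v]
          acc <- acc + sqrt(mean((f(xp) - y)^2)) - base_rmse
        }
        score[v] <- max(0, acc / n_samples)
      }
    })
  }
  out <- data.frame(variable = variables, score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score), ]
}

#' Month-by-month correlation of photosynthesis variables with yield
#'
#' Pearson correlation between each photosynthesis-related variable's monthly
#' value and county yield, per calendar month May--August (optionally per
#' year), the table used to show the within-season accumulation of the
#' photosynthesis-yield relationship.
#'
#' @param panel A `feature_panel`.
#' @param yields A `yield_table`.
#' @param months Months to tabulate (default 5:8).
#' @param variables Variables to include (default the PP group).
#' @param by_year If `TRUE`, a separate table row per year.
#' @return Data frame with `month` (and `year` if requested), one column per
#'   variable; zero-variance cells are `NA` with a warning.
#' @export
monthly_pp_correlation <- function(panel, yields, months = 5:8,
                                   variables = group_variables("PP"),
                                   by_year = FALSE) {
  panel <- as_feature_panel(panel)
  yields <- as_yield_table(yields)
  merged <- merge(panel, yields[c("county_id", "year", "yield_bu_ac")],
                  by = c("county_id", "year"))
  cell <- function(sub, v) {
    if (nrow(sub) < 3) return(NA_real_)
    if (stats::sd(sub[[v]]) == 0 || stats::sd(sub$yield_bu_ac) == 0) {
      warning("zero-variance cell for ", v, ": correlation undefined",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(sub[[v]], sub$yield_bu_ac)
  }
  grid <- if (by_year) {
    expand.grid(month = months, year = sort(unique(merged$year)),
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(month = months)
  }
  for (v in variables) {
    grid[[v]] <- vapply(seq_len(nrow(grid)), function(i) {
      sub <- merged[merged$month == grid$month[i], ]
      if (by_year) sub <- sub[sub$year == grid$year[i], ]
      cell(sub, v)
    }, numeric(1))
  }
  grid
}
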