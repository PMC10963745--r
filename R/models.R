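#' Configuration of the CNN-BiGRU-attention yield network
#'
#' The default values are the published architecture: a 1-D convolution over
#' the four-month axis with the k input variables as channels and 256 output
#' channels (kernel 3, length-preserving padding), size-2 max pooling over
#' the month axis (4 -> 2 steps), batch normalization, ReLU and dropout 0.2;
#' a 3-layer bidirectional GRU with 512 hidden units per direction; additive
#' attention over the two remaining time steps producing a 1024-dimensional
#' context; and a fully connected head 1024 -> 256 -> 256 -> 1.
#'
#' @param in_variables Number of input variables k (21 for the full panel,
#'   smaller under ablation).
#' @param conv_channels Convolution output channels (default 256).
#' @param kernel Convolution kernel size over the month axis (default 3).
#' @param pool Pooling size over the month axis (default 2).
#' @param dropout Dropout rate after the convolution block (default 0.2).
#' @param gru_hidden Hidden units per GRU direction (default 512).
#' @param gru_layers Stacked bidirectional GRU layers (default 3).
#' @param fc_hidden Hidden widths of the fully connected head (default
#'   `c(256, 256)`; the head input is always `2 * gru_hidden`).
#' @param attn_dim Width of the additive-attention projection (default 128).
#' @param n_months Input sequence length (default 4, May..August).
#' @param seed Seed for parameter initialization.
#' @return List of class `gcba_config`.
#' @export
gcba_config <- function(in_variables = 21L, conv_channels = 256L,
                        kernel = 3L, pool = 2L, dropout = 0.2,
                        gru_hidden = 512L, gru_layers = 3L,
                        fc_hidden = c(256L, 256L), attn_dim = 128L,
                        n_months = 4L, seed = 1L) {
  if (n_months < kernel) {
    stop("sequence length ", n_months, " shorter than kernel ", kernel,
         call. = FALSE)
  }
  if (n_months %% pool != 0) {
    stop("pool size ", pool, " must divide the sequence length ", n_months,
         call. = FALSE)
  }
  if (in_variables < 1) stop("need at least one input variable",
                             call. = FALSE)
  structure(list(in_variables = as.integer(in_variables),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dropout = dropout, gru_hidden = as.integer(gru_hidden),
                 gru_layers = as.integer(gru_layers),
                 fc_hidden = as.integer(fc_hidden),
                 attn_dim = as.integer(attn_dim),
                 n_months = as.integer(n_months), seed = as.integer(seed)),
            class = "gcba_config")
}

new_deep_model <- function(kind, config, layers, extra_class = character(0)) {
  structure(list(kind = kind, config = config, layers = layers,
                 history = NULL, trained = FALSE),
            class = c(extra_class, "deep_model", "yield_model"))
}

#' Build the CNN-BiGRU-attention regressor
#'
#' @param config A [gcba_config()].
#' @return An untrained model of class `gcba_model`. Fit with [fit_model()]
#'   and predict with `predict()`; per-sample attention weights are available
#'   through [gcba_attention()].
#' @examples
#' m <- build_gcba(gcba_config(in_variables = 5, conv_channels = 8,
#'                             gru_hidden = 4, attn_dim = 6,
#'                             fc_hidden = c(8)))
#' x <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
#' length(predict(m, x))
#' @export
build_gcba <- function(config = gcba_config()) {
  stopifnot(inherits(config, "gcba_config"))
  ctx_dim <- 2L * config$gru_hidden
  layers <- with_seed(config$seed, {
    head_in <- c(ctx_dim, config$fc_hidden)
    head <- lapply(seq_along(config$fc_hidden), function(i) {
      layer_dense(head_in[i], head_in[i + 1], "relu")
    })
    c(
      list(
        layer_conv1d(config$in_variables, config$conv_channels,
                     config$kernel),
        layer_pool(config$pool),
        layer_batchnorm(config$conv_channels),
        layer_relu(),
        layer_dropout(config$dropout),
        layer_gru(config$conv_channels, config$gru_hidden,
                  config$gru_layers, bidirectional = TRUE),
        layer_attention(ctx_dim, config$attn_dim)
      ),
      head,
      list(layer_dense(utils::tail(head_in, 1), 1L, "linear"))
    )
  })
  new_deep_model("gcba", config, layers, "gcba_model")
}

#' Build one of the five comparison models
#'
#' * `"SVR"`: support-vector regression (RBF kernel, C = 100, gamma = 0.1,
#'   selected upstream by fivefold cross-validation) on the flattened
#'   4k-vector of monthly values.
#' * `"RFR"`: random-forest regression (200 trees, minimum leaf size 4) on
#'   the same flattened vectors.
#' * `"CNN"`: two 1-D convolution layers with ReLU, flatten, dense head.
#' * `"GRU"`: stacked unidirectional GRU, last hidden state, dense head.
#' * `"CNN-GRU"`: convolution + pooling + batch normalization + ReLU, then
#'   GRU layers and a dense head.
#'
#' The deep baselines share the GCBA hyperparameters (channels, hidden units,
#' layer count, dropout and the training recipe).
#'
#' @param name One of `"SVR"`, `"RFR"`, `"CNN"`, `"GRU"`, `"CNN-GRU"`.
#' @param config A [gcba_config()] providing the shared hyperparameters
#'   (ignored by SVR/RFR except for `in_variables`).
#' @param svr Optional list overriding `cost`, `gamma`, `cv_folds`.
#' @param rfr Optional list overriding `n_estimators`, `min_samples_leaf`,
#'   `cv_folds`.
#' @return An untrained model object; fit with [fit_model()].
#' @export
build_baseline <- function(name, config = gcba_config(),
                           svr = list(), rfr = list()) {
  valid <- c("SVR", "RFR", "CNN", "GRU", "CNN-GRU")
  if (!name %in% valid) {
    stop("unknown model '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  k <- config$in_variables
  tt <- config$n_months
  switch(name,
    "SVR" = structure(list(
      kind = "svr", config = config,
      control = utils::modifyList(list(kernel = "radial", cost = 100,
                                       gamma = 0.1, cv_folds = 5), svr),
      fit = NULL, trained = FALSE
    ), class = c("svr_model", "yield_model")),
    "RFR" = structure(list(
      kind = "rfr", config = config,
      control = utils::modifyList(list(n_estimators = 200,
                                       min_samples_leaf = 4, cv_folds = 5),
                                  rfr),
      fit = NULL, trained = FALSE
    ), class = c("rfr_model", "yield_model")),
    "CNN" = {
      cc <- config$conv_channels
      layers <- with_seed(config$seed, list(
        layer_conv1d(k, cc, config$kernel),
        layer_relu(),
        layer_conv1d(cc, cc, config$kernel),
        layer_relu(),
        layer_flatten(),
        layer_dense(tt * cc, 1L, "linear")
      ))
      new_deep_model("cnn", config, layers, "cnn_model")
    },
    "GRU" = {
      h <- config$gru_hidden
      layers <- with_seed(config$seed, list(
        layer_gru(k, h, config$gru_layers, bidirectional = FALSE),
        layer_take_last(),
        layer_dense(h, 1L, "linear")
      ))
      new_deep_model("gru", config, layers, "gru_model")
    },
    "CNN-GRU" = {
      cc <- config$conv_channels
      h <- config$gru_hidden
      layers <- with_seed(config$seed, list(
        layer_conv1d(k, cc, config$kernel),
        layer_pool(config$pool),
        layer_batchnorm(cc),
        layer_relu(),
        layer_gru(cc, h, config$gru_layers, bidirectional = FALSE),
        layer_take_last(),
        layer_dense(h, 1L, "linear")
      ))
      new_deep_model("cnn_gru", config, layers, "cnn_gru_model")
    }
  )
}

#' Training recipe for the deep models
#'
#' Defaults are the published recipe: Huber loss, Adam, learning rate 1e-4,
#' 200 epochs. Batch size 64 and Huber delta 1 are package defaults.
#'
#' @param loss Only `"huber"` is implemented.
#' @param delta Huber transition point in bu/ac (default 1).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 200).
#' @param batch_size Minibatch size (default 64).
#' @param seed Seed controlling shuffling and dropout.
#' @param init_output_bias If `TRUE` (default) the output bias starts at the
#'   mean training yield, centering the regression before optimization.
#' @param verbose Print the loss every 10 epochs.
#' @return List of class `train_control`.
#' @export
train_control <- function(loss = "huber", delta = 1, lr = 1e-4,
                          epochs = 200L, batch_size = 64L, seed = 1L,
                          init_output_bias = TRUE, verbose = FALSE) {
  stopifnot(loss == "huber", lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(loss = loss, delta = delta, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init_output_bias = init_output_bias, verbose = verbose),
            class = "train_control")
}

check_inputs <- function(x, y, k = NULL) {
  if (length(dim(x)) != 3) {
    stop("inputs must be a (records, months, variables) array",
         call. = FALSE)
  }
  if (dim(x)[1] != length(y)) {
    stop("inputs and targets are not aligned: ", dim(x)[1], " vs ",
         length(y), call. = FALSE)
  }
  if (!is.null(k) && dim(x)[3] != k) {
    stop("model expects ", k, " variables, got ", dim(x)[3], call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a yield model
#'
#' Deep models are trained with minibatch Adam on Huber loss against raw
#' bu/ac targets; the run is deterministic given the control seed. SVR and
#' RFR dispatch to their library implementations on flattened inputs.
#'
#' @param model An untrained model from [build_gcba()] or [build_baseline()].
#' @param x Numeric array `(records, months, variables)`.
#' @param y Numeric vector of yields (bu/ac).
#' @param control A [train_control()].
#' @return The fitted model; deep models carry `history`, the epoch-wise mean
#'   training loss.
#' @export
fit_model <- function(model, x, y, control = train_control()) {
  UseMethod("fit_model")
}

#' @export
fit_model.deep_model <- function(model, x, y, control = train_control()) {
  check_inputs(x, y, model$config$in_variables)
  n <- dim(x)[1]
  layers <- model$layers
  out_layer <- layers[[length(layers)]]
  if (control$init_output_bias) {
    out_layer$env$b <- mean(y)
  }
  opt <- adam_init(layers)
  history <- numeric(control$epochs)
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      idx <- sample.int(n)
      total <- 0
      for (start in seq(1, n, by = control$batch_size)) {
        bi <- idx[start:min(start + control$batch_size - 1, n)]
        xb <- x[bi, , , drop = FALSE]
        fwd <- nn_forward(layers, xb, training = TRUE)
        pred <- drop(fwd$out)
        hl <- huber_loss(pred, y[bi], control$delta)
        if (!is.finite(hl$loss)) {
          stop("non-finite training loss at epoch ", ep,
               " (batch starting at ", start, "); check inputs and learning",
               " rate", call. = FALSE)
        }
        total <- total + hl$loss * length(bi)
        grads <- nn_backward(layers, fwd$caches,
                             matrix(hl$grad, ncol = 1))
        adam_step(layers, grads, opt, control$lr)
      }
      history[ep] <- total / n
      if (control$verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d loss %.4f", ep, history[ep]))
      }
    }
  })
  model$history <- history
  model$trained <- TRUE
  model$control <- control
  model
}

flatten_inputs <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

#' @export
fit_model.svr_model <- function(model, x, y, control = train_control()) {
  check_inputs(x, y)
  ctl <- model$control
  model$fit <- e1071::svm(x = flatten_inputs(x), y = y,
                          type = "eps-regression", kernel = ctl$kernel,
                          cost = ctl$cost, gamma = ctl$gamma, scale = FALSE)
  model$trained <- TRUE
  model
}

#' @export
fit_model.rfr_model <- function(model, x, y, control = train_control()) {
  check_inputs(x, y)
  ctl <- model$control
  model$fit <- with_seed(control$seed, {
    randomForest::randomForest(x = flatten_inputs(x), y = y,
                               ntree = ctl$n_estimators,
                               nodesize = ctl$min_samples_leaf)
  })
  model$trained <- TRUE
  model
}

#' Predict yields from a fitted model
#'
#' Deep models run in inference mode (dropout off, batch-norm running
#' statistics), so repeated predictions on the same input are identical.
#'
#' @param object A fitted model.
#' @param x Input array `(records, months, variables)`.
#' @param ... Unused.
#' @return Numeric vector of predicted yields (bu/ac).
#' @export
predict.deep_model <- function(object, x, ...) {
  check_inputs(x, rep(0, dim(x)[1]), object$config$in_variables)
  drop(nn_forward(object$layers, x, training = FALSE)$out)
}

#' @export
predict.svr_model <- function(object, x, ...) {
  if (!object$trained) stop("model is not fitted", call. = FALSE)
  unname(stats::predict(object$fit, flatten_inputs(x)))
}

#' @export
predict.rfr_model <- function(object, x, ...) {
  if (!object$trained) stop("model is not fitted", call. = FALSE)
  unname(stats::predict(object$fit, flatten_inputs(x)))
}

#' @export
print.deep_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    sum(vapply(l$param_names, function(nm) length(l$env[[nm]]), 0))
  }, 0))
  cat(toupper(x$kind), "yield model: ", x$config$in_variables,
      " variables, ", format(n_par, big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Additive attention pooling over recurrent hidden states
#'
#' Scores each time step with `e_t = v' tanh(Wa' h_t + ba)`, normalizes the
#' scores with a softmax, and returns the weighted combination of the hidden
#' states. With a single time step the weight is exactly 1; identical hidden
#' states across time receive uniform weights.
#'
#' @param hidden_states Matrix `(time, d)` of per-step hidden states.
#' @param Wa,ba,v Attention parameters (`d x a` matrix, length-`a` bias,
#'   length-`a` scoring vector). When omitted they are drawn once from a
#'   fixed-seed uniform initialization of width `attn_dim`.
#' @param attn_dim Projection width used when parameters are omitted.
#' @return List with `context` (length-`d` vector) and `weights` (length-time
#'   softmax weights).
#' @export
attention_pool <- function(hidden_states, Wa = NULL, ba = NULL, v = NULL,
                           attn_dim = 16L) {
  h <- as.matrix(hidden_states)
  d <- ncol(h)
  if (is.null(Wa) || is.null(ba) || is.null(v)) {
    l <- with_seed(1L, layer_attention(d, attn_dim))
    if (is.null(Wa)) Wa <- l$env$Wa
    if (is.null(ba)) ba <- l$env$ba
    if (is.null(v)) v <- l$env$v
  }
  u <- tanh(sweep(h %*% Wa, 2, ba, "+"))
  e <- drop(u %*% v)
  e <- e - max(e)
  w <- exp(e) / sum(exp(e))
  list(context = drop(crossprod(h, w)), weights = w)
}

#' Per-sample attention weights of a GCBA model
#'
#' @param model A `gcba_model`.
#' @param x Input array `(records, months, variables)`.
#' @return Matrix `(records, pooled time steps)` of softmax weights; each row
#'   sums to 1.
#' @export
gcba_attention <- function(model, x) {
  stopifnot(inherits(model, "gcba_model"))
  layers <- model$layers
  ai <- which(vapply(layers, `[[`, "", "type") == "attention")
  fwd_to <- layers[seq_len(ai - 1)]
  h <- nn_forward(fwd_to, x, training = FALSE)$out
  attn_forward(layers[[ai]], h)$cache$alpha
}
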