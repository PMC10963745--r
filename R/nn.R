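# Minimal neural-network toolkit for the yield models.
#
# Tensors are base-R 3D arrays (batch, time, channels); matrix products go
# through BLAS by collapsing (batch, time) into rows, which is exact because R
# arrays are column-major. Each layer is a list holding its type, shape
# configuration and an environment `env` with its parameters (and, for batch
# norm, running statistics), so optimizer updates mutate in place. Backward
# passes are written by hand and verified against finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# (B,T,C) array -> (B*T, C) matrix; row index runs over batch fastest
mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

arr3 <- function(x, b, t) {
  dim(x) <- c(b, t, ncol(x))
  x
}

# time-slice of a (B,T,C) array as a (B,C) matrix, safe for B == 1
tslice <- function(x, t) {
  d <- dim(x)
  m <- x[, t, , drop = FALSE]
  dim(m) <- c(d[1], d[3])
  m
}

uinit <- function(nr, nc, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

## ---- layer constructors -------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, kernel = 3) {
  stopifnot(kernel %% 2 == 1)
  env <- new.env(parent = emptyenv())
  env$W <- uinit(kernel * in_ch, out_ch, kernel * in_ch)
  env$b <- stats::runif(out_ch, -1, 1) / sqrt(kernel * in_ch)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       pad = (kernel - 1) %/% 2, env = env, param_names = c("W", "b"))
}

layer_pool <- function(size = 2) {
  list(type = "pool", size = size, env = new.env(parent = emptyenv()),
       param_names = character(0))
}

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  env <- new.env(parent = emptyenv())
  env$gamma <- rep(1, ch)
  env$beta <- rep(0, ch)
  env$running_mean <- rep(0, ch)
  env$running_var <- rep(1, ch)
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       env = env, param_names = c("gamma", "beta"))
}

layer_relu <- function() {
  list(type = "relu", env = new.env(parent = emptyenv()),
       param_names = character(0))
}

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, env = new.env(parent = emptyenv()),
       param_names = character(0))
}

layer_gru <- function(in_size, hidden, n_layers = 1, bidirectional = FALSE) {
  env <- new.env(parent = emptyenv())
  dirs <- if (bidirectional) c("f", "b") else "f"
  pn <- character(0)
  for (l in seq_len(n_layers)) {
    isz <- if (l == 1) in_size else hidden * length(dirs)
    for (d in dirs) {
      pre <- paste0("l", l, d, ".")
      env[[paste0(pre, "Wx")]] <- uinit(isz, 3 * hidden, hidden)
      env[[paste0(pre, "Wh")]] <- uinit(hidden, 3 * hidden, hidden)
      env[[paste0(pre, "bx")]] <- stats::runif(3 * hidden, -1, 1) /
        sqrt(hidden)
      env[[paste0(pre, "bh")]] <- stats::runif(3 * hidden, -1, 1) /
        sqrt(hidden)
      pn <- c(pn, paste0(pre, c("Wx", "Wh", "bx", "bh")))
    }
  }
  list(type = "gru", in_size = in_size, hidden = hidden, n_layers = n_layers,
       bidirectional = bidirectional, env = env, param_names = pn)
}

layer_attention <- function(in_size, attn_dim) {
  env <- new.env(parent = emptyenv())
  env$Wa <- uinit(in_size, attn_dim, in_size)
  env$ba <- rep(0, attn_dim)
  env$v <- stats::runif(attn_dim, -1, 1) / sqrt(attn_dim)
  list(type = "attention", in_size = in_size, attn_dim = attn_dim, env = env,
       param_names = c("Wa", "ba", "v"))
}

layer_take_last <- function() {
  list(type = "take_last", env = new.env(parent = emptyenv()),
       param_names = character(0))
}

layer_flatten <- function() {
  list(type = "flatten", env = new.env(parent = emptyenv()),
       param_names = character(0))
}

layer_dense <- function(in_size, out_size, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  env <- new.env(parent = emptyenv())
  env$W <- uinit(in_size, out_size, in_size)
  env$b <- stats::runif(out_size, -1, 1) / sqrt(in_size)
  list(type = "dense", in_size = in_size, out_size = out_size,
       activation = activation, env = env, param_names = c("W", "b"))
}

## ---- forward / backward -------------------------------------------------

conv1d_forward <- function(l, x) {
  d <- dim(x)
  b <- d[1]; tt <- d[2]; cin <- d[3]
  stopifnot(cin == l$in_ch)
  p <- l$pad; k <- l$kernel
  xp <- array(0, c(b, tt + 2 * p, cin))
  xp[, (p + 1):(p + tt), ] <- x
  patches <- matrix(0, b * tt, k * cin)
  for (j in seq_len(k)) {
    seg <- xp[, j:(j + tt - 1), , drop = FALSE]
    patches[, ((j - 1) * cin + 1):(j * cin)] <- mat3(seg)
  }
  out <- sweep(patches %*% l$env$W, 2, l$env$b, "+")
  list(out = arr3(out, b, tt),
       cache = list(patches = patches, b = b, tt = tt))
}

conv1d_backward <- function(l, cache, dout) {
  b <- cache$b; tt <- cache$tt; cin <- l$in_ch; k <- l$kernel; p <- l$pad
  dflat <- mat3(dout)
  dW <- crossprod(cache$patches, dflat)
  db <- colSums(dflat)
  dpatch <- tcrossprod(dflat, l$env$W)
  dxp <- array(0, c(b, tt + 2 * p, cin))
  for (j in seq_len(k)) {
    seg <- dpatch[, ((j - 1) * cin + 1):(j * cin), drop = FALSE]
    dxp[, j:(j + tt - 1), ] <- dxp[, j:(j + tt - 1), , drop = FALSE] +
      arr3(seg, b, tt)
  }
  list(dx = dxp[, (p + 1):(p + tt), , drop = FALSE],
       grads = list(W = dW, b = db))
}

pool_forward <- function(l, x) {
  d <- dim(x)
  s <- l$size
  if (d[2] %% s != 0 || d[2] < s) {
    stop("sequence length ", d[2], " not divisible by pool size ", s,
         call. = FALSE)
  }
  stopifnot(s == 2)  # the month axis pools 4 -> 2
  x1 <- x[, seq(1, d[2], 2), , drop = FALSE]
  x2 <- x[, seq(2, d[2], 2), , drop = FALSE]
  m <- x1 >= x2
  list(out = pmax(x1, x2), cache = list(m = m, d = d))
}

pool_backward <- function(l, cache, dout) {
  d <- cache$d
  dx <- array(0, d)
  dx[, seq(1, d[2], 2), ] <- dout * cache$m
  dx[, seq(2, d[2], 2), ] <- dout * !cache$m
  list(dx = dx, grads = NULL)
}

bn_forward <- function(l, x, training) {
  d <- dim(x)
  xm <- mat3(x)
  n <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    # running stats use the unbiased variance
    l$env$running_mean <- (1 - l$momentum) * l$env$running_mean +
      l$momentum * mu
    l$env$running_var <- (1 - l$momentum) * l$env$running_var +
      l$momentum * v * n / max(n - 1, 1)
  } else {
    mu <- l$env$running_mean
    v <- l$env$running_var
    xc <- sweep(xm, 2, mu)
  }
  ivar <- 1 / sqrt(v + l$eps)
  xhat <- sweep(xc, 2, ivar, "*")
  out <- sweep(sweep(xhat, 2, l$env$gamma, "*"), 2, l$env$beta, "+")
  list(out = arr3(out, d[1], d[2]),
       cache = list(xhat = xhat, xc = xc, ivar = ivar, d = d,
                    training = training))
}

bn_backward <- function(l, cache, dout) {
  d <- cache$d
  dy <- mat3(dout)
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, l$env$gamma, "*")
  if (cache$training) {
    ivar <- cache$ivar
    dvar <- colSums(dxhat * cache$xc) * (-0.5) * ivar^3
    dmu <- -colSums(dxhat) * ivar + dvar * (-2) * colMeans(cache$xc)
    dx <- sweep(dxhat, 2, ivar, "*") +
      sweep(cache$xc, 2, 2 * dvar / n, "*") +
      matrix(dmu / n, n, length(dmu), byrow = TRUE)
  } else {
    dx <- sweep(dxhat, 2, cache$ivar, "*")
  }
  list(dx = arr3(dx, d[1], d[2]),
       grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(l, x) {
  m <- x > 0
  list(out = x * m, cache = list(m = m))
}

relu_backward <- function(l, cache, dout) {
  list(dx = dout * cache$m, grads = NULL)
}

dropout_forward <- function(l, x, training) {
  if (!training || l$rate == 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- array(stats::runif(length(x)) >= l$rate, dim(x)) / (1 - l$rate)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(l, cache, dout) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = NULL))
  list(dx = dout * cache$mask, grads = NULL)
}

gru_dir_forward <- function(x, wx, wh, bx, bh, reverse = FALSE) {
  d <- dim(x)
  b <- d[1]; tt <- d[2]
  h_sz <- nrow(wh)
  ir <- 1:h_sz; iz <- (h_sz + 1):(2 * h_sz); inn <- (2 * h_sz + 1):(3 * h_sz)
  a_all <- sweep(mat3(x) %*% wx, 2, bx, "+")
  h <- matrix(0, b, h_sz)
  out <- array(0, c(b, tt, h_sz))
  cache <- vector("list", tt)
  ts <- if (reverse) tt:1 else 1:tt
  for (t in ts) {
    a <- a_all[(t - 1) * b + seq_len(b), , drop = FALSE]
    g <- sweep(h %*% wh, 2, bh, "+")
    r <- sigmoid(a[, ir] + g[, ir])
    z <- sigmoid(a[, iz] + g[, iz])
    gn <- g[, inn]
    nn <- tanh(a[, inn] + r * gn)
    cache[[t]] <- list(h_prev = h, r = r, z = z, n = nn, gn = gn)
    h <- (1 - z) * nn + z * h
    out[, t, ] <- h
  }
  list(out = out, cache = cache)
}

gru_dir_backward <- function(x, dout, wx, wh, cache, reverse = FALSE) {
  d <- dim(x)
  b <- d[1]; tt <- d[2]
  h_sz <- nrow(wh)
  da_all <- matrix(0, b * tt, 3 * h_sz)
  dwh <- matrix(0, h_sz, 3 * h_sz)
  dbh <- numeric(3 * h_sz)
  dh <- matrix(0, b, h_sz)
  ts <- if (reverse) tt:1 else 1:tt
  for (t in rev(ts)) {
    dh <- dh + tslice(dout, t)
    cc <- cache[[t]]
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    dn_pre <- dn * (1 - cc$n^2)
    dgn <- dn_pre * cc$r
    dr <- dn_pre * cc$gn
    dr_pre <- dr * cc$r * (1 - cc$r)
    dz_pre <- dz * cc$z * (1 - cc$z)
    da <- cbind(dr_pre, dz_pre, dn_pre)
    dg <- cbind(dr_pre, dz_pre, dgn)
    dwh <- dwh + crossprod(cc$h_prev, dg)
    dbh <- dbh + colSums(dg)
    da_all[(t - 1) * b + seq_len(b), ] <- da
    dh <- dh_prev + tcrossprod(dg, wh)
  }
  dwx <- crossprod(mat3(x), da_all)
  dbx <- colSums(da_all)
  dx <- arr3(tcrossprod(da_all, wx), b, tt)
  list(dx = dx, dWx = dwx, dWh = dwh, dbx = dbx, dbh = dbh)
}

gru_forward <- function(l, x) {
  dirs <- if (l$bidirectional) c("f", "b") else "f"
  inputs <- vector("list", l$n_layers)
  caches <- list()
  for (ll in seq_len(l$n_layers)) {
    inputs[[ll]] <- x
    outs <- list()
    for (dd in dirs) {
      pre <- paste0("l", ll, dd, ".")
      r <- gru_dir_forward(x, l$env[[paste0(pre, "Wx")]],
                           l$env[[paste0(pre, "Wh")]],
                           l$env[[paste0(pre, "bx")]],
                           l$env[[paste0(pre, "bh")]],
                           reverse = dd == "b")
      outs[[dd]] <- r$out
      caches[[pre]] <- r$cache
    }
    x <- if (l$bidirectional) {
      d <- dim(outs$f)
      y <- array(0, c(d[1], d[2], 2 * d[3]))
      y[, , 1:d[3]] <- outs$f
      y[, , (d[3] + 1):(2 * d[3])] <- outs$b
      y
    } else outs$f
  }
  list(out = x, cache = list(inputs = inputs, dir_caches = caches))
}

gru_backward <- function(l, cache, dout) {
  dirs <- if (l$bidirectional) c("f", "b") else "f"
  h_sz <- l$hidden
  grads <- list()
  for (ll in rev(seq_len(l$n_layers))) {
    x <- cache$inputs[[ll]]
    dx_next <- NULL
    for (dd in dirs) {
      pre <- paste0("l", ll, dd, ".")
      dslice <- if (l$bidirectional && dd == "b") {
        dout[, , (h_sz + 1):(2 * h_sz), drop = FALSE]
      } else {
        dout[, , 1:h_sz, drop = FALSE]
      }
      r <- gru_dir_backward(x, dslice, l$env[[paste0(pre, "Wx")]],
                            l$env[[paste0(pre, "Wh")]],
                            cache$dir_caches[[pre]],
                            reverse = dd == "b")
      grads[[paste0(pre, "Wx")]] <- r$dWx
      grads[[paste0(pre, "Wh")]] <- r$dWh
      grads[[paste0(pre, "bx")]] <- r$dbx
      grads[[paste0(pre, "bh")]] <- r$dbh
      dx_next <- if (is.null(dx_next)) r$dx else dx_next + r$dx
    }
    dout <- dx_next
  }
  list(dx = dout, grads = grads)
}

attn_forward <- function(l, x) {
  d <- dim(x)
  b <- d[1]; tt <- d[2]
  u <- vector("list", tt)
  e <- matrix(0, b, tt)
  for (t in seq_len(tt)) {
    u[[t]] <- tanh(sweep(tslice(x, t) %*% l$env$Wa, 2, l$env$ba, "+"))
    e[, t] <- u[[t]] %*% l$env$v
  }
  e <- e - apply(e, 1, max)
  alpha <- exp(e) / rowSums(exp(e))
  ctx <- matrix(0, b, d[3])
  for (t in seq_len(tt)) {
    ctx <- ctx + alpha[, t] * tslice(x, t)
  }
  list(out = ctx, cache = list(x = x, u = u, alpha = alpha))
}

attn_backward <- function(l, cache, dout) {
  x <- cache$x
  d <- dim(x)
  b <- d[1]; tt <- d[2]
  alpha <- cache$alpha
  dalpha <- matrix(0, b, tt)
  dx <- array(0, d)
  for (t in seq_len(tt)) {
    xt <- tslice(x, t)
    dalpha[, t] <- rowSums(dout * xt)
    dx[, t, ] <- alpha[, t] * dout
  }
  de <- alpha * (dalpha - rowSums(alpha * dalpha))
  dWa <- matrix(0, nrow(l$env$Wa), ncol(l$env$Wa))
  dba <- numeric(length(l$env$ba))
  dv <- numeric(length(l$env$v))
  for (t in seq_len(tt)) {
    ut <- cache$u[[t]]
    dv <- dv + colSums(ut * de[, t])
    du <- tcrossprod(de[, t], l$env$v)
    du_pre <- du * (1 - ut^2)
    dWa <- dWa + crossprod(tslice(x, t), du_pre)
    dba <- dba + colSums(du_pre)
    dx[, t, ] <- dx[, t, ] + tcrossprod(du_pre, l$env$Wa)
  }
  list(dx = dx, grads = list(Wa = dWa, ba = dba, v = dv))
}

take_last_forward <- function(l, x) {
  d <- dim(x)
  list(out = tslice(x, d[2]), cache = list(d = d))
}

take_last_backward <- function(l, cache, dout) {
  dx <- array(0, cache$d)
  dx[, cache$d[2], ] <- dout
  list(dx = dx, grads = NULL)
}

flatten_forward <- function(l, x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  list(out = x, cache = list(d = d))
}

flatten_backward <- function(l, cache, dout) {
  dim(dout) <- cache$d
  list(dx = dout, grads = NULL)
}

dense_forward <- function(l, x) {
  pre <- sweep(x %*% l$env$W, 2, l$env$b, "+")
  out <- if (l$activation == "relu") pre * (pre > 0) else pre
  list(out = out, cache = list(x = x, pre = pre))
}

dense_backward <- function(l, cache, dout) {
  if (l$activation == "relu") dout <- dout * (cache$pre > 0)
  list(dx = tcrossprod(dout, l$env$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv1d = conv1d_forward(l, x),
      pool = pool_forward(l, x),
      batchnorm = bn_forward(l, x, training),
      relu = relu_forward(l, x),
      dropout = dropout_forward(l, x, training),
      gru = gru_forward(l, x),
      attention = attn_forward(l, x),
      take_last = take_last_forward(l, x),
      flatten = flatten_forward(l, x),
      dense = dense_forward(l, x),
      stop("unknown layer type: ", l$type)
    )
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv1d = conv1d_backward(l, caches[[i]], dout),
      pool = pool_backward(l, caches[[i]], dout),
      batchnorm = bn_backward(l, caches[[i]], dout),
      relu = relu_backward(l, caches[[i]], dout),
      dropout = dropout_backward(l, caches[[i]], dout),
      gru = gru_backward(l, caches[[i]], dout),
      attention = attn_backward(l, caches[[i]], dout),
      take_last = take_last_backward(l, caches[[i]], dout),
      flatten = flatten_backward(l, caches[[i]], dout),
      dense = dense_backward(l, caches[[i]], dout)
    )
    dout <- r$dx
    grads[i] <- list(r$grads)  # keep NULL slots for parameter-free layers
  }
  grads
}

## ---- loss and optimizer -------------------------------------------------

huber_loss <- function(pred, target, delta = 1) {
  e <- pred - target
  small <- abs(e) <= delta
  loss <- mean(ifelse(small, 0.5 * e^2, delta * (abs(e) - 0.5 * delta)))
  grad <- ifelse(small, e, delta * sign(e)) / length(e)
  list(loss = loss, grad = grad)
}

zero_like <- function(x) {
  z <- x
  z[] <- 0
  z
}

adam_init <- function(layers) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- lapply(layers, function(l) {
    stats::setNames(lapply(l$param_names, function(nm) zero_like(l$env[[nm]])),
                    l$param_names)
  })
  opt$v <- lapply(layers, function(l) {
    stats::setNames(lapply(l$param_names, function(nm) zero_like(l$env[[nm]])),
                    l$param_names)
  })
  opt
}

# The update runs in compiled code and mutates parameters and moment
# estimates in place; every array involved is privately owned by the layer /
# optimizer environments, so no user-visible object is aliased.
adam_step <- function(layers, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in l$param_names) {
      adam_update_inplace(l$env[[nm]], grads[[i]][[nm]],
                          opt$m[[i]][[nm]], opt$v[[i]][[nm]],
                          lr, beta1, beta2, eps, bc1, bc2)
    }
  }
  invisible(opt)
}
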