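## Minimal sequence-network machinery used by the forecasters.
##
## Sequence tensors are arrays with dim (channels, time, batch); dense
## inputs are (features, batch) matrices. Each layer is a list holding its
## type, a config list and an environment with parameters `P`, gradient
## accumulators `G`, Adam state `A` and the forward cache. All arithmetic
## is batched matrix algebra so BLAS does the heavy lifting.

sigmoid <- function(x) 1 / (1 + exp(-x))

elu_fun <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

as_mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], d[2L] * d[3L])
  x
}

slice_t <- function(x, t) {
  d <- dim(x)
  matrix(x[, t, ], d[1L], d[3L])
}

new_layer <- function(type, cfg = list()) {
  env <- new.env(parent = emptyenv())
  env$P <- list()
  env$G <- list()
  env$A <- list()
  env$cache <- NULL
  list(type = type, cfg = cfg, env = env)
}

layer_identity <- function(type) new_layer(type)

layer_dense <- function(n_in, n_out) {
  new_layer("dense", list(n_in = n_in, n_out = n_out))
}

layer_lstm <- function(n_in, units, mode = c("sequence", "last")) {
  new_layer("lstm", list(D = n_in, H = units, mode = match.arg(mode)))
}

layer_gru <- function(n_in, units, mode = c("sequence", "last")) {
  new_layer("gru", list(D = n_in, H = units, mode = match.arg(mode)))
}

layer_conv1d <- function(n_in, filters, kernel = 5L, dilation = 1L,
                         elu = FALSE) {
  new_layer("conv1d", list(Cin = n_in, Cout = filters, k = kernel,
                           d = dilation, elu = elu))
}

layer_batchnorm_elu <- function(channels, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("batchnorm_elu", list(C = channels, momentum = momentum,
                                       eps = eps))
  l$env$running_mean <- rep(0, channels)
  l$env$running_var <- rep(1, channels)
  l
}

layer_avgpool <- function(stride = 5L) {
  new_layer("avgpool", list(stride = as.integer(stride)))
}

layer_dropout <- function(p = 0.25) new_layer("dropout", list(p = p))

glorot <- function(n_out, n_in, fan_in = n_in, fan_out = n_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

## (Re-)initialise parameters. Caller controls the RNG scope.
init_layer_params <- function(layer) {
  cfg <- layer$cfg
  e <- layer$env
  e$P <- switch(layer$type,
    dense = list(W = glorot(cfg$n_out, cfg$n_in), b = rep(0, cfg$n_out)),
    lstm = {
      D <- cfg$D; H <- cfg$H
      W <- glorot(4L * H, D + H, fan_in = D + H, fan_out = H)
      b <- rep(0, 4L * H)
      b[seq_len(H)] <- 1 # forget-gate bias starts open
      list(W = W, b = b)
    },
    gru = {
      D <- cfg$D; H <- cfg$H
      list(Wx = glorot(3L * H, D, fan_in = D, fan_out = H),
           Wh = glorot(3L * H, H, fan_in = H, fan_out = H),
           bx = rep(0, 3L * H), bh = rep(0, 3L * H))
    },
    conv1d = {
      W <- array(stats::runif(cfg$Cout * cfg$Cin * cfg$k,
                              -sqrt(6 / (cfg$Cin * cfg$k + cfg$Cout)),
                              sqrt(6 / (cfg$Cin * cfg$k + cfg$Cout))),
                 c(cfg$Cout, cfg$Cin, cfg$k))
      list(W = W, b = rep(0, cfg$Cout))
    },
    batchnorm_elu = list(gamma = rep(1, cfg$C), beta = rep(0, cfg$C)),
    list()
  )
  e$G <- lapply(e$P, function(p) p * 0)
  e$A <- lapply(e$P, function(p) list(m = p * 0, v = p * 0))
  invisible(layer)
}

layer_forward <- function(layer, x, training = FALSE) {
  cfg <- layer$cfg
  e <- layer$env
  switch(layer$type,
    sequence_input = {
      if (is.matrix(x)) dim(x) <- c(1L, nrow(x), ncol(x))
      x
    },
    fold = x,
    unfold_flatten = x,
    dense = {
      e$cache <- x
      e$P$W %*% x + e$P$b
    },
    lstm = forward_lstm(e, cfg, x),
    gru = forward_gru(e, cfg, x),
    conv1d = forward_conv1d(e, cfg, x),
    batchnorm_elu = forward_batchnorm_elu(e, cfg, x, training),
    avgpool = {
      T_ <- dim(x)[2L]
      idx <- seq(cfg$stride, T_, by = cfg$stride)
      if (length(idx) == 0L) {
        stop("architecture error: sequence too short for pooling stride")
      }
      e$cache <- list(T_ = T_, idx = idx)
      x[, idx, , drop = FALSE]
    },
    dropout = {
      if (training) {
        mask <- (stats::runif(length(x)) >= cfg$p) / (1 - cfg$p)
        dim(mask) <- dim(x)
        e$cache <- mask
        x * mask
      } else {
        e$cache <- NULL
        x
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dy) {
  cfg <- layer$cfg
  e <- layer$env
  switch(layer$type,
    sequence_input = dy,
    fold = dy,
    unfold_flatten = dy,
    dense = {
      x <- e$cache
      e$G$W <- e$G$W + dy %*% t(x)
      e$G$b <- e$G$b + rowSums(dy)
      crossprod(e$P$W, dy)
    },
    lstm = backward_lstm(e, cfg, dy),
    gru = backward_gru(e, cfg, dy),
    conv1d = backward_conv1d(e, cfg, dy),
    batchnorm_elu = backward_batchnorm_elu(e, cfg, dy),
    avgpool = {
      ca <- e$cache
      d <- dim(dy)
      dx <- array(0, c(d[1L], ca$T_, d[3L]))
      dx[, ca$idx, ] <- dy
      dx
    },
    dropout = {
      if (is.null(e$cache)) dy else dy * e$cache
    },
    stop("unknown layer type: ", layer$type)
  )
}

forward_lstm <- function(e, cfg, x) {
  D <- cfg$D; H <- cfg$H
  d <- dim(x); T_ <- d[2L]; B <- d[3L]
  if (d[1L] != D) stop("shape error: LSTM expected ", D, " input channels")
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  Fg <- Ig <- Gg <- Og <- TC <- CP <- array(0, c(H, T_, B))
  XH <- array(0, c(D + H, T_, B))
  Y <- if (cfg$mode == "sequence") array(0, c(H, T_, B)) else NULL
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(T_)) {
    xh <- rbind(slice_t(x, t), h)
    z <- e$P$W %*% xh + e$P$b
    f <- sigmoid(z[i1, , drop = FALSE])
    i <- sigmoid(z[i2, , drop = FALSE])
    g <- tanh(z[i3, , drop = FALSE])
    o <- sigmoid(z[i4, , drop = FALSE])
    CP[, t, ] <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    Fg[, t, ] <- f; Ig[, t, ] <- i; Gg[, t, ] <- g; Og[, t, ] <- o
    TC[, t, ] <- tc; XH[, t, ] <- xh
    if (!is.null(Y)) Y[, t, ] <- h
  }
  e$cache <- list(Fg = Fg, Ig = Ig, Gg = Gg, Og = Og, TC = TC, CP = CP,
                  XH = XH, T_ = T_, B = B)
  if (cfg$mode == "sequence") Y else h
}

backward_lstm <- function(e, cfg, dy) {
  D <- cfg$D; H <- cfg$H
  ca <- e$cache; T_ <- ca$T_; B <- ca$B
  dW <- e$G$W * 0; db <- e$G$b * 0
  dx <- array(0, c(D, T_, B))
  dh <- matrix(0, H, B); dc <- matrix(0, H, B)
  seq_mode <- cfg$mode == "sequence"
  for (t in rev(seq_len(T_))) {
    dht <- dh
    if (seq_mode) dht <- dht + slice_t(dy, t)
    else if (t == T_) dht <- dht + dy
    f <- slice_t(ca$Fg, t); i <- slice_t(ca$Ig, t)
    g <- slice_t(ca$Gg, t); o <- slice_t(ca$Og, t)
    tc <- slice_t(ca$TC, t); cp <- slice_t(ca$CP, t)
    do_ <- dht * tc
    dc <- dc + dht * o * (1 - tc^2)
    df <- dc * cp
    di <- dc * g
    dg <- dc * i
    dc <- dc * f
    dz <- rbind(df * f * (1 - f), di * i * (1 - i),
                dg * (1 - g^2), do_ * o * (1 - o))
    xh <- slice_t(ca$XH, t)
    dW <- dW + dz %*% t(xh)
    db <- db + rowSums(dz)
    dxh <- crossprod(e$P$W, dz)
    dx[, t, ] <- dxh[seq_len(D), , drop = FALSE]
    dh <- dxh[D + seq_len(H), , drop = FALSE]
  }
  e$G$W <- e$G$W + dW
  e$G$b <- e$G$b + db
  dx
}

forward_gru <- function(e, cfg, x) {
  D <- cfg$D; H <- cfg$H
  d <- dim(x); T_ <- d[2L]; B <- d[3L]
  if (d[1L] != D) stop("shape error: GRU expected ", D, " input channels")
  h <- matrix(0, H, B)
  R <- Z <- Nn <- GHn <- HP <- array(0, c(H, T_, B))
  X <- x
  Y <- if (cfg$mode == "sequence") array(0, c(H, T_, B)) else NULL
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1
  for (t in seq_len(T_)) {
    xt <- slice_t(x, t)
    gi <- e$P$Wx %*% xt + e$P$bx
    gh <- e$P$Wh %*% h + e$P$bh
    r <- sigmoid(gi[i1, , drop = FALSE] + gh[i1, , drop = FALSE])
    z <- sigmoid(gi[i2, , drop = FALSE] + gh[i2, , drop = FALSE])
    ghn <- gh[i3, , drop = FALSE]
    n <- tanh(gi[i3, , drop = FALSE] + r * ghn)
    HP[, t, ] <- h
    h <- (1 - z) * n + z * h
    R[, t, ] <- r; Z[, t, ] <- z; Nn[, t, ] <- n; GHn[, t, ] <- ghn
    if (!is.null(Y)) Y[, t, ] <- h
  }
  e$cache <- list(R = R, Z = Z, Nn = Nn, GHn = GHn, HP = HP, X = X,
                  T_ = T_, B = B)
  if (cfg$mode == "sequence") Y else h
}

backward_gru <- function(e, cfg, dy) {
  D <- cfg$D; H <- cfg$H
  ca <- e$cache; T_ <- ca$T_; B <- ca$B
  dWx <- e$G$Wx * 0; dWh <- e$G$Wh * 0
  dbx <- e$G$bx * 0; dbh <- e$G$bh * 0
  dx <- array(0, c(D, T_, B))
  dh <- matrix(0, H, B)
  seq_mode <- cfg$mode == "sequence"
  for (t in rev(seq_len(T_))) {
    dht <- dh
    if (seq_mode) dht <- dht + slice_t(dy, t)
    else if (t == T_) dht <- dht + dy
    r <- slice_t(ca$R, t); z <- slice_t(ca$Z, t)
    n <- slice_t(ca$Nn, t); ghn <- slice_t(ca$GHn, t)
    hp <- slice_t(ca$HP, t)
    dn <- dht * (1 - z)
    dz <- dht * (hp - n)
    dhp <- dht * z
    dan <- dn * (1 - n^2)
    dr <- dan * ghn
    dghn <- dan * r
    dar <- dr * r * (1 - r)
    daz <- dz * z * (1 - z)
    dgi <- rbind(dar, daz, dan)
    dgh <- rbind(dar, daz, dghn)
    xt <- slice_t(ca$X, t)
    dWx <- dWx + dgi %*% t(xt)
    dbx <- dbx + rowSums(dgi)
    dWh <- dWh + dgh %*% t(hp)
    dbh <- dbh + rowSums(dgh)
    dx[, t, ] <- crossprod(e$P$Wx, dgi)
    dh <- crossprod(e$P$Wh, dgh) + dhp
  }
  e$G$Wx <- e$G$Wx + dWx; e$G$Wh <- e$G$Wh + dWh
  e$G$bx <- e$G$bx + dbx; e$G$bh <- e$G$bh + dbh
  dx
}

forward_conv1d <- function(e, cfg, x) {
  d <- dim(x); T_ <- d[2L]; B <- d[3L]
  if (d[1L] != cfg$Cin) {
    stop("shape error: conv expected ", cfg$Cin, " input channels")
  }
  pad <- (cfg$k - 1L) * cfg$d
  xp <- array(0, c(cfg$Cin, T_ + pad, B))
  xp[, pad + seq_len(T_), ] <- x
  z <- matrix(0, cfg$Cout, T_ * B)
  for (j in seq_len(cfg$k)) {
    sl <- xp[, (j - 1L) * cfg$d + seq_len(T_), , drop = FALSE]
    dim(sl) <- c(cfg$Cin, T_ * B)
    z <- z + matrix(e$P$W[, , j], cfg$Cout, cfg$Cin) %*% sl
  }
  z <- z + e$P$b
  dim(z) <- c(cfg$Cout, T_, B)
  e$cache <- list(xp = xp, z = if (cfg$elu) z else NULL, T_ = T_, B = B)
  if (cfg$elu) elu_fun(z) else z
}

backward_conv1d <- function(e, cfg, dy) {
  ca <- e$cache; T_ <- ca$T_; B <- ca$B
  pad <- (cfg$k - 1L) * cfg$d
  if (cfg$elu) dy <- dy * elu_grad(ca$z)
  dym <- dy
  dim(dym) <- c(cfg$Cout, T_ * B)
  e$G$b <- e$G$b + rowSums(dym)
  dxp <- array(0, c(cfg$Cin, T_ + pad, B))
  for (j in seq_len(cfg$k)) {
    rng <- (j - 1L) * cfg$d + seq_len(T_)
    sl <- ca$xp[, rng, , drop = FALSE]
    dim(sl) <- c(cfg$Cin, T_ * B)
    e$G$W[, , j] <- e$G$W[, , j] + dym %*% t(sl)
    dsl <- crossprod(matrix(e$P$W[, , j], cfg$Cout, cfg$Cin), dym)
    dim(dsl) <- c(cfg$Cin, T_, B)
    dxp[, rng, ] <- dxp[, rng, , drop = FALSE] + dsl
  }
  dxp[, pad + seq_len(T_), , drop = FALSE]
}

forward_batchnorm_elu <- function(e, cfg, x, training) {
  d <- dim(x); N <- d[2L] * d[3L]
  xm <- as_mat3(x)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    e$running_mean <- cfg$momentum * e$running_mean + (1 - cfg$momentum) * mu
    e$running_var <- cfg$momentum * e$running_var + (1 - cfg$momentum) * v
  } else {
    mu <- e$running_mean
    v <- e$running_var
  }
  ivar <- 1 / sqrt(v + cfg$eps)
  xhat <- (xm - mu) * ivar
  z <- e$P$gamma * xhat + e$P$beta
  y <- elu_fun(z)
  e$cache <- list(xhat = xhat, ivar = ivar, z = z, N = N, dims = d,
                  training = training)
  dim(y) <- d
  y
}

backward_batchnorm_elu <- function(e, cfg, dy) {
  ca <- e$cache
  dym <- as_mat3(dy)
  dz <- dym * elu_grad(ca$z)
  e$G$gamma <- e$G$gamma + rowSums(dz * ca$xhat)
  e$G$beta <- e$G$beta + rowSums(dz)
  dxhat <- dz * e$P$gamma
  if (ca$training) {
    N <- ca$N
    dxm <- (ca$ivar / N) *
      (N * dxhat - rowSums(dxhat) - ca$xhat * rowSums(dxhat * ca$xhat))
  } else {
    dxm <- dxhat * ca$ivar
  }
  dim(dxm) <- ca$dims
  dxm
}

model_forward <- function(model, X, training = FALSE) {
  x <- X
  for (layer in model$layers) x <- layer_forward(layer, x, training)
  x
}

zero_grads <- function(model) {
  for (layer in model$layers) {
    layer$env$G <- lapply(layer$env$P, function(p) p * 0)
  }
  invisible(model)
}

adam_step <- function(model, lr, beta1, beta2, eps, t) {
  for (layer in model$layers) {
    e <- layer$env
    if (length(e$P) == 0L) next
    for (nm in names(e$P)) {
      g <- e$G[[nm]]
      st <- e$A[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      e$A[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      e$P[[nm]] <- e$P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}

snapshot_params <- function(model) {
  lapply(model$layers, function(l) l$env$P)
}

restore_params <- function(model, snap) {
  for (i in seq_along(model$layers)) model$layers[[i]]$env$P <- snap[[i]]
  invisible(model)
}

#' Number of trainable parameters in a forecast model
#'
#' @param model A [build_lstm()] / [build_cnn_lstm()] model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers,
             function(l) sum(lengths(l$env$P)) + 0,
             numeric(1L)))
}
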