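# Internal neural-network machinery for the inception-block regressor.
#
# A batch of windows is one (n_win * win_len) x n_channels matrix,
# window-major (see src/conv1d.cpp).  Batch normalisation is per channel
# over batch and time; all backward passes are derived by hand and are
# verified against numerical gradients in the test suite.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9     # running-statistics momentum; 30 adaptation epochs
                       # must be enough to re-estimate them on a new subject

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

he_init <- function(dim_vec, fan_in) {
  array(rnorm(prod(dim_vec), sd = sqrt(2 / fan_in)), dim = dim_vec)
}

# Column-wise broadcast without sweep() (whose aperm() dominates profiles
# on tall activation matrices): expand the per-channel vector to match the
# column-major layout and use plain vectorised arithmetic.
col_expand <- function(v, n) rep(v, rep.int(n, length(v)))

bn_forward <- function(x, gamma, beta, state, training) {
  if (training) {
    n <- nrow(x)
    fw <- bn_train_forward(x, gamma, beta, BN_EPS)
    corr <- if (n > 1L) n / (n - 1) else 1
    state$mean <- BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * drop(fw$mu)
    state$var <- BN_MOMENTUM * state$var +
      (1 - BN_MOMENTUM) * drop(fw$v) * corr
    list(y = fw$Y, cache = list(xhat = fw$xhat, inv = drop(fw$inv)),
         state = state)
  } else {
    list(y = bn_infer_forward(x, state$mean, state$var, gamma, beta, BN_EPS),
         cache = NULL, state = state)
  }
}

bn_backward <- function(dy, cache, gamma) {
  bw <- bn_train_backward(dy, cache$xhat, cache$inv, gamma)
  list(dx = bw$dX, dgamma = drop(bw$dgamma), dbeta = drop(bw$dbeta))
}

# Global average pooling over time: (n_win*T) x C -> n_win x C
gap_forward <- function(x, n_win, win_len) {
  rowsum(x, rep(seq_len(n_win), each = win_len), reorder = FALSE) / win_len
}

gap_backward <- function(dg, n_win, win_len) {
  dg[rep(seq_len(n_win), each = win_len), , drop = FALSE] / win_len
}

# Channel bookkeeping for one model: which blocks carry a residual
# shortcut and where the shortcut input comes from (0 = network input).
plan_blocks <- function(spec, n_channels) {
  c_out <- 4L * spec$n_filters
  plan <- vector("list", spec$depth)
  c_in <- n_channels
  res_from <- 0L
  res_channels <- n_channels
  for (i in seq_len(spec$depth)) {
    has_sc <- (i %% spec$residual_period == 0L)
    plan[[i]] <- list(c_in = c_in, has_shortcut = has_sc,
                      res_from = res_from, res_channels = res_channels)
    if (has_sc) { res_from <- i; res_channels <- c_out }
    c_in <- c_out
  }
  plan
}

init_params <- function(spec, n_channels) {
  ks <- spec$kernel_sizes
  nf <- spec$n_filters
  bs <- spec$bottleneck_size
  c_out <- 4L * nf
  plan <- plan_blocks(spec, n_channels)
  params <- list()
  for (i in seq_len(spec$depth)) {
    p <- plan[[i]]
    pre <- sprintf("b%d_", i)
    params[[paste0(pre, "bottleneck_W")]] <- he_init(c(1L, p$c_in, bs), p$c_in)
    for (j in 1:3)
      params[[paste0(pre, "conv", j, "_W")]] <-
        he_init(c(ks[j], bs, nf), ks[j] * bs)
    params[[paste0(pre, "pool_W")]] <- he_init(c(1L, p$c_in, nf), p$c_in)
    params[[paste0(pre, "bn_gamma")]] <- rep(1, c_out)
    params[[paste0(pre, "bn_beta")]] <- rep(0, c_out)
    if (p$has_shortcut) {
      params[[paste0(pre, "sc_W")]] <-
        he_init(c(1L, p$res_channels, c_out), p$res_channels)
      params[[paste0(pre, "sc_bn_gamma")]] <- rep(1, c_out)
      params[[paste0(pre, "sc_bn_beta")]] <- rep(0, c_out)
    }
  }
  params$head_W <- matrix(rnorm(c_out * spec$output_dim,
                                sd = sqrt(1 / c_out)),
                          c_out, spec$output_dim)
  params$head_b <- rep(0, spec$output_dim)
  params
}

init_bn_state <- function(spec) {
  c_out <- 4L * spec$n_filters
  st <- list()
  for (i in seq_len(spec$depth)) {
    st[[sprintf("b%d_bn", i)]] <- list(mean = rep(0, c_out),
                                       var = rep(1, c_out))
    if (i %% spec$residual_period == 0L)
      st[[sprintf("b%d_sc_bn", i)]] <- list(mean = rep(0, c_out),
                                            var = rep(1, c_out))
  }
  st
}

# Forward pass.  X: (n_win * win_len) x n_channels.  Returns predictions,
# per-layer cache (when `training`), and updated batch-norm state.
nn_forward <- function(model, X, n_win, training = FALSE) {
  spec <- model$spec
  pr <- model$params
  bst <- model$bn_state
  win_len <- nrow(X) / n_win
  plan <- model$plan
  acts <- vector("list", spec$depth + 1L)
  acts[[1L]] <- X
  blocks <- if (training) vector("list", spec$depth) else NULL
  for (i in seq_len(spec$depth)) {
    p <- plan[[i]]
    pre <- sprintf("b%d_", i)
    Z <- acts[[i]]
    bt <- conv1d_forward(Z, pr[[paste0(pre, "bottleneck_W")]], n_win, win_len)
    c1 <- conv1d_forward(bt, pr[[paste0(pre, "conv1_W")]], n_win, win_len)
    c2 <- conv1d_forward(bt, pr[[paste0(pre, "conv2_W")]], n_win, win_len)
    c3 <- conv1d_forward(bt, pr[[paste0(pre, "conv3_W")]], n_win, win_len)
    mp <- maxpool3_forward(Z, n_win, win_len)
    pb <- conv1d_forward(mp$Y, pr[[paste0(pre, "pool_W")]], n_win, win_len)
    cc <- cbind(c1, c2, c3, pb)
    bn <- bn_forward(cc, pr[[paste0(pre, "bn_gamma")]],
                     pr[[paste0(pre, "bn_beta")]],
                     bst[[paste0(pre, "bn")]], training)
    bst[[paste0(pre, "bn")]] <- bn$state
    m <- relu_forward(bn$y)
    if (p$has_shortcut) {
      res_in <- acts[[p$res_from + 1L]]
      sc_pre <- conv1d_forward(res_in, pr[[paste0(pre, "sc_W")]],
                               n_win, win_len)
      sc_bn <- bn_forward(sc_pre, pr[[paste0(pre, "sc_bn_gamma")]],
                          pr[[paste0(pre, "sc_bn_beta")]],
                          bst[[paste0(pre, "sc_bn")]], training)
      bst[[paste0(pre, "sc_bn")]] <- sc_bn$state
      out <- relu_forward(m + sc_bn$y)
    } else {
      sc_bn <- NULL
      out <- m
    }
    acts[[i + 1L]] <- out
    if (training)
      blocks[[i]] <- list(bt = bt, mp_y = mp$Y, mp_arg = mp$arg,
                          bn_cache = bn$cache, m = m,
                          sc_bn_cache = if (!is.null(sc_bn))
                            sc_bn$cache else NULL)
  }
  g <- gap_forward(acts[[spec$depth + 1L]], n_win, win_len)
  yhat <- g %*% pr$head_W + col_expand(pr$head_b, n_win)
  list(yhat = yhat,
       cache = if (training) list(acts = acts, blocks = blocks, g = g,
                                  n_win = n_win, win_len = win_len)
               else NULL,
       bn_state = bst)
}

# Backward pass; `dyhat` is the loss gradient at the output (n_win x
# output_dim).  Returns a gradient list aligned with model$params.
nn_backward <- function(model, cache, dyhat) {
  spec <- model$spec
  pr <- model$params
  plan <- model$plan
  n_win <- cache$n_win
  win_len <- cache$win_len
  nf <- spec$n_filters
  grads <- list()
  grads$head_W <- t(cache$g) %*% dyhat
  grads$head_b <- colSums(dyhat)
  d_acts <- vector("list", spec$depth + 1L)
  d_acts[[spec$depth + 1L]] <-
    gap_backward(dyhat %*% t(pr$head_W), n_win, win_len)
  add_grad <- function(lst, idx, val) {
    if (is.null(lst[[idx]])) lst[[idx]] <- val
    else lst[[idx]] <- lst[[idx]] + val
    lst
  }
  for (i in rev(seq_len(spec$depth))) {
    p <- plan[[i]]
    pre <- sprintf("b%d_", i)
    blk <- cache$blocks[[i]]
    da <- d_acts[[i + 1L]]
    if (p$has_shortcut) {
      dz <- relu_backward(da, cache$acts[[i + 1L]])
      dm <- dz
      sb <- bn_backward(dz, blk$sc_bn_cache, pr[[paste0(pre, "sc_bn_gamma")]])
      grads[[paste0(pre, "sc_bn_gamma")]] <- sb$dgamma
      grads[[paste0(pre, "sc_bn_beta")]] <- sb$dbeta
      want_res_dx <- p$res_from > 0L
      cb <- conv1d_backward(cache$acts[[p$res_from + 1L]],
                            pr[[paste0(pre, "sc_W")]], sb$dx,
                            n_win, win_len, want_res_dx)
      grads[[paste0(pre, "sc_W")]] <- cb$dW
      if (want_res_dx)
        d_acts <- add_grad(d_acts, p$res_from + 1L, cb$dX)
    } else {
      dm <- da
    }
    dbn_out <- relu_backward(dm, blk$m)
    bb <- bn_backward(dbn_out, blk$bn_cache, pr[[paste0(pre, "bn_gamma")]])
    grads[[paste0(pre, "bn_gamma")]] <- bb$dgamma
    grads[[paste0(pre, "bn_beta")]] <- bb$dbeta
    dcc <- bb$dx
    idx <- function(j) ((j - 1L) * nf + 1L):(j * nf)
    dbt <- NULL
    for (j in 1:3) {
      cb <- conv1d_backward(blk$bt, pr[[paste0(pre, "conv", j, "_W")]],
                            dcc[, idx(j), drop = FALSE], n_win, win_len, TRUE)
      grads[[paste0(pre, "conv", j, "_W")]] <- cb$dW
      dbt <- if (is.null(dbt)) cb$dX else dbt + cb$dX
    }
    want_dz <- i > 1L
    # pool branch (pooled values cached in the forward pass)
    cb <- conv1d_backward(blk$mp_y, pr[[paste0(pre, "pool_W")]],
                          dcc[, idx(4L), drop = FALSE], n_win, win_len,
                          want_dz)
    grads[[paste0(pre, "pool_W")]] <- cb$dW
    dZ <- NULL
    if (want_dz)
      dZ <- maxpool3_backward(cb$dX, blk$mp_arg, n_win, win_len)
    # bottleneck
    cb <- conv1d_backward(cache$acts[[i]],
                          pr[[paste0(pre, "bottleneck_W")]], dbt,
                          n_win, win_len, want_dz)
    grads[[paste0(pre, "bottleneck_W")]] <- cb$dW
    if (want_dz) {
      dZ <- dZ + cb$dX
      d_acts <- add_grad(d_acts, i, dZ)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, st, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = st)
}

# Convert window-set features (n, T, C) to the batch matrix layout.
windows_to_matrix <- function(features, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(dim(features)[1])
  sub <- features[idx, , , drop = FALSE]
  d <- dim(sub)
  matrix(aperm(sub, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
}
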