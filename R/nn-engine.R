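# Minimal convolutional-network engine.
#
# Activations are 3-D arrays [features x time x batch]. Each primitive layer
# is an environment holding its parameters in $par, gradients in $gr, and
# closures $fw(x, stoch) / $bw(dy); temporal convolutions are lowered to one
# BLAS matrix product via an im2col expansion. `stoch` switches stochastic
# layers (dropout) on; it is TRUE during training and during Monte Carlo
# dropout forward passes. Gradients are exact and verified against numerical
# differentiation in the test suite.

new_leaf <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$gr <- list()
  e
}

# im2col as one cached index-vector gather: element (f, dk, t, b) of the
# column matrix reads xp[f, t + dk - 1, b] from the padded activation
im2col_idx <- function(nf, kmax, tt, bb) {
  tp <- tt + kmax - 1L
  base <- rep(seq_len(nf), times = kmax * tt) +
    nf * (rep(rep(seq_len(kmax), each = nf), times = tt) +
          rep(seq_len(tt), each = nf * kmax) - 2L)
  as.integer(outer(base, (nf * tp) * (seq_len(bb) - 1L), `+`))
}

im2col_cached <- function(e, slot, nf, kmax, tt, bb) {
  key <- paste(slot, nf, tt, bb, sep = "_")
  idx <- e$idx_cache[[key]]
  if (is.null(idx)) {
    idx <- im2col_idx(nf, kmax, tt, bb)
    if (length(e$idx_cache) > 12L) e$idx_cache <- list()
    e$idx_cache[[key]] <- idx
  }
  idx
}

# weight initializers ---------------------------------------------------------

weight_init_fun <- function(scheme) {
  switch(scheme,
    glorot_uniform = function(n, fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      runif(n, -lim, lim)
    },
    random_uniform = function(n, fan_in, fan_out) runif(n, -0.05, 0.05),
    random_normal = function(n, fan_in, fan_out) rnorm(n, 0, 0.05),
    stop_config(sprintf("unknown init scheme '%s'", scheme))
  )
}

# primitive layers ------------------------------------------------------------

layer_dense_feat <- function(n_in, n_out, init) {
  e <- new_leaf("dense_feat")
  e$par$W <- matrix(init(n_in * n_out, n_in, n_out), n_out, n_in)
  e$par$b <- numeric(n_out)
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    x2 <- matrix(x, d[1], d[2] * d[3])
    e$x2 <- x2
    e$d <- d
    y2 <- e$par$W %*% x2 + e$par$b
    array(y2, c(n_out, d[2], d[3]))
  }
  e$bw <- function(dy) {
    d <- e$d
    dy2 <- matrix(dy, n_out, d[2] * d[3])
    e$gr$W <- tcrossprod(dy2, e$x2)
    e$gr$b <- rowSums(dy2)
    array(crossprod(e$par$W, dy2), d)
  }
  e
}

layer_conv_time <- function(n_in, n_out, k, init) {
  e <- new_leaf("conv_time")
  e$par$W <- matrix(init(n_out * n_in * k, n_in * k, n_out * k), n_out, n_in * k)
  e$par$b <- numeric(n_out)
  pl <- (k - 1L) %/% 2L
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    tt <- d[2]; bb <- d[3]
    xp <- array(0, c(n_in, tt + k - 1L, bb))
    xp[, (pl + 1L):(pl + tt), ] <- x
    xcol <- matrix(0, n_in * k, tt * bb)
    for (dk in seq_len(k)) {
      xcol[((dk - 1L) * n_in + 1L):(dk * n_in), ] <- xp[, dk:(dk + tt - 1L), ]
    }
    e$xcol <- xcol
    e$d <- d
    array(e$par$W %*% xcol + e$par$b, c(n_out, tt, bb))
  }
  e$bw <- function(dy) {
    d <- e$d
    tt <- d[2]; bb <- d[3]
    dy2 <- matrix(dy, n_out, tt * bb)
    e$gr$W <- tcrossprod(dy2, e$xcol)
    e$gr$b <- rowSums(dy2)
    dxcol <- crossprod(e$par$W, dy2)
    dxp <- array(0, c(n_in, tt + k - 1L, bb))
    for (dk in seq_len(k)) {
      dxp[, dk:(dk + tt - 1L), ] <- dxp[, dk:(dk + tt - 1L), ] +
        array(dxcol[((dk - 1L) * n_in + 1L):(dk * n_in), ], c(n_in, tt, bb))
    }
    dxp[, (pl + 1L):(pl + tt), , drop = FALSE]
  }
  e
}

# the three parallel inception convolutions fused into one conv over a
# shared im2col expansion: branch j's kernel of length kernels[j] occupies a
# centred tap range of the widest kernel, the remaining weights are
# structural zeros held at zero through a gradient mask (requires odd
# kernel lengths so the centre alignment is exact)
layer_multi_conv <- function(n_in, nf, kernels, init) {
  e <- new_leaf("multi_conv")
  kmax <- max(kernels)
  n_out <- nf * length(kernels)
  W <- matrix(0, n_out, n_in * kmax)
  mask <- matrix(FALSE, n_out, n_in * kmax)
  for (j in seq_along(kernels)) {
    k <- kernels[j]
    off <- (kmax - k) %/% 2L
    rows <- ((j - 1L) * nf + 1L):(j * nf)
    cols <- as.vector(vapply((off + 1L):(off + k), function(dk) {
      ((dk - 1L) * n_in + 1L):(dk * n_in)
    }, integer(n_in)))
    W[rows, cols] <- matrix(init(nf * n_in * k, n_in * k, nf * k), nf, n_in * k)
    mask[rows, cols] <- TRUE
  }
  e$par$W <- W
  e$par$b <- numeric(n_out)
  e$mask <- mask
  e$n_params_override <- sum(mask) + n_out
  e$idx_cache <- list()
  pl <- (kmax - 1L) %/% 2L
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    tt <- d[2]; bb <- d[3]
    xp <- array(0, c(n_in, tt + kmax - 1L, bb))
    xp[, (pl + 1L):(pl + tt), ] <- x
    xcol <- xp[im2col_cached(e, "f", n_in, kmax, tt, bb)]
    dim(xcol) <- c(n_in * kmax, tt * bb)
    e$xcol <- xcol
    e$d <- d
    array(e$par$W %*% xcol + e$par$b, c(n_out, tt, bb))
  }
  e$bw <- function(dy) {
    d <- e$d
    tt <- d[2]; bb <- d[3]
    dy2 <- matrix(dy, n_out, tt * bb)
    e$gr$W <- tcrossprod(dy2, e$xcol) * e$mask
    e$gr$b <- rowSums(dy2)
    dxcol <- crossprod(e$par$W, dy2)
    dxp <- array(0, c(n_in, tt + kmax - 1L, bb))
    for (dk in seq_len(kmax)) {
      dxp[, dk:(dk + tt - 1L), ] <- dxp[, dk:(dk + tt - 1L), ] +
        array(dxcol[((dk - 1L) * n_in + 1L):(dk * n_in), ], c(n_in, tt, bb))
    }
    dxp[, (pl + 1L):(pl + tt), , drop = FALSE]
  }
  e
}

layer_relu <- function() {
  e <- new_leaf("relu")
  e$fw <- function(x, stoch = FALSE) {
    e$m <- x > 0
    x * e$m
  }
  e$bw <- function(dy) dy * e$m
  e
}

layer_maxpool3 <- function() {
  e <- new_leaf("maxpool3")
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    tt <- d[2]
    xp <- array(-Inf, c(d[1], tt + 2L, d[3]))
    xp[, 2L:(tt + 1L), ] <- x
    s1 <- xp[, 1L:tt, , drop = FALSE]
    s2 <- xp[, 2L:(tt + 1L), , drop = FALSE]
    s3 <- xp[, 3L:(tt + 2L), , drop = FALSE]
    y <- pmax(s1, s2, s3)
    e$m1 <- s1 == y
    e$m2 <- (s2 == y) & !e$m1
    e$m3 <- !(e$m1 | e$m2)
    e$d <- d
    y
  }
  e$bw <- function(dy) {
    d <- e$d
    tt <- d[2]
    dxp <- array(0, c(d[1], tt + 2L, d[3]))
    dxp[, 1L:tt, ] <- dy * e$m1
    dxp[, 2L:(tt + 1L), ] <- dxp[, 2L:(tt + 1L), ] + dy * e$m2
    dxp[, 3L:(tt + 2L), ] <- dxp[, 3L:(tt + 2L), ] + dy * e$m3
    dxp[, 2L:(tt + 1L), , drop = FALSE]
  }
  e
}

layer_avgpool <- function(pool) {
  e <- new_leaf("avgpool")
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    to <- d[2] %/% pool
    y <- x[, seq(1L, to * pool, by = pool), , drop = FALSE]
    if (pool > 1L) {
      for (j in 2L:pool) {
        y <- y + x[, seq(j, to * pool, by = pool), , drop = FALSE]
      }
    }
    e$d <- d
    e$to <- to
    y / pool
  }
  e$bw <- function(dy) {
    d <- e$d
    dx <- array(0, d)
    for (j in seq_len(pool)) {
      dx[, seq(j, e$to * pool, by = pool), ] <- dy / pool
    }
    dx
  }
  e
}

layer_gap <- function() {
  e <- new_leaf("gap")
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    m <- matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
    e$d <- d
    array(rowMeans(m), c(d[1], 1L, d[3]))
  }
  e$bw <- function(dy) {
    d <- e$d
    dyv <- c(matrix(dy, d[1], d[3])) / d[2]
    aperm(array(rep(dyv, d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  e
}

layer_dropout <- function(rate) {
  e <- new_leaf("dropout")
  e$rate <- rate
  e$fw <- function(x, stoch = FALSE) {
    if (stoch && rate > 0) {
      m <- (runif(length(x)) >= rate) / (1 - rate)
      dim(m) <- dim(x)
      e$m <- m
      x * m
    } else {
      e$m <- NULL
      x
    }
  }
  e$bw <- function(dy) {
    if (is.null(e$m)) dy else dy * e$m
  }
  e
}

# temporal filter bank shared across input channels (EEGNet first stage):
# output feature (f-1)*C + c is channel c filtered with temporal kernel f
layer_temporal_bank <- function(n_ch, f1, k, init) {
  e <- new_leaf("temporal_bank")
  e$par$H <- matrix(init(f1 * k, k, k), f1, k)
  e$par$b <- numeric(f1)
  pl <- (k - 1L) %/% 2L
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    tt <- d[2]; bb <- d[3]
    xp <- array(0, c(n_ch, tt + k - 1L, bb))
    xp[, (pl + 1L):(pl + tt), ] <- x
    out <- array(0, c(n_ch * f1, tt, bb))
    for (f in seq_len(f1)) {
      acc <- array(e$par$b[f], c(n_ch, tt, bb))
      for (dk in seq_len(k)) {
        acc <- acc + e$par$H[f, dk] * xp[, dk:(dk + tt - 1L), , drop = FALSE]
      }
      out[((f - 1L) * n_ch + 1L):(f * n_ch), , ] <- acc
    }
    e$xp <- xp
    e$d <- d
    out
  }
  e$bw <- function(dy) {
    d <- e$d
    tt <- d[2]; bb <- d[3]
    gH <- matrix(0, f1, k)
    gb <- numeric(f1)
    dxp <- array(0, c(n_ch, tt + k - 1L, bb))
    for (f in seq_len(f1)) {
      dyf <- dy[((f - 1L) * n_ch + 1L):(f * n_ch), , , drop = FALSE]
      gb[f] <- sum(dyf)
      for (dk in seq_len(k)) {
        xs <- e$xp[, dk:(dk + tt - 1L), , drop = FALSE]
        gH[f, dk] <- sum(dyf * xs)
        dxp[, dk:(dk + tt - 1L), ] <- dxp[, dk:(dk + tt - 1L), ] +
          e$par$H[f, dk] * dyf
      }
    }
    e$gr$H <- gH
    e$gr$b <- gb
    dxp[, (pl + 1L):(pl + tt), , drop = FALSE]
  }
  e
}

# depthwise spatial map (EEGNet second stage): for each temporal filter f,
# a [D x C] weight matrix mixes the channels into D spatial filters
layer_grouped_spatial <- function(f1, n_ch, d_mult, init) {
  e <- new_leaf("grouped_spatial")
  e$par$W <- array(init(d_mult * n_ch * f1, n_ch, d_mult), c(d_mult, n_ch, f1))
  e$par$b <- numeric(f1 * d_mult)
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    x2 <- matrix(x, n_ch * f1, d[2] * d[3])
    y2 <- matrix(0, f1 * d_mult, d[2] * d[3])
    for (f in seq_len(f1)) {
      rows_in <- ((f - 1L) * n_ch + 1L):(f * n_ch)
      rows_out <- ((f - 1L) * d_mult + 1L):(f * d_mult)
      y2[rows_out, ] <- matrix(e$par$W[, , f], d_mult, n_ch) %*% x2[rows_in, , drop = FALSE]
    }
    e$x2 <- x2
    e$d <- d
    array(y2 + e$par$b, c(f1 * d_mult, d[2], d[3]))
  }
  e$bw <- function(dy) {
    d <- e$d
    dy2 <- matrix(dy, f1 * d_mult, d[2] * d[3])
    gW <- array(0, dim(e$par$W))
    dx2 <- matrix(0, n_ch * f1, d[2] * d[3])
    for (f in seq_len(f1)) {
      rows_in <- ((f - 1L) * n_ch + 1L):(f * n_ch)
      rows_out <- ((f - 1L) * d_mult + 1L):(f * d_mult)
      wf <- matrix(e$par$W[, , f], d_mult, n_ch)
      gW[, , f] <- tcrossprod(dy2[rows_out, , drop = FALSE], e$x2[rows_in, , drop = FALSE])
      dx2[rows_in, ] <- crossprod(wf, dy2[rows_out, , drop = FALSE])
    }
    e$gr$W <- gW
    e$gr$b <- rowSums(dy2)
    array(dx2, d)
  }
  e
}

# per-feature temporal kernel (the depthwise half of a separable conv)
layer_depthwise_time <- function(n_feat, k, init) {
  e <- new_leaf("depthwise_time")
  e$par$K <- matrix(init(n_feat * k, k, k), n_feat, k)
  e$par$b <- numeric(n_feat)
  pl <- (k - 1L) %/% 2L
  e$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    tt <- d[2]; bb <- d[3]
    xp <- array(0, c(n_feat, tt + k - 1L, bb))
    xp[, (pl + 1L):(pl + tt), ] <- x
    y <- array(e$par$b, c(n_feat, tt, bb))
    for (dk in seq_len(k)) {
      y <- y + e$par$K[, dk] * xp[, dk:(dk + tt - 1L), , drop = FALSE]
    }
    e$xp <- xp
    e$d <- d
    y
  }
  e$bw <- function(dy) {
    d <- e$d
    tt <- d[2]; bb <- d[3]
    gK <- matrix(0, n_feat, k)
    dxp <- array(0, c(n_feat, tt + k - 1L, bb))
    for (dk in seq_len(k)) {
      xs <- e$xp[, dk:(dk + tt - 1L), , drop = FALSE]
      gK[, dk] <- rowSums(matrix(dy * xs, n_feat))
      dxp[, dk:(dk + tt - 1L), ] <- dxp[, dk:(dk + tt - 1L), ] + e$par$K[, dk] * dy
    }
    e$gr$K <- gK
    e$gr$b <- rowSums(matrix(dy, n_feat))
    dxp[, (pl + 1L):(pl + tt), , drop = FALSE]
  }
  e
}

# inception module: bottleneck -> parallel temporal convs, plus a
# maxpool -> pointwise branch, concatenated and passed through ReLU
make_inception_module <- function(n_in, nf, nb, kernels, init) {
  m <- new.env(parent = emptyenv())
  m$bottle <- layer_dense_feat(n_in, nb, init)
  m$convs <- layer_multi_conv(nb, nf, kernels, init)
  m$pool <- layer_maxpool3()
  m$pconv <- layer_dense_feat(n_in, nf, init)
  nc <- length(kernels)
  m$n_out <- nf * (nc + 1L)
  m$leaves <- list(m$bottle, m$convs, m$pconv)
  m$fw <- function(x, stoch = FALSE) {
    d <- dim(x)
    b0 <- m$bottle$fw(x, stoch)
    out <- array(0, c(m$n_out, d[2], d[3]))
    out[1L:(nc * nf), , ] <- m$convs$fw(b0, stoch)
    p <- m$pool$fw(x, stoch)
    out[(nc * nf + 1L):m$n_out, , ] <- m$pconv$fw(p, stoch)
    m$mask <- out > 0
    out * m$mask
  }
  m$bw <- function(dy) {
    dy <- dy * m$mask
    dx <- m$bottle$bw(m$convs$bw(dy[1L:(nc * nf), , , drop = FALSE]))
    dy4 <- dy[(nc * nf + 1L):m$n_out, , , drop = FALSE]
    dx + m$pool$bw(m$pconv$bw(dy4))
  }
  m
}

# network containers ----------------------------------------------------------

build_inception_net <- function(n_channels, spe, depth, nf, nb, kernels,
                                ads, dropout_rate, init) {
  net <- new.env(parent = emptyenv())
  net$kind <- "inception"
  n_out <- nf * (length(kernels) + 1L)
  modules <- list()
  shortcuts <- list()
  in_feat <- n_channels
  res_feat <- n_channels
  for (i in seq_len(depth)) {
    modules[[i]] <- make_inception_module(in_feat, nf, nb, kernels, init)
    in_feat <- n_out
    if (i %% 3L == 0L) {
      shortcuts[[as.character(i)]] <- layer_dense_feat(res_feat, n_out, init)
      res_feat <- n_out
    }
  }
  net$modules <- modules
  net$shortcuts <- shortcuts
  net$gap <- layer_gap()
  head_in <- n_out
  if (ads) {
    net$ads_dense <- layer_dense_feat(n_out, 32L, init)
    net$ads_relu <- layer_relu()
    net$ads_drop <- layer_dropout(dropout_rate)
    head_in <- 32L
  }
  net$out <- layer_dense_feat(head_in, 1L, init)
  net$has_dropout <- ads
  net$depth <- depth
  net$leaves <- c(
    unlist(lapply(modules, function(m) m$leaves), use.names = FALSE),
    unname(shortcuts),
    if (ads) list(net$ads_dense),
    list(net$out)
  )
  net$fw <- function(x, stoch = FALSE) {
    h <- x
    res <- x
    net$merge_masks <- list()
    for (i in seq_len(net$depth)) {
      h <- net$modules[[i]]$fw(h, stoch)
      key <- as.character(i)
      if (!is.null(net$shortcuts[[key]])) {
        s <- net$shortcuts[[key]]$fw(res, stoch)
        h <- h + s
        net$merge_masks[[key]] <- h > 0
        h <- h * net$merge_masks[[key]]
        res <- h
      }
    }
    z <- net$gap$fw(h, stoch)
    if (net$has_dropout) {
      z <- net$ads_dense$fw(z, stoch)
      z <- net$ads_relu$fw(z, stoch)
      z <- net$ads_drop$fw(z, stoch)
    }
    z <- net$out$fw(z, stoch)
    as.numeric(z)
  }
  net$bw <- function(dlogit) {
    d <- net$out$bw(array(dlogit, c(1L, 1L, length(dlogit))))
    if (net$has_dropout) {
      d <- net$ads_drop$bw(d)
      d <- net$ads_relu$bw(d)
      d <- net$ads_dense$bw(d)
    }
    d <- net$gap$bw(d)
    pend <- list()
    for (i in rev(seq_len(net$depth))) {
      key <- as.character(i)
      if (!is.null(net$shortcuts[[key]])) {
        d <- d * net$merge_masks[[key]]
        pend[[as.character(i - 3L)]] <- net$shortcuts[[key]]$bw(d)
      }
      d <- net$modules[[i]]$bw(d)
      pkey <- as.character(i - 1L)
      if (!is.null(pend[[pkey]])) {
        d <- d + pend[[pkey]]
      }
    }
    invisible(d)
  }
  net
}

build_eegnet_net <- function(n_channels, spe, f1, d_mult, f2, temp_k, sep_k,
                             pool1, pool2, block_dropout, ads, dropout_rate,
                             init) {
  net <- new.env(parent = emptyenv())
  net$kind <- "eegnet"
  seq_layers <- list(
    layer_temporal_bank(n_channels, f1, temp_k, init),
    layer_grouped_spatial(f1, n_channels, d_mult, init),
    layer_relu(),
    layer_avgpool(pool1),
    layer_dropout(block_dropout),
    layer_depthwise_time(f1 * d_mult, sep_k, init),
    layer_dense_feat(f1 * d_mult, f2, init),
    layer_relu(),
    layer_avgpool(pool2),
    layer_dropout(block_dropout),
    layer_gap()
  )
  head_in <- f2
  if (ads) {
    seq_layers <- c(seq_layers, list(
      layer_dense_feat(f2, 32L, init),
      layer_relu(),
      layer_dropout(dropout_rate)
    ))
    head_in <- 32L
  }
  seq_layers <- c(seq_layers, list(layer_dense_feat(head_in, 1L, init)))
  net$layers <- seq_layers
  net$has_dropout <- TRUE  # block dropout layers are always present
  net$leaves <- Filter(function(l) length(l$par) > 0, seq_layers)
  net$fw <- function(x, stoch = FALSE) {
    h <- x
    for (l in net$layers) h <- l$fw(h, stoch)
    as.numeric(h)
  }
  net$bw <- function(dlogit) {
    d <- array(dlogit, c(1L, 1L, length(dlogit)))
    for (l in rev(net$layers)) d <- l$bw(d)
    invisible(d)
  }
  net
}

# parameter bookkeeping -------------------------------------------------------

net_params <- function(net) {
  lapply(net$leaves, function(l) l$par)
}

net_set_params <- function(net, params) {
  for (i in seq_along(net$leaves)) {
    net$leaves[[i]]$par <- params[[i]]
  }
  invisible(net)
}

net_n_params <- function(net) {
  sum(vapply(net$leaves, function(l) {
    l$n_params_override %||% sum(vapply(l$par, length, 0L))
  }, 0))
}

# Adam ------------------------------------------------------------------------

adam_new <- function(net, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state <- lapply(net$leaves, function(l) {
    lapply(l$par, function(p) {
      z <- p
      z[] <- 0
      list(m = z, v = z)
    })
  })
  list(state = state, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(net, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(net$leaves)) {
    leaf <- net$leaves[[i]]
    for (nm in names(leaf$par)) {
      g <- leaf$gr[[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      opt$state[[i]][[nm]] <- st
      leaf$par[[nm]] <- leaf$par[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    }
  }
  opt
}

# loss ------------------------------------------------------------------------

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
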