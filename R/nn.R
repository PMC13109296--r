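# Compact CPU neural-network engine.
#
# Activations are 4-D arrays with layout (H, W, B, C): spatial first, then
# the batch index, then channels. That layout lets im2col be built from
# k*k strided slices with no aperm, so each convolution is one gather plus
# one BLAS GEMM per offset block, batched over every image in the batch
# (for the teacher, "batch" is every frame of every series in the
# minibatch). Parameters live in an environment (`store`) so optimizer
# steps and running statistics mutate in place.

sigm <- function(x) 1 / (1 + exp(-x))

new_param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$state <- list()   # non-trainable (batch-norm running stats)
  e$n <- 0L
  e
}

add_param <- function(store, value, prefix = "p") {
  store$n <- store$n + 1L
  name <- sprintf("%s%04d", prefix, store$n)
  store$params[[name]] <- value
  name
}

add_state <- function(store, value, prefix = "s") {
  store$n <- store$n + 1L
  name <- sprintf("%s%04d", prefix, store$n)
  store$state[[name]] <- value
  name
}

pad_replicate <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  hi <- c(rep(1L, p), seq_len(d[1]), rep(d[1], p))
  wi <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  x[hi, wi, , , drop = FALSE]
}

# collapse replicate-padding gradient back onto edge pixels
unpad_replicate_grad <- function(dxp, p, H, W) {
  if (p == 0L) return(dxp)
  d <- dim(dxp)
  # rows
  dxr <- dxp[(p + 1L):(p + H), , , , drop = FALSE]
  for (q in seq_len(p)) {
    dxr[1L, , , ] <- dxr[1L, , , , drop = FALSE] + dxp[q, , , , drop = FALSE]
    dxr[H, , , ] <- dxr[H, , , , drop = FALSE] + dxp[p + H + q, , , , drop = FALSE]
  }
  dx <- dxr[, (p + 1L):(p + W), , , drop = FALSE]
  for (q in seq_len(p)) {
    dx[, 1L, , ] <- dx[, 1L, , , drop = FALSE] + dxr[, q, , , drop = FALSE]
    dx[, W, , ] <- dx[, W, , , drop = FALSE] + dxr[, p + W + q, , , drop = FALSE]
  }
  dx
}

## ---- layer constructors --------------------------------------------------

nn_conv <- function(store, c_in, c_out, k = 3L, stride = 1L) {
  fan_in <- k * k * c_in
  W <- matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
  list(kind = "conv", k = as.integer(k), stride = as.integer(stride),
       c_in = c_in, c_out = c_out,
       W = add_param(store, W), b = add_param(store, numeric(c_out)))
}

nn_bn <- function(store, c) {
  list(kind = "bn", c = c,
       gamma = add_param(store, rep(1, c)), beta = add_param(store, numeric(c)),
       rmean = add_state(store, numeric(c)), rvar = add_state(store, rep(1, c)),
       momentum = 0.1, eps = 1e-5)
}

nn_relu <- function() list(kind = "relu")
nn_avgpool2 <- function() list(kind = "avgpool2")
nn_maxpool3 <- function() list(kind = "maxpool3")
nn_block <- function(body, shortcut = NULL) {
  list(kind = "block", body = body, shortcut = shortcut)
}

## ---- forward / backward --------------------------------------------------

conv_forward <- function(layer, x, params, keep) {
  k <- layer$k; s <- layer$stride
  p <- (k - 1L) %/% 2L
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; Cin <- d[4]
  xp <- pad_replicate(x, p)
  dp <- dim(xp)
  Hout <- (dp[1] - k) %/% s + 1L
  Wout <- (dp[2] - k) %/% s + 1L
  n <- Hout * Wout * B
  X <- matrix(0, n, k * k * Cin)
  col <- 0L
  for (dw in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
    block <- xp[seq.int(dh + 1L, by = s, length.out = Hout),
                seq.int(dw + 1L, by = s, length.out = Wout), , , drop = FALSE]
    X[, col * Cin + seq_len(Cin)] <- block
    col <- col + 1L
  }
  Y <- X %*% params[[layer$W]]
  Y <- Y + rep(params[[layer$b]], each = n)
  y <- array(Y, c(Hout, Wout, B, layer$c_out))
  cache <- if (keep) list(X = X, H = H, W = W, B = B, Cin = Cin,
                          Hout = Hout, Wout = Wout, p = p, dp = dp) else NULL
  list(y = y, cache = cache)
}

conv_backward <- function(layer, dy, params, cache, grads) {
  k <- layer$k; s <- layer$stride
  n <- cache$Hout * cache$Wout * cache$B
  m <- matrix(dy, n, layer$c_out)
  grads$g[[layer$W]] <- grads$g[[layer$W]] + crossprod(cache$X, m)
  grads$g[[layer$b]] <- grads$g[[layer$b]] + colSums(m)
  Cin <- cache$Cin
  dXcol <- m %*% t(params[[layer$W]])
  dxp <- array(0, c(cache$dp[1], cache$dp[2], cache$B, Cin))
  col <- 0L
  for (dw in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
    hseq <- seq.int(dh + 1L, by = s, length.out = cache$Hout)
    wseq <- seq.int(dw + 1L, by = s, length.out = cache$Wout)
    slice <- array(dXcol[, col * Cin + seq_len(Cin)],
                   c(cache$Hout, cache$Wout, cache$B, Cin))
    dxp[hseq, wseq, , ] <- dxp[hseq, wseq, , , drop = FALSE] + slice
    col <- col + 1L
  }
  unpad_replicate_grad(dxp, cache$p, cache$H, cache$W)
}

bn_forward <- function(layer, x, store, training, keep) {
  d <- dim(x); nhw <- d[1] * d[2] * d[3]
  xm <- matrix(x, nhw, d[4])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    mom <- layer$momentum
    store$state[[layer$rmean]] <- (1 - mom) * store$state[[layer$rmean]] + mom * mu
    store$state[[layer$rvar]] <- (1 - mom) * store$state[[layer$rvar]] + mom * v
  } else {
    mu <- store$state[[layer$rmean]]
    v <- store$state[[layer$rvar]]
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - rep(mu, each = nhw)) * rep(inv, each = nhw)
  ym <- xhat * rep(store$params[[layer$gamma]], each = nhw) +
    rep(store$params[[layer$beta]], each = nhw)
  cache <- if (keep) list(xhat = xhat, inv = inv, nhw = nhw, d = d,
                          training = training) else NULL
  list(y = array(ym, d), cache = cache)
}

bn_backward <- function(layer, dy, store, cache, grads) {
  d <- cache$d; nhw <- cache$nhw
  dym <- matrix(dy, nhw, d[4])
  grads$g[[layer$gamma]] <- grads$g[[layer$gamma]] + colSums(dym * cache$xhat)
  grads$g[[layer$beta]] <- grads$g[[layer$beta]] + colSums(dym)
  gam <- store$params[[layer$gamma]]
  dxhat <- dym * rep(gam, each = nhw)
  if (cache$training) {
    # full batch-stat backward
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- (dxhat - rep(s1 / nhw, each = nhw) -
              cache$xhat * rep(s2 / nhw, each = nhw)) * rep(cache$inv, each = nhw)
  } else {
    dxm <- dxhat * rep(cache$inv, each = nhw)
  }
  array(dxm, d)
}

avgpool2_forward <- function(x, keep) {
  d <- dim(x)
  o1 <- seq.int(1L, d[1], by = 2L); e1 <- o1 + 1L
  o2 <- seq.int(1L, d[2], by = 2L); e2 <- o2 + 1L
  y <- (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
          x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
  list(y = y, cache = if (keep) list(d = d) else NULL)
}

avgpool2_backward <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  o1 <- seq.int(1L, d[1], by = 2L); e1 <- o1 + 1L
  o2 <- seq.int(1L, d[2], by = 2L); e2 <- o2 + 1L
  q <- dy / 4
  dx[o1, o2, , ] <- q; dx[e1, o2, , ] <- q
  dx[o1, e2, , ] <- q; dx[e1, e2, , ] <- q
  dx
}

maxpool3_forward <- function(x, keep) {
  # 3x3, stride 2, replicate pad 1
  xp <- pad_replicate(x, 1L)
  d <- dim(x); dp <- dim(xp)
  Hout <- (dp[1] - 3L) %/% 2L + 1L
  Wout <- (dp[2] - 3L) %/% 2L + 1L
  n <- Hout * Wout * d[3] * d[4]
  M <- matrix(0, n, 9L)
  col <- 0L
  for (dw in 0:2) for (dh in 0:2) {
    col <- col + 1L
    M[, col] <- xp[seq.int(dh + 1L, by = 2L, length.out = Hout),
                   seq.int(dw + 1L, by = 2L, length.out = Wout), , , drop = FALSE]
  }
  amax <- max.col(M, ties.method = "first")
  y <- array(M[cbind(seq_len(n), amax)], c(Hout, Wout, d[3], d[4]))
  list(y = y, cache = if (keep) list(amax = amax, d = d, dp = dp,
                                     Hout = Hout, Wout = Wout) else NULL)
}

maxpool3_backward <- function(dy, cache) {
  d <- cache$d; dp <- cache$dp
  n <- length(dy)
  dxp <- array(0, c(dp[1], dp[2], d[3], d[4]))
  dyv <- as.vector(dy)
  col <- 0L
  for (dw in 0:2) for (dh in 0:2) {
    col <- col + 1L
    sel <- cache$amax == col
    if (!any(sel)) next
    slice <- array(0, c(cache$Hout, cache$Wout, d[3], d[4]))
    slice[sel] <- dyv[sel]
    hseq <- seq.int(dh + 1L, by = 2L, length.out = cache$Hout)
    wseq <- seq.int(dw + 1L, by = 2L, length.out = cache$Wout)
    dxp[hseq, wseq, , ] <- dxp[hseq, wseq, , , drop = FALSE] + slice
  }
  unpad_replicate_grad(dxp, 1L, d[1], d[2])
}

layer_forward <- function(layer, x, store, training, keep) {
  switch(layer$kind,
    conv = conv_forward(layer, x, store$params, keep),
    bn = bn_forward(layer, x, store, training, keep),
    relu = list(y = pmax(x, 0), cache = NULL),
    avgpool2 = avgpool2_forward(x, keep),
    maxpool3 = maxpool3_forward(x, keep),
    block = {
      sc <- x; sc_caches <- NULL
      if (!is.null(layer$shortcut)) {
        sc_caches <- vector("list", length(layer$shortcut))
        for (i in seq_along(layer$shortcut)) {
          r <- layer_forward(layer$shortcut[[i]], sc, store, training, keep)
          sc <- r$y; sc_caches[[i]] <- r$cache
        }
      }
      h <- x; caches <- vector("list", length(layer$body))
      for (i in seq_along(layer$body)) {
        r <- layer_forward(layer$body[[i]], h, store, training, keep)
        h <- r$y
        if (keep) {
          caches[[i]] <- if (layer$body[[i]]$kind == "relu")
            list(mask = h > 0) else r$cache
        }
      }
      y <- pmax(h + sc, 0)
      list(y = y, cache = if (keep) list(body = caches, shortcut = sc_caches,
                                         mask = (h + sc) > 0) else NULL)
    },
    stopf("unknown layer kind '%s'", layer$kind))
}

layer_backward <- function(layer, dy, store, cache, grads) {
  switch(layer$kind,
    conv = conv_backward(layer, dy, store$params, cache, grads),
    bn = bn_backward(layer, dy, store, cache, grads),
    relu = dy,   # caller multiplies by mask via stored output; see seq_backward
    avgpool2 = avgpool2_backward(dy, cache),
    maxpool3 = maxpool3_backward(dy, cache),
    stopf("unknown layer kind '%s'", layer$kind))
}

# forward over a flat layer sequence; per-layer outputs are always recorded
# (taps and relu masks need them), backward caches only when keep = TRUE
seq_forward <- function(layers, x, store, training, keep) {
  outs <- vector("list", length(layers))
  caches <- if (keep) vector("list", length(layers)) else NULL
  h <- x
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], h, store, training, keep)
    h <- r$y
    outs[[i]] <- h
    if (keep) caches[[i]] <- r$cache
  }
  list(y = h, outs = outs, caches = caches)
}

seq_backward <- function(layers, dy, x0, outs, caches, store, grads,
                         tap_grads = NULL, tap_at = NULL) {
  g <- dy
  for (i in rev(seq_along(layers))) {
    if (!is.null(tap_grads)) {
      hit <- which(tap_at == i)
      if (length(hit) == 1L && !is.null(tap_grads[[hit]]))
        g <- g + tap_grads[[hit]]
    }
    ly <- layers[[i]]
    if (ly$kind == "relu") {
      g <- g * (outs[[i]] > 0)
    } else if (ly$kind == "block") {
      gpost <- g * caches[[i]]$mask
      gb <- gpost
      for (j in rev(seq_along(ly$body))) {
        lb <- ly$body[[j]]
        if (lb$kind == "relu") {
          gb <- gb * caches[[i]]$body[[j]]$mask
        } else {
          gb <- layer_backward(lb, gb, store, caches[[i]]$body[[j]], grads)
        }
      }
      gs <- gpost
      if (!is.null(ly$shortcut)) {
        for (j in rev(seq_along(ly$shortcut))) {
          gs <- layer_backward(ly$shortcut[[j]], gs, store,
                               caches[[i]]$shortcut[[j]], grads)
        }
      }
      g <- gb + gs
    } else {
      g <- layer_backward(ly, g, store, caches[[i]], grads)
    }
  }
  g
}

## ---- heads ---------------------------------------------------------------

global_avgpool <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])  # B x C
}

global_avgpool_backward <- function(dfeat, d) {
  array(rep(as.vector(dfeat) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

new_grads <- function(store) {
  e <- new.env(parent = emptyenv())
  e$g <- lapply(store$params, function(p) {
    z <- p; z[] <- 0; z
  })
  e
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(store) {
  list(m = lapply(store$params, function(p) { p[] <- 0; p }),
       v = lapply(store$params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(store, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(store$params)) {
    g <- grads$g[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    store$params[[nm]] <- store$params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  opt
}
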