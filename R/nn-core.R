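## Minimal convolutional-network engine.
##
## Tensors are numeric arrays with layout (H, W, N, C): rows, columns, batch,
## channels. Convolutions are im2col + BLAS matrix products; every layer has
## an explicit, hand-derived backward pass. This is deliberately small: only
## what the translation generators, patch discriminators and the
## encoder-decoder segmenter need.
##
## Internal throughout (no exports).

## ---- layers ----------------------------------------------------------------

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, init_sd = 0.02) {
  list(type = "conv", k = as.integer(k), s = as.integer(stride),
       p = as.integer(pad), cin = as.integer(cin), cout = as.integer(cout),
       par = list(W = matrix(stats::rnorm(cin * k * k * cout, 0, init_sd),
                             cin * k * k, cout),
                  b = numeric(cout)))
}

nn_instnorm <- function(c) {
  list(type = "instnorm", c = as.integer(c),
       par = list(gamma = rep(1, c), beta = numeric(c)))
}

nn_relu  <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_tanh  <- function() list(type = "tanh")
nn_sigmoid <- function() list(type = "sigmoid")
nn_up2   <- function() list(type = "up2")

nn_resblock <- function(c, init_sd = 0.02) {
  list(type = "res",
       sub = list(nn_conv(c, c, 3L, 1L, 1L, init_sd), nn_instnorm(c), nn_relu(),
                  nn_conv(c, c, 3L, 1L, 1L, init_sd), nn_instnorm(c)))
}

## ---- forward ---------------------------------------------------------------

## conv forward/backward are C++ (src/conv.cpp): im2col + BLAS GEMM with a
## col2im scatter-add backward; the Xcol matrix is cached for the weight
## gradient.

nn_conv_fwd <- function(ly, x) {
  r <- conv_fwd_cpp(x, ly$par$W, ly$par$b, ly$k, ly$s, ly$p)
  list(out = r$out, cache = list(Xcol = r$Xcol, din = dim(x)))
}

nn_conv_bwd <- function(ly, cache, dout) {
  r <- conv_bwd_cpp(cache$Xcol, dout, ly$par$W, cache$din, ly$k, ly$s, ly$p)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

nn_in_fwd <- function(ly, x, eps = 1e-5) {
  r <- in_fwd_cpp(x, ly$par$gamma, ly$par$beta, eps)
  list(out = r$out,
       cache = list(xhat = r$xhat, isd = r$isd, d = dim(x)))
}

nn_in_bwd <- function(ly, cache, dout) {
  r <- in_bwd_cpp(dout, cache$xhat, cache$isd, ly$par$gamma, cache$d)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

nn_fwd_layer <- function(ly, x) {
  switch(ly$type,
    conv = nn_conv_fwd(ly, x),
    instnorm = nn_in_fwd(ly, x),
    relu = {
      m <- x > 0
      x[!m] <- 0
      list(out = x, cache = m)
    },
    lrelu = {
      sc <- ifelse(x > 0, 1, ly$alpha)
      list(out = x * sc, cache = sc)
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = out)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = out)
    },
    up2 = {
      d <- dim(x)
      out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
               drop = FALSE]
      list(out = out, cache = d)
    },
    res = {
      r <- nn_fwd_seq(ly$sub, x)
      list(out = x + r$out, cache = r$caches)
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_bwd_layer <- function(ly, cache, dout) {
  switch(ly$type,
    conv = nn_conv_bwd(ly, cache, dout),
    instnorm = nn_in_bwd(ly, cache, dout),
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = list(dx = dout * cache, grads = NULL),
    tanh = list(dx = dout * (1 - cache * cache), grads = NULL),
    sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
    up2 = {
      d <- cache
      o1 <- seq.int(1L, 2L * d[1], by = 2L)
      o2 <- seq.int(1L, 2L * d[2], by = 2L)
      dx <- dout[o1, o2, , , drop = FALSE] +
        dout[o1 + 1L, o2, , , drop = FALSE] +
        dout[o1, o2 + 1L, , , drop = FALSE] +
        dout[o1 + 1L, o2 + 1L, , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    res = {
      r <- nn_bwd_seq(ly$sub, cache, dout)
      list(dx = dout + r$dx, grads = r$grads)
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_fwd_seq <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_fwd_layer(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_bwd_seq <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_bwd_layer(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULL entries as slots
  }
  list(dx = dout, grads = grads)
}

## ---- gradient bookkeeping --------------------------------------------------

## Per-layer gradient lists mirror the layer list; entries are NULL for
## parameter-free layers, named numeric lists for conv/instnorm, nested lists
## for residual blocks.

nn_grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(nn_grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

## ---- Adam ------------------------------------------------------------------

nn_adam_state <- function() list(t = 0L, m = NULL, v = NULL)

nn_adam_zeros_like <- function(layers) {
  lapply(layers, function(ly) {
    if (!is.null(ly$par)) lapply(ly$par, function(p) p * 0)
    else if (identical(ly$type, "res")) nn_adam_zeros_like(ly$sub)
    else NULL
  })
}

nn_adam_layers <- function(layers, grads, m, v, lr, t,
                           b1 = 0.5, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- layers[[i]]
    if (identical(ly$type, "res")) {
      r <- nn_adam_layers(ly$sub, g, m[[i]], v[[i]], lr, t, b1, b2, eps)
      layers[[i]]$sub <- r$layers
      m[[i]] <- r$m
      v[[i]] <- r$v
    } else {
      for (nm in names(g)) {
        m[[i]][[nm]] <- b1 * m[[i]][[nm]] + (1 - b1) * g[[nm]]
        v[[i]][[nm]] <- b2 * v[[i]][[nm]] + (1 - b2) * g[[nm]]^2
        step <- lr * (m[[i]][[nm]] / c1) / (sqrt(v[[i]][[nm]] / c2) + eps)
        layers[[i]]$par[[nm]] <- ly$par[[nm]] - step
      }
    }
  }
  list(layers = layers, m = m, v = v)
}

nn_adam_step <- function(net_layers, grads, state, lr,
                         b1 = 0.5, b2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- nn_adam_zeros_like(net_layers)
    state$v <- nn_adam_zeros_like(net_layers)
  }
  state$t <- state$t + 1L
  r <- nn_adam_layers(net_layers, grads, state$m, state$v, lr, state$t,
                      b1, b2, eps)
  state$m <- r$m
  state$v <- r$v
  list(layers = r$layers, state = state)
}
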