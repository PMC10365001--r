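## Network architectures built on the nn-core engine.
##
## Generator: the residual-block encoder-transform-decoder used for
## unpaired translation (7x7 stem, two stride-2 downsamplings, n residual
## blocks, two nearest-neighbour x2 upsamplings, 7x7 head). With
## `global_skip` the head predicts a residual added to the input, so a
## freshly initialized generator is already near the identity map — a
## stabilizing choice for short training schedules that also matches the
## semantics of the directional constraint (the network learns *changes*
## to the input intensities).
##
## Discriminator: a small patch-level CNN emitting one realness score per
## receptive-field patch.

nn_generator <- function(base = 8L, n_blocks = 2L, global_skip = TRUE) {
  b <- as.integer(base)
  layers <- c(
    list(nn_conv(1L, b, 7L, 1L, 3L), nn_instnorm(b), nn_relu(),
         nn_conv(b, 2L * b, 3L, 2L, 1L), nn_instnorm(2L * b), nn_relu(),
         nn_conv(2L * b, 4L * b, 3L, 2L, 1L), nn_instnorm(4L * b), nn_relu()),
    lapply(seq_len(n_blocks), function(i) nn_resblock(4L * b)),
    ## decoder: conv-then-nearest-upsample (resize-conv); keeps the wide
    ## convolutions at the lower resolution
    list(nn_conv(4L * b, 2L * b, 3L, 1L, 1L), nn_instnorm(2L * b), nn_relu(),
         nn_up2(),
         nn_conv(2L * b, b, 3L, 1L, 1L), nn_instnorm(b), nn_relu(), nn_up2(),
         nn_conv(b, 1L, 3L, 1L, 1L))
  )
  if (!global_skip) layers <- c(layers, list(nn_tanh()))
  list(layers = layers, global_skip = global_skip)
}

gen_fwd <- function(gen, x) {
  r <- nn_fwd_seq(gen$layers, x)
  if (gen$global_skip) r$out <- r$out + x
  r
}

## dout is the gradient at the generator output; returns dx at the input
## and per-layer parameter gradients.
gen_bwd <- function(gen, fwd, dout) {
  r <- nn_bwd_seq(gen$layers, fwd$caches, dout)
  if (gen$global_skip) r$dx <- r$dx + dout
  r
}

nn_discriminator <- function(in_ch = 1L, base = 8L, n_layers = 3L) {
  b <- as.integer(base)
  layers <- list(nn_conv(in_ch, b, 4L, 2L, 1L), nn_lrelu())
  ch <- b
  if (n_layers > 2L) for (i in seq_len(n_layers - 2L)) {
    layers <- c(layers, list(nn_conv(ch, 2L * ch, 4L, 2L, 1L),
                             nn_instnorm(2L * ch), nn_lrelu()))
    ch <- 2L * ch
  }
  layers <- c(layers, list(nn_conv(ch, 1L, 4L, 1L, 1L)))
  list(layers = layers)
}

disc_fwd <- function(disc, x) nn_fwd_seq(disc$layers, x)
disc_bwd <- function(disc, fwd, dout) nn_bwd_seq(disc$layers, fwd$caches, dout)

## ---- encoder-decoder segmenter (U-Net style) -------------------------------
##
## Three stride-2 encoder stages, decoder with skip concatenations, sigmoid
## head. Fixed topology, parameterized width; wiring (and therefore the
## concat/split bookkeeping in the backward pass) is explicit.

nn_unet <- function(base = 8L, in_ch = 1L) {
  b <- as.integer(base)
  list(
    b = b,
    e1 = nn_conv(in_ch, b, 4L, 2L, 1L),
    e2 = nn_conv(b, 2L * b, 4L, 2L, 1L), e2n = nn_instnorm(2L * b),
    e3 = nn_conv(2L * b, 4L * b, 4L, 2L, 1L), e3n = nn_instnorm(4L * b),
    d3 = nn_conv(4L * b, 2L * b, 3L, 1L, 1L), d3n = nn_instnorm(2L * b),
    d2 = nn_conv(4L * b, b, 3L, 1L, 1L), d2n = nn_instnorm(b),
    d1 = nn_conv(2L * b, b, 3L, 1L, 1L), d1n = nn_instnorm(b),
    out = nn_conv(b, 1L, 3L, 1L, 1L)
  )
}

unet_layer_names <- c("e1", "e2", "e2n", "e3", "e3n",
                      "d3", "d3n", "d2", "d2n", "d1", "d1n", "out")

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unet_fwd <- function(net, x) {
  cc <- list()
  r <- nn_conv_fwd(net$e1, x); cc$e1 <- r$cache
  a1 <- nn_fwd_layer(nn_lrelu(), r$out); cc$a1 <- a1$cache
  r <- nn_conv_fwd(net$e2, a1$out); cc$e2 <- r$cache
  n2 <- nn_in_fwd(net$e2n, r$out); cc$e2n <- n2$cache
  a2 <- nn_fwd_layer(nn_lrelu(), n2$out); cc$a2 <- a2$cache
  r <- nn_conv_fwd(net$e3, a2$out); cc$e3 <- r$cache
  n3 <- nn_in_fwd(net$e3n, r$out); cc$e3n <- n3$cache
  a3 <- nn_fwd_layer(nn_lrelu(), n3$out); cc$a3 <- a3$cache

  u3 <- nn_fwd_layer(nn_up2(), a3$out); cc$u3 <- u3$cache
  r <- nn_conv_fwd(net$d3, u3$out); cc$d3 <- r$cache
  m3 <- nn_in_fwd(net$d3n, r$out); cc$d3n <- m3$cache
  h3 <- nn_fwd_layer(nn_relu(), m3$out); cc$h3 <- h3$cache
  c3 <- cat_ch(h3$out, a2$out)                # 2b + 2b channels

  u2 <- nn_fwd_layer(nn_up2(), c3); cc$u2 <- u2$cache
  r <- nn_conv_fwd(net$d2, u2$out); cc$d2 <- r$cache
  m2 <- nn_in_fwd(net$d2n, r$out); cc$d2n <- m2$cache
  h2 <- nn_fwd_layer(nn_relu(), m2$out); cc$h2 <- h2$cache
  c2 <- cat_ch(h2$out, a1$out)                # b + b channels

  u1 <- nn_fwd_layer(nn_up2(), c2); cc$u1 <- u1$cache
  r <- nn_conv_fwd(net$d1, u1$out); cc$d1 <- r$cache
  m1 <- nn_in_fwd(net$d1n, r$out); cc$d1n <- m1$cache
  h1 <- nn_fwd_layer(nn_relu(), m1$out); cc$h1 <- h1$cache
  r <- nn_conv_fwd(net$out, h1$out); cc$out <- r$cache
  sg <- nn_fwd_layer(nn_sigmoid(), r$out); cc$sg <- sg$cache
  list(out = sg$out, caches = cc)
}

unet_bwd <- function(net, cc, dout) {
  g <- list()
  b <- net$b
  d <- nn_bwd_layer(nn_sigmoid(), cc$sg, dout)$dx
  r <- nn_conv_bwd(net$out, cc$out, d); g$out <- r$grads
  d <- nn_bwd_layer(nn_relu(), cc$h1, r$dx)$dx
  r <- nn_in_bwd(net$d1n, cc$d1n, d); g$d1n <- r$grads
  r2 <- nn_conv_bwd(net$d1, cc$d1, r$dx); g$d1 <- r2$grads
  d <- nn_bwd_layer(nn_up2(), cc$u1, r2$dx)$dx   # grad at c2
  dh2 <- d[, , , seq_len(b), drop = FALSE]
  da1 <- d[, , , b + seq_len(b), drop = FALSE]

  d <- nn_bwd_layer(nn_relu(), cc$h2, dh2)$dx
  r <- nn_in_bwd(net$d2n, cc$d2n, d); g$d2n <- r$grads
  r2 <- nn_conv_bwd(net$d2, cc$d2, r$dx); g$d2 <- r2$grads
  d <- nn_bwd_layer(nn_up2(), cc$u2, r2$dx)$dx   # grad at c3
  dh3 <- d[, , , seq_len(2L * b), drop = FALSE]
  da2 <- d[, , , 2L * b + seq_len(2L * b), drop = FALSE]

  d <- nn_bwd_layer(nn_relu(), cc$h3, dh3)$dx
  r <- nn_in_bwd(net$d3n, cc$d3n, d); g$d3n <- r$grads
  r2 <- nn_conv_bwd(net$d3, cc$d3, r$dx); g$d3 <- r2$grads
  da3 <- nn_bwd_layer(nn_up2(), cc$u3, r2$dx)$dx

  d <- nn_bwd_layer(nn_lrelu(), cc$a3, da3)$dx
  r <- nn_in_bwd(net$e3n, cc$e3n, d); g$e3n <- r$grads
  r2 <- nn_conv_bwd(net$e3, cc$e3, r$dx); g$e3 <- r2$grads
  da2 <- da2 + r2$dx

  d <- nn_bwd_layer(nn_lrelu(), cc$a2, da2)$dx
  r <- nn_in_bwd(net$e2n, cc$e2n, d); g$e2n <- r$grads
  r2 <- nn_conv_bwd(net$e2, cc$e2, r$dx); g$e2 <- r2$grads
  da1 <- da1 + r2$dx

  d <- nn_bwd_layer(nn_lrelu(), cc$a1, da1)$dx
  r <- nn_conv_bwd(net$e1, cc$e1, d); g$e1 <- r$grads
  list(dx = r$dx, grads = g)
}

## Adapters so the unet can share the Adam machinery (treated as a flat
## layer list in fixed order).
unet_as_layers <- function(net) lapply(unet_layer_names, function(nm) net[[nm]])
unet_from_layers <- function(net, layers) {
  for (i in seq_along(unet_layer_names)) net[[unet_layer_names[i]]] <- layers[[i]]
  net
}
unet_grads_as_list <- function(g) lapply(unet_layer_names, function(nm) g[[nm]])
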