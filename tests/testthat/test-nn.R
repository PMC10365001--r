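# Conv-net engine: analytic gradients vs central finite differences.
# eps = 1e-6 keeps the perturbation inside the locally smooth region of
# the piecewise-linear activations.

ns <- asNamespace("muscleTranSeg")

fd_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("generator input gradients match finite differences", {
  set.seed(101)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  gen <- ns$nn_generator(base = 4L, n_blocks = 1L, global_skip = TRUE)
  w <- array(rnorm(length(x)), dim(x))
  fw <- ns$gen_fwd(gen, x)
  bb <- ns$gen_bwd(gen, fw, w)
  num <- fd_grad(function(v) {
    dim(v) <- dim(x); sum(ns$gen_fwd(gen, v)$out * w)
  }, as.numeric(x))
  expect_lt(max(abs(bb$dx - num)) / max(abs(num)), 1e-5)
})

test_that("conv and instance-norm parameter gradients match finite differences", {
  set.seed(102)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  gen <- ns$nn_generator(base = 4L, n_blocks = 1L, global_skip = TRUE)
  w <- array(rnorm(length(x)), dim(x))
  fw <- ns$gen_fwd(gen, x)
  bb <- ns$gen_bwd(gen, fw, w)
  f0 <- function(g) sum(ns$gen_fwd(g, x)$out * w)

  idx <- sample(length(gen$layers[[4]]$par$W), 20)
  num <- sapply(idx, function(i) {
    gp <- gen; gp$layers[[4]]$par$W[i] <- gp$layers[[4]]$par$W[i] + 1e-6
    gm <- gen; gm$layers[[4]]$par$W[i] <- gm$layers[[4]]$par$W[i] - 1e-6
    (f0(gp) - f0(gm)) / 2e-6
  })
  expect_lt(max(abs(bb$grads[[4]]$W[idx] - num)) / max(abs(num)), 1e-4)

  gm0 <- gen$layers[[2]]$par$gamma
  num <- sapply(seq_along(gm0), function(i) {
    gp <- gen; gp$layers[[2]]$par$gamma[i] <- gm0[i] + 1e-6
    gm_ <- gen; gm_$layers[[2]]$par$gamma[i] <- gm0[i] - 1e-6
    (f0(gp) - f0(gm_)) / 2e-6
  })
  expect_lt(max(abs(bb$grads[[2]]$gamma - num)) / max(abs(num)), 1e-4)
})

test_that("encoder-decoder segmenter gradients flow through the skips", {
  set.seed(103)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  un <- ns$nn_unet(base = 4L)
  fw <- ns$unet_fwd(un, x)
  w <- array(rnorm(length(fw$out)), dim(fw$out))
  bb <- ns$unet_bwd(un, fw$caches, w)
  num <- fd_grad(function(v) {
    dim(v) <- dim(x); sum(ns$unet_fwd(un, v)$out * w)
  }, as.numeric(x))
  expect_lt(max(abs(bb$dx - num)) / max(abs(num)), 1e-5)

  f0 <- function(u) sum(ns$unet_fwd(u, x)$out * w)
  idx <- seq_along(un$e1$par$W)
  num <- sapply(idx, function(i) {
    up <- un; up$e1$par$W[i] <- up$e1$par$W[i] + 1e-6
    um <- un; um$e1$par$W[i] <- um$e1$par$W[i] - 1e-6
    (f0(up) - f0(um)) / 2e-6
  })
  expect_lt(max(abs(bb$grads$e1$W - num)) / max(abs(num)), 1e-4)
})

test_that("discriminator scores are patch-shaped, not scalar", {
  set.seed(104)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2, 1))
  dsc <- ns$nn_discriminator(1L, 4L, 3L)
  out <- ns$disc_fwd(dsc, x)$out
  expect_gt(prod(dim(out)[1:2]), 1)    # several receptive-field patches
  expect_equal(dim(out)[3], 2)         # batch preserved
})
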