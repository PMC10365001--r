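# Translation objective components

test_that("cycle loss matches hand-computed cases and vanishes for inverses", {
  idf <- function(x) x
  e <- rand_batch(); h <- rand_batch()
  expect_equal(cycleConsistencyLoss(idf, idf, e, h), 0)

  # 1x2 image e = (0.2, 0.6) with F(G(e)) = (0.3, 0.6); h term zero
  e1 <- array(c(0.2, 0.6), c(1, 2, 1))
  Fmap <- function(x) if (length(x) == 2) array(c(0.3, 0.6), dim(x)) else x
  expect_equal(cycleConsistencyLoss(Fmap, idf, e1, rand_batch(1, 3, 1)), 0.05)

  # invariant to permuting batch order
  F2 <- function(x) 0.9 * x + 0.02
  G2 <- function(x) x^1.1
  perm <- c(2, 1)
  expect_equal(cycleConsistencyLoss(F2, G2, e, h),
               cycleConsistencyLoss(F2, G2, e[, , perm], h[, , perm]))
})

test_that("loss components equal explicit-loop recomputation", {
  set.seed(31)
  F1 <- function(x) pmin(pmax(0.8 * x + 0.05 * sin(7 * x), 0), 1)
  G1 <- function(x) pmin(pmax(x^0.9, 0), 1)
  for (rep in 1:5) {
    e <- rand_batch(); h <- rand_batch()
    expect_equal(cycleConsistencyLoss(F1, G1, e, h),
                 loop_l1(F1(G1(e)), e) + loop_l1(G1(F1(h)), h),
                 tolerance = 1e-12)
    expect_equal(directionalReluLoss(F1, G1, e, h),
                 loop_relu_mean(F1(h), h) + loop_relu_mean(e, G1(e)),
                 tolerance = 1e-12)
    expect_equal(identityLoss(F1, G1, e, h),
                 loop_l1(F1(e), e) + loop_l1(G1(h), h),
                 tolerance = 1e-12)
  }
})

test_that("directional loss is one-sided, shift-invariant and monotone", {
  set.seed(17)
  e <- rand_batch(); h <- rand_batch()
  # never brightening / never darkening => exactly zero
  Fdark <- function(x) x - abs(0.3 * sin(5 * x))
  Gbright <- function(x) x + 0.1
  expect_identical(directionalReluLoss(Fdark, Gbright, e, h), 0)

  # clamping F(h) at h sends the h-term to exactly zero
  Fany <- function(x) x + 0.2 * sin(9 * x)
  Fclamp <- function(x) pmin(Fany(x), x)
  expect_identical(directionalReluLoss(Fclamp, Gbright, e, h), 0)

  # invariant under a common additive shift of F(h) and h
  c0 <- 0.37
  lhs <- mean(pmax(Fany(h) - h, 0))
  rhs <- mean(pmax((Fany(h) + c0) - (h + c0), 0))
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # monotone non-decreasing in any single pixel of F(h)
  fh <- Fany(h)
  base <- mean(pmax(fh - h, 0))
  fh2 <- fh; fh2[2, 3, 1] <- fh2[2, 3, 1] + 0.2
  expect_gte(mean(pmax(fh2 - h, 0)), base)
})

test_that("identity loss is positive iff a generator moves its input", {
  e <- rand_batch(); h <- rand_batch()
  idf <- function(x) x
  expect_equal(identityLoss(idf, idf, e, h), 0)
  e1 <- array(0.4, c(1, 1, 1))
  Fm <- function(x) if (length(x) == 1) array(0.1, dim(x)) else x
  expect_equal(identityLoss(Fm, idf, e1, rand_batch(1, 1, 1)), 0.3)
  Fp <- function(x) x + 1e-6
  expect_gt(identityLoss(Fp, idf, e, h), 0)
})

test_that("least-squares adversarial objectives behave as scored games", {
  e <- rand_batch(); h <- rand_batch()
  fe <- rand_batch(); fh <- rand_batch()
  # perfect discrimination => objective at its minimum, 0
  perfect <- function(real) function(x) {
    if (identical(x, real)) array(1, dim(x)) else array(0, dim(x))
  }
  r <- adversarialLosses(perfect(h), perfect(e), h, e, fh, fe)
  expect_equal(r$discriminator, 0)

  # constant 0.5 output => 0.25 per term, 1.0 over the four terms
  half <- function(x) array(0.5, dim(x))
  r <- adversarialLosses(half, half, h, e, fh, fe)
  expect_equal(r$discriminator, 4 * 0.25)
  expect_equal(r$generator, 2 * 0.25)

  # generator objective decreases as fake scores approach 1
  sc <- function(v) function(x) array(v, dim(x))
  g1 <- adversarialLosses(sc(0.2), sc(0.2), h, e, fh, fe)$generator
  g2 <- adversarialLosses(sc(0.8), sc(0.8), h, e, fh, fe)$generator
  expect_gt(g1, g2)
})

test_that("adversarial objectives match explicit recomputation", {
  set.seed(23)
  DH <- function(x) 0.3 + 0.4 * x[1:2, 1:2, , drop = FALSE]
  DE <- function(x) 0.9 - 0.5 * x[1:2, 1:2, , drop = FALSE]
  for (rep in 1:5) {
    e <- rand_batch(); h <- rand_batch()
    fe <- rand_batch(); fh <- rand_batch()
    r <- adversarialLosses(DH, DE, h, e, fh, fe)
    dRef <- mean((DH(h) - 1)^2) + mean(DH(fh)^2) +
      mean((DE(e) - 1)^2) + mean(DE(fe)^2)
    gRef <- mean((DH(fh) - 1)^2) + mean((DE(fe) - 1)^2)
    expect_equal(r$discriminator, dRef, tolerance = 1e-12)
    expect_equal(r$generator, gRef, tolerance = 1e-12)
  }
})

test_that("combined objective is the advertised weighted sum", {
  comps <- list(adversarial = 0.2, cycle = 0.4, directional = 0.1,
                identity = 0.3)
  expect_equal(totalGeneratorObjective(lossWeights(wr = 0.5, wi = 1), comps),
               0.2 + 0.4 + 0.05 + 0.3)
  expect_equal(totalGeneratorObjective(lossWeights(0, 0),
                                       list(adversarial = 0, cycle = 0,
                                            directional = 0, identity = 0)),
               0)
  # the standard cyclic objective: adversarial + cycle only
  expect_equal(totalGeneratorObjective(lossWeights(0, 0), comps),
               comps$adversarial + comps$cycle)
  expect_error(lossWeights(wr = -0.1), "non-negative")
})

test_that("configuration names map (wr, wi) in the conventional order", {
  expect_equal(configName(lossWeights(0, 0)), "G_{0,0}")
  expect_equal(configName(lossWeights(0.5, 1)), "G_{.5,1}")
  expect_equal(configName(lossWeights(2, 1)), "G_{2,1}")
})
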