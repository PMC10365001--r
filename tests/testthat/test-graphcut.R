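# Appearance model, graph-cut and shape-prior graph-cut

test_that("appearance likelihoods are proper floored distributions", {
  set.seed(7)
  img <- matrix(c(rnorm(200, 0.35, 0.03), rnorm(200, 0.85, 0.03)), 20)
  img <- pmin(pmax(img, 0), 1)
  msk <- matrix(c(rep(1L, 200), rep(0L, 200)), 20)
  m <- fitAppearanceModel(img, msk)
  expect_equal(sum(m@pMuscle), 1, tolerance = 1e-9)
  expect_equal(sum(m@pOther), 1, tolerance = 1e-9)
  expect_true(all(m@pMuscle > 0) && all(m@pOther > 0))
  lk <- appearanceLikelihood(m, 0.35)
  expect_gt(lk$muscle / lk$other, 1)
  lk <- appearanceLikelihood(m, 0.85)
  expect_lt(lk$muscle / lk$other, 1)
  expect_error(fitAppearanceModel(img, matrix(1L, 20, 20)), "per class")
})

test_that("zero smoothness weight reduces to pixelwise maximum likelihood", {
  model <- make_appearance()
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.4, seed = 77L)
  for (i in 1:10) {
    sl <- generatePhantomSlice(cfg, subjectGeometry(cfg, 77L + i), 200L + i)
    img <- sliceImage(sl)
    got <- graphCutSegment(img, model, graphCutParams(lambdaS = 0, sigma = 0))
    lk <- appearanceLikelihood(model, img)
    ml <- matrix(as.integer(lk$muscle > lk$other), nrow(img))
    ties <- lk$muscle == lk$other
    expect_true(all(got[!ties] == ml[!ties]))
  }
})

test_that("min-cut energies equal exhaustive enumeration on small grids", {
  model <- make_appearance()
  set.seed(91)
  lambdaGrid <- c(0.001, 0.002, 0.05, 0.1, 0.2, 0.5)
  for (inst in 1:10) {
    dims <- if (inst %% 2 == 0) c(3, 3) else c(3, 4)
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    for (ls in lambdaGrid) {
      tm <- gc_terms(img, model, ls, sigma = 0)
      got <- graphCutSegment(img, model, graphCutParams(ls, sigma = 0))
      eMin <- brute_force_min_energy(tm$D0, tm$D1, tm$edges, tm$wEdge)
      expect_equal(attr(got, "energy"), eMin, tolerance = 1e-9)
      expect_equal(segmentationEnergy(got, tm$D0, tm$D1, tm$edges, tm$wEdge),
                   eMin, tolerance = 1e-9)
    }
  }
})

test_that("stronger smoothing never lengthens the label boundary", {
  model <- make_appearance()
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.35,
                       seed = 31L)
  sl <- generatePhantomSlice(cfg, subjectGeometry(cfg, 31L), 311L)
  img <- sliceImage(sl)
  edges <- muscleTranSeg:::grid_edges(64, 64)
  nb <- sapply(c(0.001, 0.05, 0.2, 0.5, 2), function(ls) {
    m <- graphCutSegment(img, model, graphCutParams(ls, sigma = 1))
    sum(m[edges[, 1]] != m[edges[, 2]])
  })
  expect_true(all(diff(nb) <= 0))
})

test_that("shape prior averages similarity-aligned masks", {
  m1 <- matrix(0L, 32, 32); m1[10:20, 8:24] <- 1L
  # identical, pre-aligned masks reproduce the mask exactly
  pr <- buildShapePrior(list(m1, m1, m1))
  expect_equal(pr@probMap, matrix(as.numeric(m1), 32), tolerance = 1e-12)

  # two masks with identical moments (centroid, axes, area) but different
  # outlines: alignment is the identity, so the prior is exactly the mean
  # and equals 0.5 on the symmetric difference
  a <- matrix(0L, 40, 40); a[15:26, 15:26] <- 1L    # 12 x 12 square
  b <- matrix(0L, 40, 40); b[17:24, 12:29] <- 1L    # 8 x 18 rectangle
  pr2 <- buildShapePrior(list(a, b))
  symdiff <- xor(a == 1, b == 1)
  expect_true(all(abs(pr2@probMap[symdiff] - 0.5) < 1e-9))
  expect_true(all(pr2@probMap >= 0 & pr2@probMap <= 1))
})

test_that("spgc with zero prior weight is exactly the plain graph cut", {
  model <- make_appearance()
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.4, seed = 13L)
  prior <- buildShapePrior(lapply(1:3, function(i) {
    muscleMask(generatePhantomSlice(cfg, subjectGeometry(cfg, 13L + i),
                                    400L + i))
  }))
  for (i in 1:3) {
    sl <- generatePhantomSlice(cfg, subjectGeometry(cfg, 50L + i), 500L + i)
    gc <- graphCutSegment(sliceImage(sl), model, graphCutParams(0.1, 1))
    sp <- spgcSegment(sliceImage(sl), model, prior,
                      spgcParams(lambdaSp = 0, pN = 0.3,
                                 gc = graphCutParams(0.1, 1)))
    expect_identical(as.integer(sp), as.integer(gc))
  }
})

test_that("a categorical prior with full weight dictates the labeling", {
  model <- make_appearance()
  m1 <- matrix(0L, 32, 32); m1[8:24, 10:22] <- 1L
  prior <- buildShapePrior(list(m1, m1))
  img <- matrix(runif(32 * 32, 0.2, 0.9), 32)
  out <- spgcSegment(img, model, prior,
                     spgcParams(lambdaSp = 1, pN = 0.3,
                                gc = graphCutParams(lambdaS = 0, sigma = 0)),
                     init = m1)
  expect_identical(as.integer(out), as.integer(m1))
})

test_that("spgc energies equal exhaustive enumeration on small grids", {
  model <- make_appearance()
  m1 <- matrix(0L, 3, 4); m1[2, 2:3] <- 1L
  prior <- buildShapePrior(list(m1))
  set.seed(97)
  for (inst in 1:10) {
    dims <- if (inst %% 2 == 0) c(3, 3) else c(3, 4)
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    init <- matrix(0L, dims[1], dims[2]); init[2, 2] <- 1L
    for (lsp in c(0.1, 0.2, 0.5, 0.7, 1)) for (pn in c(0.2, 0.5)) {
      pp <- spgcParams(lambdaSp = lsp, pN = pn,
                       gc = graphCutParams(0.1, sigma = 0))
      got <- spgcSegment(img, model, prior, pp, init = init)
      # rebuild the blended unaries exactly as the segmenter does
      initM <- muscleTranSeg:::mask_moments(init)
      pmap <- muscleTranSeg:::warp_to_frame(prior@probMap,
                                            prior@referenceMoments, initM,
                                            dims)
      pmap <- pmin(pmax(pmap, 0), 1)
      lk <- appearanceLikelihood(model, img)
      D1 <- -log((1 - lsp) * lk$muscle + lsp * (pn + (1 - pn) * pmap))
      D0 <- -log((1 - lsp) * lk$other + lsp * (pn + (1 - pn) * (1 - pmap)))
      tm <- gc_terms(img, model, 0.1, sigma = 0)
      eMin <- brute_force_min_energy(as.numeric(D0), as.numeric(D1),
                                     tm$edges, tm$wEdge)
      expect_equal(attr(got, "energy"), eMin, tolerance = 1e-9)
    }
  }
})

test_that("the shape prior recovers infiltrated muscle the appearance loses", {
  # appearance trained on non-infiltrated slices: bright pixels look like
  # fat, so the plain cut drops infiltrated muscle; a prior built from the
  # true masks pulls it back
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0, seed = 61L)
  trainSl <- lapply(1:3, function(i)
    generatePhantomSlice(cfg, subjectGeometry(cfg, 61L + i), 600L + i))
  model <- fitAppearanceModel(lapply(trainSl, sliceImage),
                              lapply(trainSl, muscleMask))
  cfgH <- cfg; cfgH@infiltrationFraction <- 0.5
  geomT <- subjectGeometry(cfg, 65L)
  testSl <- generatePhantomSlice(cfgH, geomT, 700L)
  prior <- buildShapePrior(c(lapply(trainSl, muscleMask),
                             list(muscleMask(
                               generatePhantomSlice(cfg, geomT, 701L)))))
  img <- sliceImage(testSl)
  init <- gmmSegment(img)
  gcm <- graphCutSegment(img, model, graphCutParams(0.1, 1), init)
  spm <- spgcSegment(img, model, prior,
                     spgcParams(lambdaSp = 0.5, pN = 0.3,
                                gc = graphCutParams(0.1, 1)), init)
  infiltrated <- testSl@infiltrationMask == 1
  expect_gt(sum(spm[infiltrated]), sum(gcm[infiltrated]))
  expect_gt(dice(spm, muscleMask(testSl)), dice(gcm, muscleMask(testSl)))
})
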