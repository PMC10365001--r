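# Translation model mechanics (training behaviour at the smallest scale;
# the full tiny-preset study lives in the acceptance suite)

small_domains <- function(seed = 19L) {
  generateDomainDatasets(3, 3, 2, phantomConfig(imageSize = 64, seed = seed))
}

test_that("translation preserves shape and the [0,1] range", {
  dd <- small_domains()
  cfg <- trainConfig("tiny", seed = 2L)
  m <- untrainedTranslationModel(cfg)
  img <- sliceImage(dd$hard[[1]])
  out <- translateToEasy(m, img)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
  out2 <- translateToHard(m, sliceImage(dd$easy[[1]]))
  expect_true(all(out2 >= 0 & out2 <= 1))
})

test_that("training is reproducible and logs every loss component", {
  dd <- small_domains()
  cfg <- trainConfig("tiny", epochs = 2L, seed = 5L)
  m1 <- trainTranslation(dd$easy, dd$hard, lossWeights(0.5, 1), cfg)
  m2 <- trainTranslation(dd$easy, dd$hard, lossWeights(0.5, 1), cfg)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_equal(names(lossHistory(m1)),
               c("epoch", "L_d", "L_adv", "L_c", "L_r", "L_i", "total"))
  expect_equal(nrow(lossHistory(m1)), 2)
  expect_true(all(is.finite(as.matrix(lossHistory(m1)))))
  # identical generators, bitwise
  img <- sliceImage(dd$hard[[1]])
  expect_identical(translateToEasy(m1, img), translateToEasy(m2, img))
})

test_that("a different seed changes the trajectory", {
  dd <- small_domains()
  m1 <- trainTranslation(dd$easy, dd$hard, lossWeights(0, 0),
                         trainConfig("tiny", epochs = 1L, seed = 5L))
  m2 <- trainTranslation(dd$easy, dd$hard, lossWeights(0, 0),
                         trainConfig("tiny", epochs = 1L, seed = 6L))
  expect_false(identical(lossHistory(m1)$total, lossHistory(m2)$total))
})

test_that("empty domains and invalid weights are rejected", {
  dd <- small_domains()
  empty <- new("DomainDataset", slices = list(), domainLabel = "easy")
  expect_error(trainTranslation(empty, dd$hard), "non-empty")
  expect_error(lossWeights(wr = -1), "non-negative")
})

test_that("checkpoints round-trip the full model state", {
  dd <- small_domains()
  m <- trainTranslation(dd$easy, dd$hard, lossWeights(0.5, 1),
                        trainConfig("tiny", epochs = 1L, seed = 9L))
  p <- tempfile(fileext = ".rds")
  saveTranslationModel(m, p)
  m2 <- loadTranslationModel(p)
  img <- sliceImage(dd$hard[[1]])
  expect_identical(translateToEasy(m2, img), translateToEasy(m, img))
  expect_identical(lossHistory(m2), lossHistory(m))
  expect_equal(configName(m2@weights), "G_{.5,1}")
})
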