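# Synthetic thigh phantom generator

test_that("infiltration placement hits the requested fraction", {
  sl0 <- tiny_phantom(frac = 0, noise = 0)
  expect_equal(sum(sl0@infiltrationMask), 0)
  expect_equal(realizedInfiltrationFraction(sl0), 0)

  sl <- tiny_phantom(frac = 0.4, noise = 0)
  got <- sum(sl@infiltrationMask == 1) / sum(sl@muscleMask == 1)
  expect_gte(got, 0.35)
  expect_lte(got, 0.45)
  expect_equal(realizedInfiltrationFraction(sl), got)
})

test_that("slice generation is bit-reproducible under a fixed seed", {
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.3, seed = 4L)
  g <- subjectGeometry(cfg, 9L)
  a <- generatePhantomSlice(cfg, g, 21L)
  b <- generatePhantomSlice(cfg, g, 21L)
  expect_identical(sliceImage(a), sliceImage(b))
  expect_identical(a@infiltrationMask, b@infiltrationMask)
})

test_that("tissue masks partition the image and respect containment", {
  for (seed in c(2L, 5L, 8L)) {
    sl <- tiny_phantom(frac = 0.35, noise = 0.02, seed = seed,
                       sliceSeed = seed + 100L)
    expect_true(validObject(sl))
    bg <- 1L - pmin(sl@fatMask + sl@boneMask + sl@muscleMask, 1L)
    total <- bg + sl@fatMask + sl@boneMask +
      (sl@muscleMask - sl@infiltrationMask) + sl@infiltrationMask
    expect_true(all(total == 1L))             # disjoint cover
    expect_true(all(sl@infiltrationMask <= sl@muscleMask))
  }
})

test_that("noiseless slices take exactly the configured tissue levels", {
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.3,
                       noiseSd = 0, seed = 3L)
  sl <- generatePhantomSlice(cfg, subjectGeometry(cfg, 3L), 14L)
  img <- sliceImage(sl)
  lv <- cfg@tissueLevels
  expect_true(all(img[sl@infiltrationMask == 1] == lv[["infiltration"]]))
  expect_true(all(img[sl@fatMask == 1] == lv[["subcutaneous_fat"]]))
  expect_true(all(img[sl@boneMask == 1] == lv[["bone"]]))
  expect_true(all(img[sl@muscleMask == 1 & sl@infiltrationMask == 0] ==
                    lv[["muscle"]]))
  # the core difficulty: infiltration and fat share one gray level
  expect_identical(lv[["infiltration"]], lv[["subcutaneous_fat"]])
})

test_that("tissue-level ordering and fraction bounds are enforced", {
  expect_error(phantomConfig(infiltrationFraction = 1.2), "0, 1")
  expect_error(phantomConfig(tissueLevels = c(background = 0.5, bone = 0.15,
                                              muscle = 0.35,
                                              subcutaneous_fat = 0.85,
                                              infiltration = 0.85)),
               "ordered")
  expect_error(phantomConfig(tissueLevels = c(background = 0.05, bone = 0.15,
                                              muscle = 0.35,
                                              subcutaneous_fat = 0.85,
                                              infiltration = 0.7)),
               "equal")
})

test_that("domain datasets share geometry but differ in intensity content", {
  dd <- generateDomainDatasets(2, 2, 3, phantomConfig(seed = 6L))
  expect_s4_class(dd$easy, "DomainDataset")
  expect_equal(length(dd$easy), 6)
  expect_equal(length(dd$hard), 6)
  expect_equal(domainLabel(dd$easy), "easy")
  expect_equal(domainLabel(dd$hard), "hard")

  fr <- vapply(datasetSlices(dd$easy), realizedInfiltrationFraction,
               numeric(1))
  expect_lte(mean(fr), 0.02)
  frH <- vapply(datasetSlices(dd$hard), realizedInfiltrationFraction,
                numeric(1))
  expect_gte(mean(frH), 0.15)

  areaE <- mean(vapply(datasetSlices(dd$easy),
                       function(s) sum(muscleMask(s)), numeric(1)))
  areaH <- mean(vapply(datasetSlices(dd$hard),
                       function(s) sum(muscleMask(s)), numeric(1)))
  expect_lt(abs(areaE - areaH) / areaE, 0.10)
})

test_that("dataset generation is a pure function of counts and config", {
  a <- generateDomainDatasets(2, 2, 2, phantomConfig(seed = 12L))
  b <- generateDomainDatasets(2, 2, 2, phantomConfig(seed = 12L))
  expect_identical(lapply(datasetSlices(a$hard), sliceImage),
                   lapply(datasetSlices(b$hard), sliceImage))
})

test_that("datasets round-trip through disk in both formats", {
  dd <- generateDomainDatasets(1, 2, 2, phantomConfig(seed = 9L))
  for (fmt in c("nifti", "png")) {
    dir <- file.path(tempfile(), fmt)
    manifest <- writeDataset(dd$hard, dir, fmt)
    expect_equal(nrow(manifest), length(dd$hard))
    back <- readDataset(dir)
    expect_equal(length(back), length(dd$hard))
    tol <- if (fmt == "png") 1 / 255 else 1e-7
    for (i in seq_len(length(back))) {
      expect_lt(max(abs(sliceImage(back[[i]]) - sliceImage(dd$hard[[i]]))),
                tol + 1e-12)
      expect_identical(muscleMask(back[[i]]), muscleMask(dd$hard[[i]]))
    }
    expect_identical(subjectId(back[[1]]), subjectId(dd$hard[[1]]))
  }
})
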