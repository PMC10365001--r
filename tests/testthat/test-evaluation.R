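# Dice, grid search and experiment bookkeeping

test_that("dice matches hand counts and handles empty masks", {
  m <- matrix(0L, 4, 4)
  a <- m; a[1:2, 1:2] <- 1L            # |a| = 4
  b <- m; b[2:3, 1:2] <- 1L            # |b| = 4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  d <- m; d[4, 4] <- 1L
  expect_equal(dice(a, d), 0)          # disjoint
  expect_equal(dice(m, m), 1)          # both empty by convention
  expect_error(dice(a, matrix(0L, 3, 3)), "shape")
})

test_that("dice is symmetric and monotone in true/false positives", {
  set.seed(71)
  for (rep in 1:20) {
    a <- matrix(rbinom(36, 1, 0.4), 6)
    b <- matrix(rbinom(36, 1, 0.4), 6)
    expect_equal(dice(a, b), dice(b, a))
  }
  a <- matrix(rbinom(100, 1, 0.3), 10)
  b <- matrix(rbinom(100, 1, 0.3), 10)
  # adding a true-positive pixel never decreases the score
  missed <- which(b == 1 & a == 0)
  if (length(missed)) {
    a2 <- a; a2[missed[1]] <- 1L
    expect_gte(dice(a2, b), dice(a, b))
  }
  # adding a false positive (intersection fixed) never increases it
  fp <- which(b == 0 & a == 0)
  a3 <- a; a3[fp[1]] <- 1L
  expect_lte(dice(a3, b), dice(a, b))
})

make_labeled_hard <- function(nSub = 3, slices = 2, seed = 81L) {
  generateDomainDatasets(1, nSub, slices,
                         phantomConfig(imageSize = 64, seed = seed))$hard
}

test_that("leave-one-out grid search scores every subject exactly once", {
  ds <- make_labeled_hard()
  grid <- gridSpec(lambdaS = c(0.05, 0.2), sigma = 1, lambdaSp = 0.5,
                   pN = 0.3)
  r <- gridSearch("gc", ds, grid, annotateEvery = 1L)
  expect_equal(sort(names(r$perSubject)),
               sort(unique(sapply(datasetSlices(ds), subjectId))))
  expect_true(all(r$perSubject >= 0 & r$perSubject <= 1))
  expect_equal(length(r$selections), 3)
})

test_that("a single-candidate grid is direct evaluation of that candidate", {
  ds <- make_labeled_hard()
  grid1 <- gridSpec(lambdaS = 0.1, sigma = 1, lambdaSp = 0.5, pN = 0.3)
  r <- gridSearch("gc", ds, grid1, annotateEvery = 1L)
  for (sel in r$selections) {
    expect_equal(sel$lambdaS, 0.1)
    expect_equal(sel$sigma, 1)
  }
})

test_that("selection ignores the held-out subject entirely", {
  ds <- make_labeled_hard()
  grid <- gridSpec(lambdaS = c(0.05, 0.2), sigma = 1, lambdaSp = 0.5,
                   pN = 0.3)
  r1 <- gridSearch("gc", ds, grid, annotateEvery = 1L)
  # corrupt one subject's images and ground truth: every OTHER fold used it,
  # but its own fold's model fitting and selection must not have
  target <- names(r1$perSubject)[1]
  ds2 <- ds
  for (i in seq_along(datasetSlices(ds2))) {
    if (subjectId(ds2[[i]]) == target) {
      sl <- ds2@slices[[i]]
      sl@image <- matrix(runif(length(sl@image)), nrow(sl@image))
      sl@muscleMask <- matrix(rbinom(length(sl@image), 1, 0.5),
                              nrow(sl@image))
      ds2@slices[[i]] <- sl
    }
  }
  r2 <- gridSearch("gc", ds2, grid, annotateEvery = 1L)
  expect_equal(r2$selections[[target]]$lambdaS,
               r1$selections[[target]]$lambdaS)
  expect_equal(r2$selections[[target]]$innerMeanDsc,
               r1$selections[[target]]$innerMeanDsc)
})

test_that("experiment summaries are recomputable from the stored scores", {
  ds <- make_labeled_hard(nSub = 4)
  res <- runExperiment(ds, methods = "gmm", seed = 5L)
  sc <- experimentScores(res)
  expect_equal(nrow(sc), 4)            # one row per subject, OI only
  s <- summarizeExperiment(res)
  expect_equal(nrow(s), 1)
  expect_equal(s$median, median(sc$dsc))
  expect_equal(s$min, min(sc$dsc))
  expect_equal(s$max, max(sc$dsc))
  # declared quartile convention: linear interpolation on the sorted list
  v <- sort(sc$dsc)
  expect_equal(s$q1, as.numeric(stats::quantile(v, 0.25, type = 7)))

  dir <- tempfile()
  paths <- writeExperimentCsv(res, dir)
  back <- readExperimentScores(paths[["results"]])
  expect_equal(back$dsc, sc$dsc)
  expect_equal(back$subject_id, sc$subject_id)
})

test_that("every k-th-slice annotation filter drives scoring", {
  ds <- make_labeled_hard(nSub = 2, slices = 4)
  idx1 <- muscleTranSeg:::annotated_indices(ds, 1L)
  idx4 <- muscleTranSeg:::annotated_indices(ds, 4L)
  expect_equal(length(idx1), 8)
  expect_equal(length(idx4), 2)        # slice 1 of each subject
})

test_that("the experiment harness wires all segmenters per configuration", {
  dd <- generateDomainDatasets(1, 4, 1,
                               phantomConfig(imageSize = 64, seed = 83L))
  grid1 <- gridSpec(lambdaS = 0.1, sigma = 1, lambdaSp = 0.5, pN = 0.3)
  res <- runExperiment(dd$hard, methods = c("gmm", "gc", "cnn"),
                       grid = grid1,
                       cnnCfg = cnnConfig("tiny", epochs = 2L),
                       seed = 11L)
  sc <- experimentScores(res)
  expect_setequal(unique(sc$method), c("gmm", "gc", "cnn"))
  expect_equal(nrow(sc), 3 * 4)              # 3 methods x 4 subjects, OI only
  expect_true(all(sc$dsc >= 0 & sc$dsc <= 1))
  s <- summarizeExperiment(res)
  expect_equal(nrow(s), 3)
  expect_true(all(c("gc.OI") %in% names(res@selections)))
})
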