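## Dice evaluation, cross-validated grid search, and the experiment
## harness comparing direct segmentation of original images (OI) against
## segmentation of translated images under different loss-weight
## configurations.

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for binary masks; defined as 1 when both
#' masks are empty.
#'
#' @param a,b binary matrices of identical shape.
#' @return numeric in \[0, 1\].
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice(m, m)          # 1
#' dice(m, 1 - m)      # 0
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical shape")
  sa <- sum(a == 1)
  sb <- sum(b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}

## slices carrying ground truth that enter evaluation: every k-th slice
## of each subject (annotation economy on real data; k = 1 scores all)
annotated_indices <- function(dataset, annotateEvery) {
  which(vapply(dataset@slices, function(s) {
    length(s@muscleMask) > 0 && (s@sliceIndex - 1L) %% annotateEvery == 0L
  }, logical(1)))
}

subject_of_slices <- function(dataset) {
  vapply(dataset@slices, subjectId, character(1))
}

## per-subject mean DSC over annotated slices, given a segmentation
## function image -> mask
score_by_subject <- function(dataset, segfun, annotateEvery = 1L,
                             subjects = NULL) {
  idx <- annotated_indices(dataset, annotateEvery)
  sid <- subject_of_slices(dataset)[idx]
  if (!is.null(subjects)) {
    keep <- sid %in% subjects
    idx <- idx[keep]; sid <- sid[keep]
  }
  d <- vapply(idx, function(i) {
    sl <- dataset@slices[[i]]
    dice(segfun(sl@image), sl@muscleMask)
  }, numeric(1))
  tapply(d, sid, mean)
}

grid_combos <- function(method, grid) {
  if (method == "gc")
    expand.grid(lambdaS = grid@lambdaS, sigma = grid@sigma,
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(lambdaS = grid@lambdaS, sigma = grid@sigma,
                lambdaSp = grid@lambdaSp, pN = grid@pN,
                KEEP.OUT.ATTRS = FALSE)
}

#' Leave-one-subject-out grid search for the graph-cut segmenters
#'
#' For each held-out subject, the appearance model (and for `"spgc"` the
#' shape prior) is fitted on the remaining subjects' annotated slices;
#' hyper-parameters are selected by mean Dice over those remaining
#' subjects and the held-out subject is then scored once with the
#' selection. The held-out subject's data never enters model fitting or
#' selection.
#'
#' @param method `"gc"` or `"spgc"`.
#' @param dataset a [DomainDataset-class] whose slices carry ground-truth
#'   masks (>= 2 subjects).
#' @param grid a [GridSpec-class]; see [gridSpec()].
#' @param annotateEvery score only every k-th slice per subject (default
#'   4, mirroring sparse expert annotation).
#' @param segImages optional list of replacement images (e.g. translated
#'   versions), parallel to the dataset's slices: segmentation and model
#'   fitting run on these while Dice is always computed against the
#'   dataset's original ground truth.
#' @return list with `perSubject` (named numeric vector of held-out Dice
#'   scores), `selections` (per-fold chosen hyper-parameters) and
#'   `method`.
#' @export
gridSearch <- function(method = c("gc", "spgc"), dataset, grid = gridSpec(),
                       annotateEvery = 4L, segImages = NULL) {
  method <- match.arg(method)
  stopifnot(is(dataset, "DomainDataset"))
  work <- dataset
  if (!is.null(segImages)) {
    stopifnot(length(segImages) == length(dataset@slices))
    for (i in seq_along(segImages)) work@slices[[i]]@image <- segImages[[i]]
  }
  subs <- unique(subject_of_slices(dataset))
  if (length(subs) < 2L) stop("leave-one-out needs at least 2 subjects")
  combos <- grid_combos(method, grid)
  annIdx <- annotated_indices(dataset, annotateEvery)
  sidAll <- subject_of_slices(dataset)

  seg_with <- function(model, prior, cb) {
    if (method == "gc") {
      pp <- graphCutParams(lambdaS = cb$lambdaS, sigma = cb$sigma)
      function(img) graphCutSegment(img, model, pp)
    } else {
      pp <- spgcParams(lambdaSp = cb$lambdaSp, pN = cb$pN,
                       gc = graphCutParams(lambdaS = cb$lambdaS,
                                           sigma = cb$sigma))
      function(img) spgcSegment(img, model, prior, pp)
    }
  }

  perSubject <- numeric(length(subs))
  names(perSubject) <- subs
  selections <- vector("list", length(subs))
  names(selections) <- subs

  for (s in subs) {
    trainIdx <- annIdx[sidAll[annIdx] != s]
    model <- fitAppearanceModel(
      lapply(work@slices[trainIdx], sliceImage),
      lapply(dataset@slices[trainIdx], muscleMask))
    prior <- if (method == "spgc")
      buildShapePrior(lapply(dataset@slices[trainIdx], muscleMask))
    else NULL
    innerScores <- vapply(seq_len(nrow(combos)), function(ci) {
      mean(score_by_subject(work, seg_with(model, prior, combos[ci, ]),
                            annotateEvery, subjects = setdiff(subs, s)))
    }, numeric(1))
    best <- which.max(innerScores)   # first maximum on ties
    selections[[s]] <- c(as.list(combos[best, ]),
                         list(innerMeanDsc = innerScores[best]))
    held <- score_by_subject(work, seg_with(model, prior, combos[best, ]),
                             annotateEvery, subjects = s)
    perSubject[s] <- held[[s]]
  }
  list(perSubject = perSubject, selections = selections, method = method)
}

## fourfold (or nSubjects-fold if fewer) cross-validation for the CNN
cnn_cv_scores <- function(dataset, annotateEvery, cnnCfg, segImages = NULL,
                          foldSeedBase = 1L) {
  work <- dataset
  if (!is.null(segImages))
    for (i in seq_along(segImages)) work@slices[[i]]@image <- segImages[[i]]
  subs <- unique(subject_of_slices(dataset))
  k <- min(4L, length(subs))
  foldOf <- rep(seq_len(k), length.out = length(subs))
  annIdx <- annotated_indices(dataset, annotateEvery)
  sidAll <- subject_of_slices(dataset)
  out <- numeric(0)
  for (f in seq_len(k)) {
    testSubs <- subs[foldOf == f]
    trainIdx <- annIdx[!sidAll[annIdx] %in% testSubs]
    cfg <- cnnCfg
    cfg$seed <- mix_seed(foldSeedBase, 500L, f)
    mdl <- trainCnnSegmenter(lapply(work@slices[trainIdx], sliceImage),
                             lapply(dataset@slices[trainIdx], muscleMask),
                             cfg)
    sc <- score_by_subject(work, function(img) predictCnn(mdl, img),
                           annotateEvery, subjects = testSubs)
    out <- c(out, sc)
  }
  out[subs]
}

#' Run the translate-then-segment comparison experiment
#'
#' For every requested segmentation method and every configuration — `OI`
#' (direct segmentation of the original hard images) plus one column per
#' translation model — hard-domain slices are segmented (on the translated
#' image where applicable) and the resulting masks are scored against the
#' *original* images' ground truth, aggregated per subject.
#'
#' @param hard a [DomainDataset-class] of hard slices with ground truth.
#' @param models named list of [TranslationModel-class] objects — or
#'   [LossWeights-class] objects, in which case a model is trained per
#'   configuration from `easy`/`hard` with `trainCfg`; names become
#'   configuration labels (e.g. `"G_{0.5,1}"`). May be empty to evaluate
#'   `OI` only.
#' @param easy easy-domain [DomainDataset-class], needed only when
#'   `models` contains untrained weight configurations.
#' @param trainCfg a [TrainConfig-class] used when training is requested.
#' @param methods subset of `c("gmm", "gc", "spgc", "cnn")`.
#' @param grid a [GridSpec-class] for the graph-cut methods.
#' @param cnnCfg settings from [cnnConfig()] for the CNN.
#' @param annotateEvery score every k-th slice per subject.
#' @param seed integer seed for the stochastic stages.
#' @return an [ExperimentResult-class].
#' @seealso [summarizeExperiment()], [writeExperimentCsv()]
#' @export
runExperiment <- function(hard, models = list(), methods = "gmm",
                          grid = gridSpec(), cnnCfg = cnnConfig("tiny"),
                          annotateEvery = 1L, seed = 1L,
                          easy = NULL, trainCfg = trainConfig("tiny")) {
  stopifnot(is(hard, "DomainDataset"))
  methods <- match.arg(methods, c("gmm", "gc", "spgc", "cnn"),
                       several.ok = TRUE)
  models <- lapply(models, function(m) {
    if (is(m, "LossWeights")) {
      if (is.null(easy)) stop("training requested but no easy dataset given")
      tc <- trainCfg
      tc@seed <- mix_seed(seed, 900L, 1L)
      trainTranslation(easy, hard, m, tc)
    } else m
  })
  set.seed(seed)
  configs <- c(list(OI = NULL), models)
  rows <- list()
  selections <- list()
  for (cn in names(configs)) {
    segImages <- if (is.null(configs[[cn]])) NULL
    else lapply(hard@slices,
                function(s) translateToEasy(configs[[cn]], s@image))
    work <- hard
    if (!is.null(segImages))
      for (i in seq_along(segImages)) work@slices[[i]]@image <- segImages[[i]]
    for (m in methods) {
      sc <- switch(m,
        gmm = score_by_subject(work, function(img) gmmSegment(img),
                               annotateEvery),
        gc = {
          r <- gridSearch("gc", hard, grid, annotateEvery, segImages)
          selections[[paste(m, cn, sep = ".")]] <- r$selections
          r$perSubject
        },
        spgc = {
          r <- gridSearch("spgc", hard, grid, annotateEvery, segImages)
          selections[[paste(m, cn, sep = ".")]] <- r$selections
          r$perSubject
        },
        cnn = cnn_cv_scores(hard, annotateEvery, cnnCfg, segImages,
                            foldSeedBase = seed)
      )
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, config = cn,
                   subject_id = names(sc), dsc = as.numeric(sc),
                   stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  new("ExperimentResult", scores = scores, selections = selections,
      seeds = c(experiment = as.integer(seed)))
}

#' Summarize an experiment as one row per method x configuration
#'
#' Quartiles use linear interpolation (R quantile type 7), stated here so
#' recomputation is unambiguous.
#'
#' @param result an [ExperimentResult-class].
#' @return data.frame with columns `method, config, n, median, q1, q3,
#'   min, max`.
#' @export
summarizeExperiment <- function(result) {
  stopifnot(is(result, "ExperimentResult"))
  sc <- result@scores
  keys <- unique(sc[, c("method", "config")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    d <- sc$dsc[sc$method == keys$method[i] & sc$config == keys$config[i]]
    data.frame(method = keys$method[i], config = keys$config[i],
               n = length(d), median = stats::median(d),
               q1 = as.numeric(stats::quantile(d, 0.25, type = 7)),
               q3 = as.numeric(stats::quantile(d, 0.75, type = 7)),
               min = min(d), max = max(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read experiment result tables as CSV
#'
#' `results.csv` holds the per-subject scores
#' (`method,config,subject_id,dsc`); `summary.csv` holds the
#' [summarizeExperiment()] table. Writing is deterministic: identical
#' results produce byte-identical files.
#'
#' @param result an [ExperimentResult-class].
#' @param directory output directory (created if missing).
#' @return `writeExperimentCsv` invisibly returns the two file paths;
#'   `readExperimentScores` returns the scores data.frame.
#' @export
writeExperimentCsv <- function(result, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(directory, "results.csv")
  sp <- file.path(directory, "summary.csv")
  utils::write.csv(result@scores, rp, row.names = FALSE)
  utils::write.csv(summarizeExperiment(result), sp, row.names = FALSE)
  invisible(c(results = rp, summary = sp))
}

#' @rdname writeExperimentCsv
#' @param path path to a `results.csv` written by [writeExperimentCsv()].
#' @export
readExperimentScores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
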