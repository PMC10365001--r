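## User-facing constructors, accessors and show methods.

#' Create a phantom generator configuration
#'
#' Default tissue levels put background at 0.05, bone at 0.15, muscle at
#' 0.35 and subcutaneous fat — and therefore infiltration — at 0.85: well
#' separated levels, so that three-class intensity clustering is
#' near-perfect on non-infiltrated slices and fails on infiltrated ones in
#' a controlled way.
#'
#' @param imageSize pixels per side (square slice), >= 32.
#' @param infiltrationFraction target infiltrated fraction of muscle area.
#' @param noiseSd additive Gaussian noise sd on the \[0,1\] scale.
#' @param tissueLevels named numeric vector; see [PhantomConfig-class].
#' @param geometryJitter relative anatomical variability across subjects.
#' @param twoThighs draw two side-by-side thighs.
#' @param seed integer base seed.
#' @return a [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.4)
#' @export
phantomConfig <- function(imageSize = 64L,
                          infiltrationFraction = 0,
                          noiseSd = 0.03,
                          tissueLevels = c(background = 0.05, bone = 0.15,
                                           muscle = 0.35,
                                           subcutaneous_fat = 0.85,
                                           infiltration = 0.85),
                          geometryJitter = 0.08,
                          twoThighs = FALSE,
                          seed = 1L) {
  new("PhantomConfig",
      imageSize = as.integer(imageSize),
      infiltrationFraction = infiltrationFraction,
      noiseSd = noiseSd,
      tissueLevels = tissueLevels,
      geometryJitter = geometryJitter,
      twoThighs = twoThighs,
      seed = as.integer(seed))
}

#' Create translation-objective weights
#'
#' @param wr directional (one-sided brightening penalty) weight.
#' @param wi identity weight.
#' @param wd adversarial weight (1 in all named configurations).
#' @param wc cycle-consistency weight (1 in all named configurations).
#' @return a [LossWeights-class] object.
#' @examples
#' lossWeights(0.5, 1)        # the G_{0.5,1} configuration
#' lossWeights(0, 0)          # the standard cycle-GAN objective
#' @export
lossWeights <- function(wr = 0, wi = 0, wd = 1, wc = 1) {
  new("LossWeights", wd = wd, wc = wc, wr = wr, wi = wi)
}

#' Name of a weight configuration
#'
#' Renders the conventional `G_{wr,wi}` label (`"OI"` is reserved for the
#' untranslated baseline and is not a [LossWeights-class]).
#' @param w a [LossWeights-class] object.
#' @return character scalar such as `"G_{0.5,1}"`.
#' @export
configName <- function(w) {
  stopifnot(is(w, "LossWeights"))
  fmt <- function(x) sub("0\\.", ".", format(x, trim = TRUE))
  sprintf("G_{%s,%s}", fmt(w@wr), fmt(w@wi))
}

#' Create a translation training configuration
#'
#' Two presets are provided. `"paper"` is the full-scale setting (256x256
#' crops from 300x300 padding, 9 residual blocks, 200 epochs, learning rate
#' 2e-4). `"tiny"` is a desk-scale setting for 64x64 phantoms (2 residual
#' blocks, 8 base channels, batch 4, 40 epochs at rate 5e-4) that trains
#' in minutes on one CPU while preserving every structural element of the
#' full model.
#'
#' @param preset `"tiny"` or `"paper"`; individual arguments override the
#'   preset values.
#' @param epochs,learningRate,batchSize,nBlocks,baseChannels training and
#'   generator-architecture controls.
#' @param discLayers,discChannels patch-discriminator depth and width.
#' @param imagePadTo,cropSize augmentation pad/crop sizes.
#' @param lrDecayStart epoch after which the rate decays linearly to zero.
#' @param advForm `"lsgan"` or `"logistic"`.
#' @param globalSkip generators predict a residual added to the input.
#' @param bufferSize replay-buffer capacity.
#' @param seed integer RNG seed.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(preset = c("tiny", "paper"),
                        epochs = NULL, learningRate = NULL, batchSize = NULL,
                        nBlocks = NULL, baseChannels = NULL,
                        discLayers = NULL, discChannels = NULL,
                        imagePadTo = NULL, cropSize = NULL,
                        lrDecayStart = NULL, advForm = "lsgan",
                        globalSkip = TRUE, bufferSize = 50L, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(epochs = 40L, learningRate = 5e-4, batchSize = 4L, nBlocks = 2L,
         baseChannels = 8L, discLayers = 3L, discChannels = 8L,
         imagePadTo = 72L, cropSize = 64L, lrDecayStart = 30L)
  } else {
    list(epochs = 200L, learningRate = 2e-4, batchSize = 1L, nBlocks = 9L,
         baseChannels = 64L, discLayers = 3L, discChannels = 64L,
         imagePadTo = 300L, cropSize = 256L, lrDecayStart = 100L)
  }
  take <- function(x, d) if (is.null(x)) d else x
  new("TrainConfig",
      epochs = as.integer(take(epochs, def$epochs)),
      learningRate = take(learningRate, def$learningRate),
      batchSize = as.integer(take(batchSize, def$batchSize)),
      nBlocks = as.integer(take(nBlocks, def$nBlocks)),
      baseChannels = as.integer(take(baseChannels, def$baseChannels)),
      discLayers = as.integer(take(discLayers, def$discLayers)),
      discChannels = as.integer(take(discChannels, def$discChannels)),
      imagePadTo = as.integer(take(imagePadTo, def$imagePadTo)),
      cropSize = as.integer(take(cropSize, def$cropSize)),
      lrDecayStart = as.integer(take(lrDecayStart, def$lrDecayStart)),
      advForm = advForm, globalSkip = globalSkip,
      bufferSize = as.integer(bufferSize), seed = as.integer(seed))
}

#' EM controls for the Gaussian-mixture segmenter
#' @param maxIter iteration cap.
#' @param tol convergence tolerance on the mean log-likelihood.
#' @return a [GMMParams-class] object.
#' @export
gmmParams <- function(maxIter = 100L, tol = 1e-4) {
  new("GMMParams", maxIter = as.integer(maxIter), tol = tol)
}

#' Graph-cut parameters
#' @param lambdaS smoothness weight.
#' @param sigma low-pass Gaussian width in pixels.
#' @return a [GraphCutParams-class] object.
#' @export
graphCutParams <- function(lambdaS = 0.1, sigma = 1) {
  new("GraphCutParams", lambdaS = lambdaS, sigma = sigma)
}

#' Shape-prior graph-cut parameters
#' @param lambdaSp shape-prior weight in \[0, 1\].
#' @param pN neutral probability in (0, 1).
#' @param gc embedded [GraphCutParams-class].
#' @return an [SPGCParams-class] object.
#' @export
spgcParams <- function(lambdaSp = 0.5, pN = 0.3, gc = graphCutParams()) {
  new("SPGCParams", lambdaSp = lambdaSp, pN = pN, gc = gc)
}

#' Hyper-parameter search grids
#'
#' Defaults are the method's printed candidate grids; pass shorter vectors
#' to cut the search cost.
#' @param lambdaS,sigma,lambdaSp,pN candidate values.
#' @return a [GridSpec-class] object.
#' @export
gridSpec <- function(lambdaS = c(0.001, 0.002, 0.05, 0.1, 0.2, 0.5),
                     sigma = c(1, 2),
                     lambdaSp = c(0.1, 0.2, 0.5, 0.7, 1),
                     pN = c(0.2, 0.3, 0.4, 0.5)) {
  new("GridSpec", lambdaS = lambdaS, sigma = sigma,
      lambdaSp = lambdaSp, pN = pN)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn ImageSlice-class the image matrix.
#' @param x an object.
#' @export
sliceImage <- function(x) x@image

#' @describeIn ImageSlice-class the binary muscle ground-truth mask (or a
#'   0x0 matrix when absent).
#' @export
muscleMask <- function(x) x@muscleMask

#' @describeIn ImageSlice-class the subject identifier.
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn PhantomSlice-class the achieved infiltrated fraction of the
#'   muscle area.
#' @param x a [PhantomSlice-class].
#' @export
realizedInfiltrationFraction <- function(x) x@realizedInfiltrationFraction

#' @describeIn DomainDataset-class the list of slices.
#' @param x a [DomainDataset-class].
#' @export
datasetSlices <- function(x) x@slices

#' @describeIn DomainDataset-class the domain label (`"easy"`/`"hard"`).
#' @export
domainLabel <- function(x) x@domainLabel

#' @describeIn DomainDataset-class number of slices.
#' @export
setMethod("length", "DomainDataset", function(x) length(x@slices))

#' @describeIn DomainDataset-class extract one slice.
#' @param i index.
#' @export
setMethod("[[", "DomainDataset", function(x, i) x@slices[[i]])

#' Number of distinct subjects in a dataset
#' @param x a [DomainDataset-class].
#' @return integer.
#' @export
nSubjects <- function(x) length(unique(vapply(x@slices, subjectId, character(1))))

#' @describeIn TranslationModel-class the per-epoch loss table.
#' @param x a [TranslationModel-class].
#' @export
lossHistory <- function(x) x@lossHistory

#' @describeIn ExperimentResult-class the per-subject score table.
#' @param x an [ExperimentResult-class].
#' @export
experimentScores <- function(x) x@scores

## ---- show methods ----------------------------------------------------------

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %dx%d, infiltration %.2f, noise sd %.3f, jitter %.2f\n",
              object@imageSize, object@imageSize, object@infiltrationFraction,
              object@noiseSd, object@geometryJitter))
  lv <- object@tissueLevels
  cat("  levels:", paste(sprintf("%s=%.2f", names(lv), lv), collapse = ", "), "\n")
})

setMethod("show", "ImageSlice", function(object) {
  cat(sprintf("%s %dx%d [subject %s, slice %d]%s\n",
              class(object), nrow(object@image), ncol(object@image),
              object@subjectId, object@sliceIndex,
              if (length(object@muscleMask)) " +mask" else ""))
  if (is(object, "PhantomSlice"))
    cat(sprintf("  realized infiltration fraction: %.3f\n",
                object@realizedInfiltrationFraction))
})

setMethod("show", "DomainDataset", function(object) {
  cat(sprintf("DomainDataset '%s': %d slices from %d subjects\n",
              object@domainLabel, length(object@slices), nSubjects(object)))
})

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights %s (wd=%g, wc=%g, wr=%g, wi=%g)\n",
              configName(object), object@wd, object@wc, object@wr, object@wi))
})

setMethod("show", "TranslationModel", function(object) {
  cat(sprintf("TranslationModel %s: %d epochs, crop %d, %d residual blocks\n",
              configName(object@weights), object@config@epochs,
              object@config@cropSize, object@config@nBlocks))
  if (nrow(object@lossHistory)) {
    last <- object@lossHistory[nrow(object@lossHistory), ]
    cat(sprintf("  final losses: L_d=%.4f L_adv=%.4f L_c=%.4f L_r=%.4f L_i=%.4f\n",
                last$L_d, last$L_adv, last$L_c, last$L_r, last$L_i))
  }
})

setMethod("show", "ExperimentResult", function(object) {
  s <- summarizeExperiment(object)
  cat("ExperimentResult:\n")
  print(s, row.names = FALSE)
})
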