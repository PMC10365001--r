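#' @import methods
NULL

## ---- phantom configuration -------------------------------------------------

#' Configuration for the synthetic thigh phantom generator
#'
#' Describes a family of synthetic transversal thigh slices: a bright
#' subcutaneous-fat ring enclosing a darker muscle compartment, a dark(er)
#' bone disc inside the muscle, and bright fatty-infiltration blobs placed
#' inside the muscle at a controllable area fraction. Fatty infiltration is
#' generated at exactly the subcutaneous-fat gray level, so the two tissues
#' are indistinguishable by intensity alone — the difficulty the
#' translate-then-segment pipeline exists to remove.
#'
#' @slot imageSize integer, pixels per side of the square slice (>= 32).
#' @slot infiltrationFraction target fraction of muscle area replaced by
#'   infiltration blobs, in \[0, 1\].
#' @slot noiseSd standard deviation of additive Gaussian noise on the
#'   \[0, 1\] intensity scale.
#' @slot tissueLevels named numeric vector of mean intensities in \[0, 1\]
#'   for `background`, `subcutaneous_fat`, `muscle`, `infiltration`, `bone`.
#'   `infiltration` must equal `subcutaneous_fat`, and
#'   `background < muscle < subcutaneous_fat`.
#' @slot geometryJitter relative variability of ellipse axes/positions
#'   across subjects (non-negative).
#' @slot twoThighs logical, draw two side-by-side thighs instead of one.
#' @slot seed integer base seed; dataset generation is a pure function of
#'   the configuration and the requested counts.
#'
#' @seealso [phantomConfig()], [generatePhantomSlice()],
#'   [generateDomainDatasets()]
#' @export
setClass("PhantomConfig",
  representation(
    imageSize = "integer",
    infiltrationFraction = "numeric",
    noiseSd = "numeric",
    tissueLevels = "numeric",
    geometryJitter = "numeric",
    twoThighs = "logical",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  needed <- c("background", "subcutaneous_fat", "muscle", "infiltration", "bone")
  tl <- object@tissueLevels
  if (length(object@imageSize) != 1L || object@imageSize < 32L)
    msg <- c(msg, "imageSize must be a single integer >= 32")
  if (object@infiltrationFraction < 0 || object@infiltrationFraction > 1)
    msg <- c(msg, "infiltrationFraction must lie in [0, 1]")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (!all(needed %in% names(tl)))
    msg <- c(msg, paste("tissueLevels must name:", paste(needed, collapse = ", ")))
  else {
    if (any(tl < 0 | tl > 1))
      msg <- c(msg, "tissueLevels must lie in [0, 1]")
    if (tl[["infiltration"]] != tl[["subcutaneous_fat"]])
      msg <- c(msg, "infiltration level must equal subcutaneous_fat level")
    if (!(tl[["background"]] < tl[["muscle"]] && tl[["muscle"]] < tl[["subcutaneous_fat"]]))
      msg <- c(msg, "tissue levels must be ordered background < muscle < subcutaneous_fat")
  }
  if (object@geometryJitter < 0)
    msg <- c(msg, "geometryJitter must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---- slices and datasets ---------------------------------------------------

#' A single 2-D slice with (optional) muscle ground truth
#'
#' The minimal unit the segmentation and evaluation machinery operates on: a
#' grayscale image on the \[0, 1\] scale plus, when available, a binary
#' muscle mask (1 = muscle, including any fatty infiltration) and the
#' subject it belongs to (cross-validation splits are always by subject).
#'
#' @slot image numeric matrix with values in \[0, 1\].
#' @slot muscleMask integer/logical matrix over \{0, 1\}, same shape as
#'   `image`; may be a 0x0 matrix when no ground truth exists.
#' @slot subjectId character scalar.
#' @slot sliceIndex integer position of the slice within its subject.
#' @export
setClass("ImageSlice",
  representation(
    image = "matrix",
    muscleMask = "matrix",
    subjectId = "character",
    sliceIndex = "integer"
  )
)

setValidity("ImageSlice", function(object) {
  msg <- character()
  if (!is.numeric(object@image) || anyNA(object@image) ||
      any(!is.finite(object@image)))
    msg <- c(msg, "image must be a finite numeric matrix")
  else if (any(object@image < 0 | object@image > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  if (length(object@muscleMask)) {
    if (!identical(dim(object@muscleMask), dim(object@image)))
      msg <- c(msg, "muscleMask must match image shape")
    if (!all(object@muscleMask %in% c(0, 1)))
      msg <- c(msg, "muscleMask must be binary")
  }
  if (length(msg)) msg else TRUE
})

#' A synthetic phantom slice with full per-tissue ground truth
#'
#' Extends [ImageSlice-class] with the remaining tissue masks produced by
#' the phantom generator. `muscleMask` covers the whole muscle compartment
#' *including* infiltrated regions (the quantity the pipeline must
#' segment); `infiltrationMask` is always a subset of it, and fat, bone,
#' non-infiltrated muscle, infiltration and background partition the image.
#'
#' @slot fatMask binary matrix, subcutaneous fat ring.
#' @slot boneMask binary matrix, bone disc.
#' @slot infiltrationMask binary matrix, fatty infiltration blobs.
#' @slot realizedInfiltrationFraction achieved |infiltration| / |muscle|.
#' @export
setClass("PhantomSlice",
  contains = "ImageSlice",
  representation(
    fatMask = "matrix",
    boneMask = "matrix",
    infiltrationMask = "matrix",
    realizedInfiltrationFraction = "numeric"
  )
)

setValidity("PhantomSlice", function(object) {
  msg <- character()
  d <- dim(object@image)
  for (nm in c("fatMask", "boneMask", "infiltrationMask")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d)) msg <- c(msg, paste(nm, "must match image shape"))
    if (!all(m %in% c(0, 1))) msg <- c(msg, paste(nm, "must be binary"))
  }
  mm <- object@muscleMask; im <- object@infiltrationMask
  if (identical(dim(mm), d) && identical(dim(im), d)) {
    if (any(im == 1 & mm == 0))
      msg <- c(msg, "infiltrationMask must be contained in muscleMask")
    if (any(mm == 1 & object@fatMask == 1))
      msg <- c(msg, "muscleMask and fatMask must be disjoint")
    if (any(mm == 1 & object@boneMask == 1))
      msg <- c(msg, "muscleMask and boneMask must be disjoint")
    if (sum(mm) > 0) {
      f <- sum(im) / sum(mm)
      if (abs(f - object@realizedInfiltrationFraction) > 1e-12)
        msg <- c(msg, "realizedInfiltrationFraction must equal |infiltration|/|muscle|")
    }
  }
  if (length(msg)) msg else TRUE
})

#' An ordered collection of slices from one intensity domain
#'
#' The two unpaired training sets of the translation stage: an "easy"
#' domain (no visible fatty infiltration) and a "hard" domain (moderate to
#' severe infiltration). The two domains are assumed to share the same
#' distribution of muscle shapes while differing in intensity content.
#'
#' @slot slices list of [ImageSlice-class] (or [PhantomSlice-class])
#'   objects, all of one image size.
#' @slot domainLabel `"easy"` or `"hard"`.
#' @export
setClass("DomainDataset",
  representation(
    slices = "list",
    domainLabel = "character"
  )
)

setValidity("DomainDataset", function(object) {
  msg <- character()
  if (!object@domainLabel %in% c("easy", "hard"))
    msg <- c(msg, "domainLabel must be 'easy' or 'hard'")
  if (!all(vapply(object@slices, is, logical(1), class2 = "ImageSlice")))
    msg <- c(msg, "slices must all be ImageSlice objects")
  if (length(object@slices) > 1) {
    dims <- vapply(object@slices, function(s) dim(s@image), integer(2))
    if (any(dims != dims[, 1]))
      msg <- c(msg, "all slices must share one image size")
  }
  if (length(msg)) msg else TRUE
})

## ---- translation -----------------------------------------------------------

#' Weights of the combined translation objective
#'
#' A training configuration is written `G_{wr,wi}`: the adversarial and
#' cycle-consistency terms are fixed at weight 1, while the directional
#' (one-sided brightening penalty) weight `wr` and the identity weight `wi`
#' vary. `G_{0,0}` is the standard cycle-GAN objective.
#'
#' @slot wd adversarial weight (>= 0).
#' @slot wc cycle-consistency weight (>= 0).
#' @slot wr directional ReLU weight (>= 0).
#' @slot wi identity weight (>= 0).
#' @seealso [lossWeights()], [totalGeneratorObjective()]
#' @export
setClass("LossWeights",
  representation(wd = "numeric", wc = "numeric", wr = "numeric", wi = "numeric")
)

setValidity("LossWeights", function(object) {
  w <- c(object@wd, object@wc, object@wr, object@wi)
  if (length(w) != 4 || any(!is.finite(w)) || any(w < 0))
    "all four weights must be finite and non-negative" else TRUE
})

#' Training configuration for the translation model
#'
#' @slot epochs number of passes over the smaller domain.
#' @slot learningRate Adam step size.
#' @slot batchSize slices per update.
#' @slot nBlocks residual blocks in each generator.
#' @slot baseChannels channel width of the first generator layer.
#' @slot discLayers,discChannels patch-discriminator depth and width.
#' @slot imagePadTo pad side length before random cropping (augmentation).
#' @slot cropSize crop side length fed to the networks (<= imagePadTo).
#' @slot lrDecayStart epoch after which the learning rate decays linearly
#'   to zero (set >= epochs for a constant rate).
#' @slot advForm `"lsgan"` (least-squares, the reference implementation's
#'   default) or `"logistic"` (the printed cross-entropy form).
#' @slot globalSkip logical; when TRUE each generator predicts a residual
#'   added to its input rather than the output image directly.
#' @slot bufferSize replay-buffer capacity for discriminator fakes.
#' @slot seed integer RNG seed; training is reproducible given the seed.
#' @seealso [trainConfig()], [trainTranslation()]
#' @export
setClass("TrainConfig",
  representation(
    epochs = "integer", learningRate = "numeric", batchSize = "integer",
    nBlocks = "integer", baseChannels = "integer",
    discLayers = "integer", discChannels = "integer",
    imagePadTo = "integer", cropSize = "integer",
    lrDecayStart = "integer", advForm = "character",
    globalSkip = "logical", bufferSize = "integer", seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (object@cropSize > object@imagePadTo)
    msg <- c(msg, "cropSize must not exceed imagePadTo")
  if (!object@advForm %in% c("lsgan", "logistic"))
    msg <- c(msg, "advForm must be 'lsgan' or 'logistic'")
  if (length(msg)) msg else TRUE
})

#' A trained unpaired translation model
#'
#' Holds the two generators — `F` maps hard-domain (infiltrated) slices to
#' easy-looking ones, `G` maps the other way — and the two patch
#' discriminators used during training, plus training metadata and the
#' per-epoch loss history.
#'
#' @slot netF,netG generator networks (opaque lists of layers).
#' @slot netDH,netDE patch discriminators for the hard / easy domain.
#' @slot weights the [LossWeights-class] trained with.
#' @slot config the [TrainConfig-class] trained with.
#' @slot lossHistory data.frame, one row per epoch:
#'   `epoch, L_d, L_adv, L_c, L_r, L_i, total`.
#' @seealso [trainTranslation()], [translateToEasy()]
#' @export
setClass("TranslationModel",
  representation(
    netF = "list", netG = "list", netDH = "list", netDE = "list",
    weights = "LossWeights", config = "TrainConfig",
    lossHistory = "data.frame"
  )
)

## ---- segmentation ----------------------------------------------------------

#' Controls for the three-class Gaussian-mixture segmenter
#'
#' @slot maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @slot nBins unused by EM; kept for interface symmetry.
#' @export
setClass("GMMParams",
  representation(maxIter = "integer", tol = "numeric")
)

#' Per-label intensity likelihoods for graph-cut unaries
#'
#' Histogram densities of gray values under muscle and non-muscle,
#' estimated from annotated training slices, floored at a small epsilon and
#' normalized to unit mass over the bins.
#'
#' @slot breaks bin edges over \[0, 1\].
#' @slot pMuscle,pOther per-bin probability mass (each sums to 1).
#' @seealso [fitAppearanceModel()]
#' @export
setClass("AppearanceModel",
  representation(breaks = "numeric", pMuscle = "numeric", pOther = "numeric")
)

setValidity("AppearanceModel", function(object) {
  msg <- character()
  nb <- length(object@breaks) - 1L
  if (length(object@pMuscle) != nb || length(object@pOther) != nb)
    msg <- c(msg, "probability vectors must have one entry per bin")
  if (abs(sum(object@pMuscle) - 1) > 1e-9 || abs(sum(object@pOther) - 1) > 1e-9)
    msg <- c(msg, "per-label probabilities must sum to 1")
  if (any(object@pMuscle <= 0) || any(object@pOther <= 0))
    msg <- c(msg, "probabilities must be strictly positive (floored)")
  if (length(msg)) msg else TRUE
})

#' Graph-cut parameters
#'
#' @slot lambdaS smoothness (curvature) weight of the contrast-sensitive
#'   Potts pairwise term.
#' @slot sigma Gaussian low-pass width (pixels) applied before computing
#'   unary and pairwise terms.
#' @export
setClass("GraphCutParams",
  representation(lambdaS = "numeric", sigma = "numeric")
)

setValidity("GraphCutParams", function(object) {
  if (object@lambdaS < 0 || object@sigma < 0)
    "lambdaS and sigma must be non-negative" else TRUE
})

#' A statistical shape prior as a registered probability map
#'
#' Per-pixel probability of muscle after moment-based similarity alignment
#' of the training masks onto a reference frame (the first mask's frame).
#'
#' @slot probMap numeric matrix in \[0, 1\].
#' @slot referenceMoments list with the reference mask's centroid,
#'   principal-axis angle and scale, used to register the prior onto a new
#'   image before segmentation.
#' @seealso [buildShapePrior()], [spgcSegment()]
#' @export
setClass("ShapePrior",
  representation(probMap = "matrix", referenceMoments = "list")
)

setValidity("ShapePrior", function(object) {
  if (any(object@probMap < 0 | object@probMap > 1))
    "probMap values must lie in [0, 1]" else TRUE
})

#' Shape-prior graph-cut parameters
#'
#' @slot lambdaSp shape-prior weight in \[0, 1\]; 0 reduces exactly to the
#'   plain graph-cut.
#' @slot pN neutral probability in (0, 1): the floor toward which the
#'   registered prior is pulled, limiting how categorical the shape term
#'   can be.
#' @slot gc embedded [GraphCutParams-class].
#' @export
setClass("SPGCParams",
  representation(lambdaSp = "numeric", pN = "numeric", gc = "GraphCutParams")
)

setValidity("SPGCParams", function(object) {
  msg <- character()
  if (object@lambdaSp < 0 || object@lambdaSp > 1)
    msg <- c(msg, "lambdaSp must lie in [0, 1]")
  if (object@pN <= 0 || object@pN >= 1)
    msg <- c(msg, "pN must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

## ---- evaluation ------------------------------------------------------------

#' Candidate hyper-parameter values for cross-validated grid search
#'
#' Defaults are the printed search grids of the method: smoothness weight
#' lambdaS in \{0.001, 0.002, 0.05, 0.1, 0.2, 0.5\}, low-pass sigma in
#' \{1, 2\}, shape-prior weight lambdaSp in \{0.1, 0.2, 0.5, 0.7, 1\} and
#' neutral probability pN in \{0.2, 0.3, 0.4, 0.5\}.
#'
#' @slot lambdaS,sigma,lambdaSp,pN numeric candidate vectors (non-empty).
#' @seealso [gridSpec()], [gridSearch()]
#' @export
setClass("GridSpec",
  representation(lambdaS = "numeric", sigma = "numeric",
                 lambdaSp = "numeric", pN = "numeric")
)

setValidity("GridSpec", function(object) {
  if (!length(object@lambdaS) || !length(object@sigma) ||
      !length(object@lambdaSp) || !length(object@pN))
    "all candidate lists must be non-empty" else TRUE
})

#' Results of a translate-then-segment experiment
#'
#' Per-subject Dice scores for every method x configuration cell, where the
#' configuration is either `OI` (segmentation of the original image) or a
#' translation setting `G_{wr,wi}`, plus per-fold hyper-parameter
#' selections and the seeds used.
#'
#' @slot scores data.frame with columns `method, config, subject_id, dsc`.
#' @slot selections list of per-fold hyper-parameter choices (may be empty
#'   for parameter-free methods).
#' @slot seeds named integer vector of the seeds driving each stochastic
#'   stage.
#' @seealso [runExperiment()], [summarizeExperiment()]
#' @export
setClass("ExperimentResult",
  representation(scores = "data.frame", selections = "list", seeds = "integer")
)

setValidity("ExperimentResult", function(object) {
  msg <- character()
  need <- c("method", "config", "subject_id", "dsc")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, paste("scores must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@scores) &&
           any(object@scores$dsc < 0 | object@scores$dsc > 1))
    msg <- c(msg, "dsc values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
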