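## The four components of the unpaired translation objective. The public
## functions here take the mappings F (hard -> easy) and G (easy -> hard)
## as plain R functions acting on image batches, so they can be exercised
## against arbitrary maps in tests; the training loop computes the same
## quantities from its own forward passes.
##
## Batches are numeric arrays (H, W, N) or single matrices; all losses
## reduce by mean over pixels and batch jointly (equal image sizes), which
## keeps the weights comparable across image sizes.

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

l1_mean <- function(a, b) mean(abs(a - b))

#' Cycle-consistency loss
#'
#' Mean absolute reconstruction error of the two round trips: easy images
#' through G then F, and hard images through F then G. Zero exactly when F
#' and G are mutual inverses on the batches.
#'
#' @param F,G functions mapping an image batch (array `H x W x N` or a
#'   single matrix) to a batch of the same shape; `F` translates hard to
#'   easy, `G` easy to hard.
#' @param eBatch,hBatch easy-/hard-domain image batches.
#' @return non-negative scalar.
#' @examples
#' idf <- function(x) x
#' cycleConsistencyLoss(idf, idf,
#'                      matrix(runif(16), 4), matrix(runif(16), 4))  # 0
#' @export
cycleConsistencyLoss <- function(F, G, eBatch, hBatch) {
  e <- as_batch(eBatch); h <- as_batch(hBatch)
  if (!length(e) || !length(h)) stop("batches must be non-empty")
  l1_mean(F(G(e)), e) + l1_mean(G(F(h)), h)
}

#' Directional ReLU loss
#'
#' The domain-specific one-sided penalty: translating hard to easy must not
#' brighten any voxel (healthy muscle is darker than fat-infiltrated
#' tissue), and translating easy to hard must not darken any voxel.
#' `mean(max(0, F(h) - h)) + mean(max(0, e - G(e)))`; zero iff F never
#' increases and G never decreases a pixel value.
#'
#' @inheritParams cycleConsistencyLoss
#' @return non-negative scalar.
#' @export
directionalReluLoss <- function(F, G, eBatch, hBatch) {
  e <- as_batch(eBatch); h <- as_batch(hBatch)
  mean(pmax(F(h) - h, 0)) + mean(pmax(e - G(e), 0))
}

#' Identity loss
#'
#' Mean absolute change each generator applies to inputs already in its
#' target domain: `mean(|F(e) - e|) + mean(|G(h) - h|)`. Counterbalances
#' the directional penalty's darkening pressure on easy-domain content.
#'
#' @inheritParams cycleConsistencyLoss
#' @return non-negative scalar.
#' @export
identityLoss <- function(F, G, eBatch, hBatch) {
  e <- as_batch(eBatch); h <- as_batch(hBatch)
  l1_mean(F(e), e) + l1_mean(G(h), h)
}

#' Adversarial objectives
#'
#' Scores the discriminators on real and translated batches and returns
#' both sides of the adversarial game. The default `"lsgan"` form is
#' least-squares with targets 1 (real) and 0 (fake): the discriminator
#' objective is the sum of the four mean squared errors (0 at perfect
#' discrimination; 0.25 per term for a constant 0.5 output), and the
#' generator term is the mean squared distance of fake scores from 1. The
#' `"logistic"` form returns the cross-entropy objectives instead (the
#' generator term is the non-saturating variant).
#'
#' @param DH,DE discriminator functions (batch -> array of patch scores)
#'   for the hard and easy domain.
#' @param realH,realE real batches of each domain.
#' @param fakeH,fakeE translated batches `G(e)` and `F(h)`.
#' @param form `"lsgan"` or `"logistic"`.
#' @return list with scalars `discriminator` and `generator` (both to be
#'   minimized by their respective players).
#' @export
adversarialLosses <- function(DH, DE, realH, realE, fakeH, fakeE,
                              form = c("lsgan", "logistic")) {
  form <- match.arg(form)
  sRH <- DH(as_batch(realH)); sFH <- DH(as_batch(fakeH))
  sRE <- DE(as_batch(realE)); sFE <- DE(as_batch(fakeE))
  if (form == "lsgan") {
    list(discriminator = mean((sRH - 1)^2) + mean(sFH^2) +
           mean((sRE - 1)^2) + mean(sFE^2),
         generator = mean((sFH - 1)^2) + mean((sFE - 1)^2))
  } else {
    eps <- 1e-12
    sig <- function(x) 1 / (1 + exp(-x))
    list(discriminator = -(mean(log(sig(sRH) + eps)) +
                             mean(log(1 - sig(sFH) + eps)) +
                             mean(log(sig(sRE) + eps)) +
                             mean(log(1 - sig(sFE) + eps))),
         generator = -(mean(log(sig(sFH) + eps)) +
                         mean(log(sig(sFE) + eps))))
  }
}

#' Combined generator objective
#'
#' The weighted sum `wd * adversarial + wc * cycle + wr * directional +
#' wi * identity`. With weights `(wd, wc, wr, wi) = (1, 1, 0, 0)` this is
#' the standard cycle-GAN objective.
#'
#' @param weights a [LossWeights-class].
#' @param components named list or numeric vector with elements
#'   `adversarial`, `cycle`, `directional`, `identity` computed on one
#'   batch.
#' @return scalar.
#' @examples
#' totalGeneratorObjective(lossWeights(wr = 0.5, wi = 1),
#'   list(adversarial = 0.2, cycle = 0.4, directional = 0.1,
#'        identity = 0.3))
#' @export
totalGeneratorObjective <- function(weights, components) {
  stopifnot(is(weights, "LossWeights"))
  validObject(weights)
  cm <- as.list(components)
  need <- c("adversarial", "cycle", "directional", "identity")
  if (!all(need %in% names(cm)))
    stop("components must name: ", paste(need, collapse = ", "))
  weights@wd * cm$adversarial + weights@wc * cm$cycle +
    weights@wr * cm$directional + weights@wi * cm$identity
}
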