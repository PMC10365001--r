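## Adversarially trained encoder-decoder segmenter.
##
## A small U-Net (skip-connected encoder-decoder, sigmoid head) trained on
## (image, mask) pairs with an L1 segmentation term plus a least-squares
## adversarial term from a patch discriminator that scores (image, mask)
## channel pairs — the conditional-GAN segmentation setup. Augmentation
## (random crop from padded slices, 90-degree rotations, flips) matches
## the translation module's.

#' Configuration for the CNN segmenter
#'
#' @param preset `"tiny"` (64x64, base width 8, 30 epochs) or `"paper"`
#'   (256x256, base width 64, 200 epochs, learning rate 2e-4).
#' @param epochs,learningRate,batchSize,baseChannels,imagePadTo,cropSize
#'   overrides of the preset.
#' @param lambdaL1 weight of the L1 segmentation term relative to the
#'   adversarial term.
#' @param seed integer RNG seed.
#' @return a plain list of settings consumed by [trainCnnSegmenter()].
#' @export
cnnConfig <- function(preset = c("tiny", "paper"),
                      epochs = NULL, learningRate = NULL, batchSize = NULL,
                      baseChannels = NULL, imagePadTo = NULL, cropSize = NULL,
                      lambdaL1 = 100, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(epochs = 30L, learningRate = 2e-4, batchSize = 4L,
         baseChannels = 8L, imagePadTo = 72L, cropSize = 64L)
  } else {
    list(epochs = 200L, learningRate = 2e-4, batchSize = 1L,
         baseChannels = 64L, imagePadTo = 300L, cropSize = 256L)
  }
  take <- function(x, d) if (is.null(x)) d else x
  list(epochs = as.integer(take(epochs, def$epochs)),
       learningRate = take(learningRate, def$learningRate),
       batchSize = as.integer(take(batchSize, def$batchSize)),
       baseChannels = as.integer(take(baseChannels, def$baseChannels)),
       imagePadTo = as.integer(take(imagePadTo, def$imagePadTo)),
       cropSize = as.integer(take(cropSize, def$cropSize)),
       lambdaL1 = lambdaL1, seed = as.integer(seed))
}

#' Train the adversarial encoder-decoder segmenter
#'
#' @param images list of numeric matrices in \[0, 1\].
#' @param masks matching list of binary masks.
#' @param cfg settings from [cnnConfig()].
#' @param verbose print per-epoch losses.
#' @return an opaque model list (class `"cnnSegmenter"`) with the
#'   generator, discriminator and a per-epoch loss history data.frame.
#' @seealso [predictCnn()]
#' @export
trainCnnSegmenter <- function(images, masks, cfg = cnnConfig("tiny"),
                              verbose = FALSE) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(images) == length(masks), length(images) >= 1)
  set.seed(cfg$seed)

  net <- nn_unet(cfg$baseChannels)
  dsc <- nn_discriminator(2L, cfg$baseChannels, 3L)
  stG <- nn_adam_state(); stD <- nn_adam_state()
  bs <- cfg$batchSize
  nIter <- max(1L, length(images) %/% bs)
  lam <- cfg$lambdaL1
  hist <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(length(images))
    acc <- c(L_seg = 0, L_adv = 0, L_d = 0)
    for (it in seq_len(nIter)) {
      idx <- perm[(it - 1L) * bs + seq_len(min(bs, length(perm) - (it - 1L) * bs))]
      xs <- vector("list", length(idx)); ys <- xs
      for (j in seq_along(idx)) {
        img <- pad_replicate(images[[idx[j]]], cfg$imagePadTo)
        msk <- pad_replicate(matrix(as.numeric(masks[[idx[j]]]),
                                    nrow(masks[[idx[j]]])), cfg$imagePadTo)
        d <- dim(img)
        r0 <- if (d[1] > cfg$cropSize) sample.int(d[1] - cfg$cropSize + 1L, 1L) else 1L
        c0 <- if (d[2] > cfg$cropSize) sample.int(d[2] - cfg$cropSize + 1L, 1L) else 1L
        rr <- r0 + seq_len(cfg$cropSize) - 1L
        cc <- c0 + seq_len(cfg$cropSize) - 1L
        img <- img[rr, cc]; msk <- msk[rr, cc]
        k <- sample.int(4L, 1L) - 1L
        img <- rot90k(img, k); msk <- rot90k(msk, k)
        if (stats::runif(1) < 0.5) {
          img <- img[, rev(seq_len(ncol(img)))]
          msk <- msk[, rev(seq_len(ncol(msk)))]
        }
        xs[[j]] <- img; ys[[j]] <- msk
      }
      x <- make_batch(xs)
      y <- make_batch(ys)
      np <- length(y)

      ## generator step
      fw <- unet_fwd(net, x)
      pred <- fw$out
      fakePair <- cat_ch(x, pred)
      df <- disc_fwd(dsc, fakePair)
      lAdv <- mean((df$out - 1)^2)
      lSeg <- mean(abs(pred - y))
      dScore <- 2 * (df$out - 1) / length(df$out)
      bD <- disc_bwd(dsc, df, dScore)
      dPred <- bD$dx[, , , 2L, drop = FALSE] + lam * sign(pred - y) / np
      bG <- unet_bwd(net, fw$caches, dPred)
      rG <- nn_adam_step(unet_as_layers(net), unet_grads_as_list(bG$grads),
                         stG, cfg$learningRate)
      net <- unet_from_layers(net, rG$layers); stG <- rG$state

      ## discriminator step
      realPair <- cat_ch(x, y)
      fr <- disc_fwd(dsc, realPair)
      ff <- disc_fwd(dsc, cat_ch(x, pred))
      lD <- mean((fr$out - 1)^2) + mean(ff$out^2)
      gD <- nn_grads_add(
        disc_bwd(dsc, fr, (fr$out - 1) / length(fr$out))$grads,
        disc_bwd(dsc, ff, ff$out / length(ff$out))$grads)
      rD <- nn_adam_step(dsc$layers, gD, stD, cfg$learningRate)
      dsc$layers <- rD$layers; stD <- rD$state

      if (!is.finite(lSeg + lAdv + lD))
        stop(sprintf("non-finite loss at epoch %d iter %d", epoch, it))
      acc <- acc + c(lSeg, lAdv, lD)
    }
    acc <- acc / nIter
    hist[[epoch]] <- data.frame(epoch = epoch, L_seg = acc[["L_seg"]],
                                L_adv = acc[["L_adv"]], L_d = acc[["L_d"]])
    if (verbose)
      message(sprintf("epoch %3d  L_seg %.4f  L_adv %.4f  L_d %.4f",
                      epoch, acc[["L_seg"]], acc[["L_adv"]], acc[["L_d"]]))
  }
  structure(list(net = net, disc = dsc, cfg = cfg,
                 lossHistory = do.call(rbind, hist)),
            class = "cnnSegmenter")
}

#' Predict a muscle mask with the trained CNN segmenter
#'
#' @param model a `"cnnSegmenter"` from [trainCnnSegmenter()].
#' @param image numeric matrix in \[0, 1\] whose sides are multiples of 8.
#' @return binary integer matrix (1 = muscle), prediction thresholded at
#'   0.5.
#' @export
predictCnn <- function(model, image) {
  stopifnot(inherits(model, "cnnSegmenter"), is.matrix(image))
  d <- dim(image)
  x <- array(image, c(d[1], d[2], 1L, 1L))
  p <- unet_fwd(model$net, x)$out
  matrix(as.integer(p >= 0.5), d[1], d[2])
}
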