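## Unpaired cyclic translation training.
##
## Two generators (F: hard -> easy, G: easy -> hard) and two patch
## discriminators are optimized alternately with Adam (beta1 = 0.5). The
## generator objective is
##   wd * adversarial + wc * cycle + wr * directional + wi * identity,
## computed on an internal [-1, 1] intensity scale (the directional and
## identity semantics are preserved under this affine map). Discriminators
## train on a replay buffer of past fakes. Everything is reproducible from
## the TrainConfig seed.

clip01 <- function(x) pmin(pmax(x, 0), 1)
to_internal <- function(x) 2 * x - 1
from_internal <- function(x) clip01((x + 1) / 2)

pad_replicate <- function(m, to) {
  d <- dim(m)
  if (d[1] >= to && d[2] >= to) return(m)
  ri <- pmin(pmax(seq_len(to) - (to - d[1]) %/% 2L, 1L), d[1])
  ci <- pmin(pmax(seq_len(to) - (to - d[2]) %/% 2L, 1L), d[2])
  m[ri, ci]
}

rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m
}

augment_slice <- function(m, pad_to, crop) {
  m <- pad_replicate(m, pad_to)
  d <- dim(m)
  r0 <- if (d[1] > crop) sample.int(d[1] - crop + 1L, 1L) else 1L
  c0 <- if (d[2] > crop) sample.int(d[2] - crop + 1L, 1L) else 1L
  m <- m[r0 + seq_len(crop) - 1L, c0 + seq_len(crop) - 1L]
  m <- rot90k(m, sample.int(4L, 1L) - 1L)
  if (stats::runif(1) < 0.5) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

make_batch <- function(mats) {
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(d[1], d[2], length(mats), 1L))
}

## replay buffer (reference-implementation behaviour): returns the batch
## the discriminator sees; mutates the buffer environment.
buffer_query <- function(buf, fakes_list, capacity) {
  out <- vector("list", length(fakes_list))
  for (i in seq_along(fakes_list)) {
    img <- fakes_list[[i]]
    if (length(buf$items) < capacity) {
      buf$items[[length(buf$items) + 1L]] <- img
      out[[i]] <- img
    } else if (stats::runif(1) < 0.5) {
      j <- sample.int(length(buf$items), 1L)
      out[[i]] <- buf$items[[j]]
      buf$items[[j]] <- img
    } else {
      out[[i]] <- img
    }
  }
  out
}

split_batch <- function(arr) {
  n <- dim(arr)[3]
  lapply(seq_len(n), function(i) arr[, , i, 1])
}

## gradient of the generator-side adversarial term wrt discriminator score
adv_gen_grad <- function(s, form) {
  n <- length(s)
  if (form == "lsgan") 2 * (s - 1) / n else -(1 / (1 + exp(s))) / n
}
adv_gen_value <- function(s, form) {
  if (form == "lsgan") mean((s - 1)^2)
  else -mean(log(1 / (1 + exp(-s)) + 1e-12))
}
adv_disc_value <- function(sr, sf, form) {
  if (form == "lsgan") mean((sr - 1)^2) + mean(sf^2)
  else -mean(log(1 / (1 + exp(-sr)) + 1e-12)) -
    mean(log(1 - 1 / (1 + exp(-sf)) + 1e-12))
}
adv_disc_grads <- function(sr, sf, form) {
  if (form == "lsgan")
    list(dr = 2 * (sr - 1) / length(sr), df = 2 * sf / length(sf))
  else
    list(dr = -(1 / (1 + exp(sr))) / length(sr),
         df = (1 / (1 + exp(-sf))) / length(sf))
}

#' Train the unpaired translation model
#'
#' Alternates generator and discriminator Adam updates per batch over the
#' two unpaired domains, with random-crop / 90-degree-rotation / flip
#' augmentation, a replay buffer for discriminator fakes, and an optional
#' linear learning-rate decay. Returns the final-epoch model (no
#' validation-based selection). Aborts with a diagnostic if any loss
#' becomes non-finite.
#'
#' @param easy,hard [DomainDataset-class] objects (unpaired).
#' @param weights a [LossWeights-class] (e.g. `lossWeights(0.5, 1)` for
#'   the `G_{0.5,1}` configuration).
#' @param cfg a [TrainConfig-class]; see [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return a [TranslationModel-class].
#' @seealso [translateToEasy()], [lossHistory()]
#' @export
trainTranslation <- function(easy, hard, weights = lossWeights(0.5, 1),
                             cfg = trainConfig("tiny"), verbose = FALSE) {
  stopifnot(is(easy, "DomainDataset"), is(hard, "DomainDataset"))
  if (!length(easy@slices) || !length(hard@slices))
    stop("both domains must be non-empty")
  validObject(weights); validObject(cfg)
  set.seed(cfg@seed)

  eImgs <- lapply(easy@slices, function(s) to_internal(s@image))
  hImgs <- lapply(hard@slices, function(s) to_internal(s@image))

  netF <- nn_generator(cfg@baseChannels, cfg@nBlocks, cfg@globalSkip)
  netG <- nn_generator(cfg@baseChannels, cfg@nBlocks, cfg@globalSkip)
  netDH <- nn_discriminator(1L, cfg@discChannels, cfg@discLayers)
  netDE <- nn_discriminator(1L, cfg@discChannels, cfg@discLayers)
  stF <- nn_adam_state(); stG <- nn_adam_state()
  stDH <- nn_adam_state(); stDE <- nn_adam_state()
  bufH <- new.env(); bufH$items <- list()
  bufE <- new.env(); bufE$items <- list()

  bs <- cfg@batchSize
  nIter <- max(1L, min(length(eImgs), length(hImgs)) %/% bs)
  form <- cfg@advForm
  wd <- weights@wd; wc <- weights@wc; wr <- weights@wr; wi <- weights@wi
  hist <- vector("list", cfg@epochs)

  for (epoch in seq_len(cfg@epochs)) {
    lr <- cfg@learningRate
    if (epoch > cfg@lrDecayStart)
      lr <- lr * (1 - (epoch - cfg@lrDecayStart) /
                    (cfg@epochs - cfg@lrDecayStart + 1))
    ePerm <- sample(length(eImgs))
    hPerm <- sample(length(hImgs))
    acc <- c(L_d = 0, L_adv = 0, L_c = 0, L_r = 0, L_i = 0, total = 0)

    for (it in seq_len(nIter)) {
      # wrap around when a domain holds fewer slices than one batch
      eIdx <- ePerm[(((it - 1L) * bs + seq_len(bs) - 1L) %% length(ePerm)) + 1L]
      hIdx <- hPerm[(((it - 1L) * bs + seq_len(bs) - 1L) %% length(hPerm)) + 1L]
      e <- make_batch(lapply(eImgs[eIdx], augment_slice,
                             pad_to = cfg@imagePadTo, crop = cfg@cropSize))
      h <- make_batch(lapply(hImgs[hIdx], augment_slice,
                             pad_to = cfg@imagePadTo, crop = cfg@cropSize))
      np <- length(h)

      ## ---- generator step ----
      fF1 <- gen_fwd(netF, h)          # fh = F(h)
      fh <- fF1$out
      fG1 <- gen_fwd(netG, fh)         # G(F(h))
      fG2 <- gen_fwd(netG, e)          # ge = G(e)
      ge <- fG2$out
      fF2 <- gen_fwd(netF, ge)         # F(G(e))

      dFE <- disc_fwd(netDE, fh)
      dHH <- disc_fwd(netDH, ge)

      lAdv <- adv_gen_value(dFE$out, form) + adv_gen_value(dHH$out, form)
      lCyc <- mean(abs(fG1$out - h)) + mean(abs(fF2$out - e))
      lDir <- mean(pmax(fh - h, 0)) + mean(pmax(e - ge, 0))

      ## d(loss)/d(fh)
      bDE <- disc_bwd(netDE, dFE, wd * adv_gen_grad(dFE$out, form))
      bG1 <- gen_bwd(netG, fG1, wc * sign(fG1$out - h) / np)
      gG <- bG1$grads
      dfh <- bDE$dx + bG1$dx + wr * (fh > h) / np
      bF1 <- gen_bwd(netF, fF1, dfh)
      gF <- bF1$grads

      ## d(loss)/d(ge)
      bDH <- disc_bwd(netDH, dHH, wd * adv_gen_grad(dHH$out, form))
      bF2 <- gen_bwd(netF, fF2, wc * sign(fF2$out - e) / np)
      gF <- nn_grads_add(gF, bF2$grads)
      dge <- bDH$dx + bF2$dx - wr * (e > ge) / np
      bG2 <- gen_bwd(netG, fG2, dge)
      gG <- nn_grads_add(gG, bG2$grads)

      ## identity terms
      lIdt <- 0
      if (wi > 0) {
        fF3 <- gen_fwd(netF, e)
        fG3 <- gen_fwd(netG, h)
        lIdt <- mean(abs(fF3$out - e)) + mean(abs(fG3$out - h))
        gF <- nn_grads_add(gF, gen_bwd(netF, fF3,
                                       wi * sign(fF3$out - e) / np)$grads)
        gG <- nn_grads_add(gG, gen_bwd(netG, fG3,
                                       wi * sign(fG3$out - h) / np)$grads)
      }

      rF <- nn_adam_step(netF$layers, gF, stF, lr)
      netF$layers <- rF$layers; stF <- rF$state
      rG <- nn_adam_step(netG$layers, gG, stG, lr)
      netG$layers <- rG$layers; stG <- rG$state

      ## ---- discriminator step (on buffered fakes, detached) ----
      fakeE <- make_batch(buffer_query(bufE, split_batch(fh), cfg@bufferSize))
      fakeH <- make_batch(buffer_query(bufH, split_batch(ge), cfg@bufferSize))

      lD <- 0
      for (side in c("E", "H")) {
        nd <- if (side == "E") netDE else netDH
        real <- if (side == "E") e else h
        fake <- if (side == "E") fakeE else fakeH
        fr <- disc_fwd(nd, real)
        ff <- disc_fwd(nd, fake)
        lD <- lD + adv_disc_value(fr$out, ff$out, form)
        gdd <- adv_disc_grads(fr$out, ff$out, form)
        gD <- nn_grads_add(disc_bwd(nd, fr, 0.5 * gdd$dr)$grads,
                           disc_bwd(nd, ff, 0.5 * gdd$df)$grads)
        if (side == "E") {
          rD <- nn_adam_step(netDE$layers, gD, stDE, lr)
          netDE$layers <- rD$layers; stDE <- rD$state
        } else {
          rD <- nn_adam_step(netDH$layers, gD, stDH, lr)
          netDH$layers <- rD$layers; stDH <- rD$state
        }
      }

      tot <- wd * lAdv + wc * lCyc + wr * lDir + wi * lIdt
      if (!is.finite(tot) || !is.finite(lD))
        stop(sprintf(
          "non-finite loss at epoch %d iter %d (adv=%g cyc=%g dir=%g idt=%g d=%g)",
          epoch, it, lAdv, lCyc, lDir, lIdt, lD))
      acc <- acc + c(lD, lAdv, lCyc, lDir, lIdt, tot)
    }

    acc <- acc / nIter
    hist[[epoch]] <- data.frame(epoch = epoch, L_d = acc[["L_d"]],
                                L_adv = acc[["L_adv"]], L_c = acc[["L_c"]],
                                L_r = acc[["L_r"]], L_i = acc[["L_i"]],
                                total = acc[["total"]])
    if (verbose)
      message(sprintf(
        "epoch %3d  L_d %.4f  L_adv %.4f  L_c %.4f  L_r %.4f  L_i %.4f",
        epoch, acc[["L_d"]], acc[["L_adv"]], acc[["L_c"]], acc[["L_r"]],
        acc[["L_i"]]))
  }

  new("TranslationModel", netF = netF, netG = netG,
      netDH = netDH, netDE = netDE,
      weights = weights, config = cfg,
      lossHistory = do.call(rbind, hist))
}

#' Create an untrained (randomly initialized) translation model
#'
#' Useful as the before-training baseline when measuring what training
#' changes (e.g. the directional excess of the hard-to-easy mapping).
#'
#' @param cfg a [TrainConfig-class].
#' @param weights a [LossWeights-class] recorded on the model.
#' @return a [TranslationModel-class] with freshly initialized networks.
#' @export
untrainedTranslationModel <- function(cfg = trainConfig("tiny"),
                                      weights = lossWeights(0, 0)) {
  set.seed(cfg@seed)
  new("TranslationModel",
      netF = nn_generator(cfg@baseChannels, cfg@nBlocks, cfg@globalSkip),
      netG = nn_generator(cfg@baseChannels, cfg@nBlocks, cfg@globalSkip),
      netDH = nn_discriminator(1L, cfg@discChannels, cfg@discLayers),
      netDE = nn_discriminator(1L, cfg@discChannels, cfg@discLayers),
      weights = weights, config = cfg,
      lossHistory = data.frame())
}

translate_with <- function(net, image) {
  d <- dim(image)
  x <- array(to_internal(image), c(d[1], d[2], 1L, 1L))
  out <- gen_fwd(net, x)$out
  from_internal(matrix(out, d[1], d[2]))
}

#' Translate a hard-domain slice into the easy domain
#'
#' Applies the trained hard-to-easy generator and maps the output back to
#' the external \[0, 1\] scale (same shape as the input). Downstream, the
#' mask obtained by segmenting the translated image is paired with the
#' *original* image unchanged — translation only produces an intermediate,
#' easier-to-segment representation.
#'
#' @param model a [TranslationModel-class].
#' @param image numeric matrix in \[0, 1\].
#' @return numeric matrix in \[0, 1\], same shape.
#' @export
translateToEasy <- function(model, image) {
  stopifnot(is(model, "TranslationModel"), is.matrix(image))
  translate_with(model@netF, image)
}

#' Translate an easy-domain slice into the hard domain
#' @inheritParams translateToEasy
#' @return numeric matrix in \[0, 1\], same shape.
#' @export
translateToHard <- function(model, image) {
  stopifnot(is(model, "TranslationModel"), is.matrix(image))
  translate_with(model@netG, image)
}

#' Mean directional excess of the hard-to-easy mapping
#'
#' `mean(max(0, F(h) - h))` averaged over the supplied slices, on the
#' \[0, 1\] scale: how much, on average, the translation *brightens*
#' pixels it should only darken. The quantity the directional loss drives
#' toward zero.
#'
#' @param model a [TranslationModel-class].
#' @param dataset a [DomainDataset-class] of hard slices.
#' @return non-negative scalar.
#' @export
directionalExcess <- function(model, dataset) {
  vals <- vapply(dataset@slices, function(s) {
    mean(pmax(translateToEasy(model, s@image) - s@image, 0))
  }, numeric(1))
  mean(vals)
}

#' Save / load a translation model checkpoint
#'
#' The checkpoint holds both generators, both discriminators, the loss
#' weights, the training configuration and the loss history.
#'
#' @param model a [TranslationModel-class].
#' @param path checkpoint file path (`.rds`).
#' @return `saveTranslationModel` returns the path invisibly;
#'   `loadTranslationModel` returns the model.
#' @export
saveTranslationModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveTranslationModel
#' @export
loadTranslationModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "TranslationModel"))
  m
}
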