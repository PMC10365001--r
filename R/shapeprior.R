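## Statistical shape prior as a registered probability map.
##
## Training masks are aligned to the first mask's frame by a moment-based
## similarity transform (centroid + principal-axis angle + area scale);
## the prior is the per-pixel mean of the aligned masks. At segmentation
## time the prior is registered onto the test image through the same
## moment procedure applied to an initialization mask (by default the
## unsupervised mixture segmentation), then blended into the graph-cut
## unaries.

mask_moments <- function(mask) {
  idx <- which(mask == 1)
  if (!length(idx)) stop("empty mask")
  H <- nrow(mask)
  ys <- ((idx - 1L) %% H) + 1L
  xs <- ((idx - 1L) %/% H) + 1L
  cy <- mean(ys); cx <- mean(xs)
  u <- xs - cx; v <- ys - cy
  cxx <- mean(u * u); cyy <- mean(v * v); cxy <- mean(u * v)
  # principal-axis angle in (-pi/2, pi/2]
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  list(cx = cx, cy = cy, theta = theta, scale = sqrt(length(idx)))
}

## Similarity transform taking coordinates in frame `from` to frame `to`;
## applied by inverse warping with bilinear interpolation.
warp_to_frame <- function(img, from, to, outDim) {
  s <- from$scale / to$scale
  dth <- from$theta - to$theta
  H <- outDim[1]; W <- outDim[2]
  xs <- matrix(rep(seq_len(W), each = H), H)
  ys <- matrix(rep(seq_len(H), times = W), H)
  # map output (to-frame) coords back into the source (from-frame)
  u <- xs - to$cx; v <- ys - to$cy
  xsrc <- from$cx + s * (cos(dth) * u - sin(dth) * v)
  ysrc <- from$cy + s * (sin(dth) * u + cos(dth) * v)
  bilinear_sample(img, ysrc, xsrc)
}

bilinear_sample <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    out <- numeric(length(yy))
    out[ok] <- img[cbind(yy[ok], xx[ok])]
    out
  }
  out <- (1 - fy) * (1 - fx) * gv(y0, x0) +
    (1 - fy) * fx * gv(y0, x0 + 1) +
    fy * (1 - fx) * gv(y0 + 1, x0) +
    fy * fx * gv(y0 + 1, x0 + 1)
  matrix(out, nrow(ys), ncol(ys))
}

#' Build a shape prior from training masks
#'
#' Aligns every training mask onto the first mask's frame with a
#' moment-based similarity transform and averages them into a per-pixel
#' muscle probability map.
#'
#' @param trainingMasks list of at least two binary masks (or a single
#'   list of one, in which case the prior is that mask).
#' @return a [ShapePrior-class].
#' @export
buildShapePrior <- function(trainingMasks) {
  if (is.matrix(trainingMasks)) trainingMasks <- list(trainingMasks)
  stopifnot(length(trainingMasks) >= 1)
  ref <- trainingMasks[[1]]
  refM <- mask_moments(ref)
  aligned <- lapply(trainingMasks, function(m) {
    mm <- mask_moments(m)
    warp_to_frame(matrix(as.numeric(m), nrow(m)), mm, refM, dim(ref))
  })
  prior <- Reduce(`+`, aligned) / length(aligned)
  prior <- pmin(pmax(prior, 0), 1)
  new("ShapePrior", probMap = prior,
      referenceMoments = refM)
}

#' Shape-prior graph-cut segmentation
#'
#' Registers the shape prior onto the test image (similarity transform
#' from the prior's reference frame to the frame of an initialization
#' mask, by default the unsupervised mixture segmentation), blends it
#' toward the neutral probability `pN`, and solves the graph-cut with
#' unaries
#' `-log[(1 - lambdaSp) * P(I | L) + lambdaSp * P_shape(L)]`
#' where `P_shape(muscle) = pN + (1 - pN) * prior` and
#' `P_shape(other) = pN + (1 - pN) * (1 - prior)`. With `lambdaSp = 0`
#' this reduces exactly to [graphCutSegment()].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param model an [AppearanceModel-class].
#' @param prior a [ShapePrior-class] from [buildShapePrior()].
#' @param params an [SPGCParams-class]; see [spgcParams()].
#' @param init optional binary initialization mask used for registering
#'   the prior; computed by [gmmSegment()] when absent.
#' @return binary integer matrix (1 = muscle) with attribute `"energy"`.
#' @export
spgcSegment <- function(image, model, prior, params = spgcParams(),
                        init = NULL) {
  validObject(params)
  H <- nrow(image); W <- ncol(image)
  if (params@lambdaSp > 0) {
    if (is.null(init)) init <- gmmSegment(image)
    initM <- mask_moments(init)
    pmap <- warp_to_frame(prior@probMap, prior@referenceMoments, initM,
                          c(H, W))
    pmap <- pmin(pmax(pmap, 0), 1)
  } else {
    pmap <- matrix(0.5, H, W)   # unused (lambdaSp = 0)
  }
  sm <- smooth_image(image, params@gc@sigma)
  lk <- appearanceLikelihood(model, sm)
  pn <- params@pN
  lsp <- params@lambdaSp
  q1 <- pn + (1 - pn) * pmap
  q0 <- pn + (1 - pn) * (1 - pmap)
  D1 <- -log((1 - lsp) * lk$muscle + lsp * q1)
  D0 <- -log((1 - lsp) * lk$other + lsp * q0)
  if (any(!is.finite(D0)) || any(!is.finite(D1)))
    stop("non-finite unaries")
  edges <- grid_edges(H, W)
  dI2 <- (sm[edges[, 1]] - sm[edges[, 2]])^2
  beta <- mean(dI2)
  wEdge <- if (beta > 1e-12) params@gc@lambdaS * exp(-dI2 / (2 * beta))
           else rep(params@gc@lambdaS, nrow(edges))
  lab <- mincut_label(as.numeric(D0), as.numeric(D1), edges, wEdge)
  mask <- matrix(lab, H, W)
  attr(mask, "energy") <- segmentationEnergy(mask, D0, D1, edges, wEdge)
  mask
}
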