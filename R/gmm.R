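## Unsupervised three-class Gaussian-mixture segmentation.
##
## The body is first separated from background (two-class k-means on gray
## values, threshold at the midpoint of the centers, largest connected
## component, holes filled); inside it a three-component 1-D mixture
## (muscle, fat, bone/vessels) is fitted by EM from fixed initial centers
## at the minimum gray value, the maximum, and min + range/6. The muscle
## mask is the set of body pixels whose maximum-responsibility component is
## the one whose converged mean lies nearest the initial middle center.

#' Fixed initial cluster centers for the three-class mixture
#'
#' Returns `(s_min, s_min + (s_max - s_min) / 6, s_max)` where `s_min`,
#' `s_max` are the minimum and maximum gray values of the image. The
#' placement encodes the expected ordering dark-muscle / mid / bright-fat
#' and is affine-equivariant in the intensities.
#'
#' @param image numeric matrix (any intensity units).
#' @return numeric vector of three strictly increasing centers.
#' @examples
#' gmmInitCenters(matrix(c(0, 0.5, 1), 1))   # 0, 1/6, 1
#' @export
gmmInitCenters <- function(image) {
  sMin <- min(image)
  sMax <- max(image)
  if (sMax <= sMin)
    stop("degenerate input: image is constant (s_min == s_max)")
  c(sMin, sMin + (sMax - sMin) / 6, sMax)
}

## EM for a 1-D 3-component Gaussian mixture with fixed initial centers and
## shared initial variance ((range/10)^2). Returns means, variances,
## weights, responsibilities, convergence flag.
gmm_em <- function(x, centers, maxIter = 100L, tol = 1e-4) {
  K <- length(centers)
  mu <- centers
  v <- rep(((max(x) - min(x)) / 10)^2, K)
  v <- pmax(v, 1e-8)
  w <- rep(1 / K, K)
  n <- length(x)
  prevLL <- -Inf
  converged <- FALSE
  R <- NULL
  for (iter in seq_len(maxIter)) {
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sqrt(v[k]), log = TRUE) + log(w[k])
    }, numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    R <- exp(logd - lse)
    ll <- mean(lse)
    nk <- colSums(R)
    nk <- pmax(nk, 1e-12)
    mu <- colSums(R * x) / nk
    v <- pmax(colSums(R * (x - rep(mu, each = n))^2) / nk, 1e-8)
    w <- nk / n
    if (is.finite(ll) && abs(ll - prevLL) < tol) {
      converged <- TRUE
      break
    }
    prevLL <- ll
  }
  list(mu = mu, v = v, w = w, R = R, converged = converged)
}

## Background separation: 2-means on intensities (deterministic extreme
## initialization), threshold at the center midpoint, keep the largest
## connected foreground component, fill holes (bone and dark muscle are
## interior to the bright fat ring).
foreground_mask <- function(image) {
  km <- stats::kmeans(as.numeric(image),
                      centers = matrix(range(image), 2, 1))
  thr <- mean(km$centers)
  fg <- image > thr
  lab <- EBImage::bwlabel(matrix(as.integer(fg), nrow(image)))
  if (max(lab) == 0) return(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(matrix(as.integer(keep), nrow(image)))
  matrix(filled > 0, nrow(image))
}

#' Segment muscle by unsupervised three-class mixture clustering
#'
#' Completely unsupervised: no training data is used. Works well when
#' muscle is the only mid-intensity tissue; fat-infiltrated muscle is
#' (by construction of the problem) assigned to the fat component, which
#' is the failure mode the translate-then-segment pipeline removes.
#'
#' @param image numeric matrix in \[0, 1\] (at least 3 distinct values).
#' @param params a [GMMParams-class]; see [gmmParams()].
#' @return binary integer matrix (1 = muscle) of the image's shape, with
#'   attribute `"converged"` (logical EM flag).
#' @examples
#' dd <- generateDomainDatasets(1, 1, 1, phantomConfig(seed = 3L))
#' m <- gmmSegment(sliceImage(dd$easy[[1]]))
#' dice(m, muscleMask(dd$easy[[1]]))
#' @export
gmmSegment <- function(image, params = gmmParams()) {
  if (length(unique(as.numeric(image))) < 3L)
    stop("degenerate input: need at least 3 distinct gray values")
  fg <- foreground_mask(image)
  px <- image[fg]
  if (!length(px) || max(px) <= min(px))
    stop("degenerate input: foreground is empty or constant")
  centers <- gmmInitCenters(matrix(px, 1))
  fit <- gmm_em(px, centers, params@maxIter, params@tol)
  if (!fit$converged)
    warning("EM did not converge within maxIter; returning best-so-far fit")
  # EM preserves component identity: muscle is the component initialized at
  # the middle center. (Selecting by distance of converged means to that
  # center instead is fragile: a small dark bone/vessel tail component can
  # converge nearer to it than muscle does.)
  muscleComp <- 2L
  assign <- max.col(fit$R, ties.method = "first")
  mask <- matrix(0L, nrow(image), ncol(image))
  fgIdx <- which(fg)
  mask[fgIdx[assign == muscleComp]] <- 1L
  attr(mask, "converged") <- fit$converged
  mask
}
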