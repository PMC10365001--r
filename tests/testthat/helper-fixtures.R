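# Shared fixtures: small phantom datasets built in code, plus brute-force
# reference implementations used as independent oracles.

tiny_phantom <- function(size = 64, frac = 0, noise = 0.03, seed = 1L,
                         sliceSeed = 10L) {
  cfg <- phantomConfig(imageSize = size, infiltrationFraction = frac,
                       noiseSd = noise, seed = seed)
  generatePhantomSlice(cfg, subjectGeometry(cfg, seed), sliceSeed)
}

# explicit-loop L1 mean of two batches (H x W x N arrays)
loop_l1 <- function(a, b) {
  tot <- 0; n <- 0
  for (k in seq_len(dim(a)[3]))
    for (i in seq_len(dim(a)[1]))
      for (j in seq_len(dim(a)[2])) {
        tot <- tot + abs(a[i, j, k] - b[i, j, k]); n <- n + 1
      }
  tot / n
}

loop_relu_mean <- function(a, b) {   # mean over pixels of max(0, a - b)
  tot <- 0; n <- 0
  for (k in seq_len(dim(a)[3]))
    for (i in seq_len(dim(a)[1]))
      for (j in seq_len(dim(a)[2])) {
        tot <- tot + max(0, a[i, j, k] - b[i, j, k]); n <- n + 1
      }
  tot / n
}

rand_batch <- function(h = 4, w = 4, n = 2) array(runif(h * w * n), c(h, w, n))

# an appearance model fitted on a couple of infiltrated phantoms
make_appearance <- function(seed = 55L, n = 2) {
  cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.3, seed = seed)
  sls <- lapply(seq_len(n), function(i)
    generatePhantomSlice(cfg, subjectGeometry(cfg, seed + i), seed + 10L + i))
  fitAppearanceModel(lapply(sls, sliceImage), lapply(sls, muscleMask))
}

# enumerate all binary labelings of np pixels and return the minimum energy
brute_force_min_energy <- function(D0, D1, edges, wEdge) {
  np <- length(D0)
  best <- Inf
  for (code in 0:(2^np - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(np)]
    e <- sum(ifelse(lab == 1L, D1, D0)) +
      sum(wEdge[lab[edges[, 1]] != lab[edges[, 2]]])
    if (e < best) best <- e
  }
  best
}

# unaries/pairwise exactly as the segmenters build them (kept in sync with
# the package; used only to feed the exhaustive-enumeration oracle)
gc_terms <- function(image, model, lambdaS, sigma) {
  sm <- if (sigma > 0) as.matrix(EBImage::gblur(image, sigma = sigma)) else image
  lk <- appearanceLikelihood(model, sm)
  edges <- muscleTranSeg:::grid_edges(nrow(image), ncol(image))
  dI2 <- (sm[edges[, 1]] - sm[edges[, 2]])^2
  beta <- mean(dI2)
  w <- if (beta > 1e-12) lambdaS * exp(-dI2 / (2 * beta))
       else rep(lambdaS, nrow(edges))
  list(D0 = -log(lk$other), D1 = -log(lk$muscle), edges = edges, wEdge = w,
       sm = sm)
}
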