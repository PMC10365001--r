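## Synthetic thigh phantom generator.
##
## Geometry: a jittered outer ellipse (thigh boundary) encloses a jittered
## inner ellipse (muscle compartment); a disc at a jittered interior
## position is bone; the ring between the ellipses is subcutaneous fat.
## Fatty infiltration is a union of random discs accepted only if fully
## inside the muscle compartment, grown until the infiltrated area fraction
## first enters a +/-0.05 band around the target. Infiltration is drawn at
## the subcutaneous-fat gray level, so the two tissues are pixelwise
## indistinguishable by intensity — which is exactly what makes the "hard"
## domain hard.

# deterministic seed mixing; keeps derived seeds within 32-bit range
mix_seed <- function(base, a = 0L, b = 0L, c = 0L) {
  as.integer((as.numeric(base) %% 1e6 + 97561 * a + 1013 * b + 7 * c + 11) %%
               2147483647)
}

ellipse_mask <- function(n, cx, cy, a, b, theta = 0) {
  xs <- matrix(rep(seq_len(n), each = n), n)   # column coordinate
  ys <- matrix(rep(seq_len(n), times = n), n)  # row coordinate
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Sample per-subject thigh geometry
#'
#' Draws jittered ellipse/bone parameters for one subject; all slices of a
#' subject share this geometry. The geometry distribution does not depend
#' on the domain label, encoding the method's core assumption that the easy
#' and hard domains share one shape distribution.
#'
#' @param config a [PhantomConfig-class].
#' @param subjectSeed integer seed for this subject.
#' @return a list of geometry parameters understood by
#'   [generatePhantomSlice()].
#' @export
subjectGeometry <- function(config, subjectSeed) {
  set.seed(subjectSeed)
  n <- config@imageSize
  j <- config@geometryJitter
  u <- function(scale = 1) scale * stats::runif(1, -1, 1)
  one_thigh <- function(cx0) {
    cx <- cx0 + n * 0.03 * u()
    cy <- n * (0.5 + 0.03 * u())
    outerA <- n * (if (config@twoThighs) 0.22 else 0.40) * (1 + j * u())
    outerB <- n * 0.36 * (1 + j * u())
    theta <- stats::runif(1, -pi / 10, pi / 10)
    muscleA <- outerA * 0.72 * (1 + 0.4 * j * u())
    muscleB <- outerB * 0.70 * (1 + 0.4 * j * u())
    boneR <- n * 0.055 * (1 + j * u())
    # bone center offset, kept well inside the muscle ellipse
    phi <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.3)
    boneX <- cx + rad * muscleA * cos(phi)
    boneY <- cy + rad * muscleB * sin(phi)
    list(cx = cx, cy = cy, outerA = outerA, outerB = outerB, theta = theta,
         muscleA = muscleA, muscleB = muscleB,
         boneX = boneX, boneY = boneY, boneR = boneR)
  }
  if (config@twoThighs)
    list(thighs = list(one_thigh(n * 0.27), one_thigh(n * 0.73)))
  else
    list(thighs = list(one_thigh(n * 0.5)))
}

#' Generate one synthetic phantom slice
#'
#' Regions are concentric: the fat ring encloses the muscle compartment,
#' the bone disc sits inside the muscle, infiltration discs are placed only
#' where they fit entirely inside muscle, and the realized infiltrated
#' fraction stops within +/-0.05 of the configured target (or when no
#' further blob fits). Noise is added last; the image is clipped to
#' \[0, 1\]. Output is bit-reproducible given (config, geometry, seed).
#'
#' @param config a [PhantomConfig-class].
#' @param geometry per-subject geometry from [subjectGeometry()].
#' @param sliceSeed integer seed for blob placement and noise.
#' @param subjectId,sliceIndex identifiers stored on the slice.
#' @return a [PhantomSlice-class].
#' @examples
#' cfg <- phantomConfig(imageSize = 64, infiltrationFraction = 0.4,
#'                      noiseSd = 0)
#' sl <- generatePhantomSlice(cfg, subjectGeometry(cfg, 7L), 11L)
#' realizedInfiltrationFraction(sl)
#' @export
generatePhantomSlice <- function(config, geometry, sliceSeed,
                                 subjectId = "s1", sliceIndex = 1L) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  set.seed(sliceSeed)
  n <- config@imageSize
  tl <- config@tissueLevels

  outer <- matrix(FALSE, n, n)
  muscleEll <- matrix(FALSE, n, n)
  bone <- matrix(FALSE, n, n)
  for (th in geometry$thighs) {
    outer <- outer | ellipse_mask(n, th$cx, th$cy, th$outerA, th$outerB,
                                  th$theta)
    mEll <- ellipse_mask(n, th$cx, th$cy, th$muscleA, th$muscleB, th$theta)
    muscleEll <- muscleEll | mEll
    bone <- bone | (ellipse_mask(n, th$boneX, th$boneY, th$boneR, th$boneR) &
                      mEll)
  }
  fat <- outer & !muscleEll
  muscle <- muscleEll & !bone       # ground-truth muscle incl. infiltration
  if (!any(muscle)) stop("degenerate geometry: muscle region is empty")

  target <- config@infiltrationFraction
  muscleArea <- sum(muscle)
  infil <- matrix(FALSE, n, n)
  if (target > 0) {
    muscleIdx <- which(muscle)
    attempts <- 0L
    frac <- 0
    while (frac < target - 0.05 && attempts < 5000L) {
      attempts <- attempts + 1L
      ctr <- muscleIdx[sample.int(length(muscleIdx), 1L)]
      cy <- ((ctr - 1L) %% n) + 1L
      cx <- ((ctr - 1L) %/% n) + 1L
      r <- stats::runif(1, 1.5, 0.07 * n)
      blob <- ellipse_mask(n, cx, cy, r, r)
      if (any(blob & !muscle)) next            # must sit fully inside muscle
      cand <- infil | blob
      if (sum(cand) / muscleArea > target + 0.05) next
      infil <- cand
      frac <- sum(infil) / muscleArea
    }
  }

  img <- matrix(tl[["background"]], n, n)
  img[fat] <- tl[["subcutaneous_fat"]]
  img[muscle] <- tl[["muscle"]]
  img[bone] <- tl[["bone"]]
  img[infil] <- tl[["infiltration"]]
  if (config@noiseSd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config@noiseSd), n, n)
  img <- pmin(pmax(img, 0), 1)

  new("PhantomSlice",
      image = img,
      muscleMask = matrix(as.integer(muscle), n, n),
      fatMask = matrix(as.integer(fat), n, n),
      boneMask = matrix(as.integer(bone), n, n),
      infiltrationMask = matrix(as.integer(infil), n, n),
      realizedInfiltrationFraction = sum(infil) / muscleArea,
      subjectId = subjectId,
      sliceIndex = as.integer(sliceIndex))
}

#' Generate matched easy- and hard-domain phantom datasets
#'
#' Easy-domain slices carry (near) zero infiltration; hard-domain slices
#' draw their target infiltrated fraction uniformly from
#' `hardFractionRange`. Subject geometry is seeded by subject index alone —
#' not by domain — so the distribution of muscle shapes is identical across
#' domains while the intensity content differs, mirroring the statistical
#' assumption the translation approach rests on.
#'
#' @param nEasySubjects,nHardSubjects,slicesPerSubject counts (all >= 1).
#' @param config a [PhantomConfig-class]; its `infiltrationFraction` is
#'   overridden per domain as described.
#' @param hardFractionRange range the hard-domain infiltration targets are
#'   drawn from.
#' @return list with elements `easy` and `hard`, both
#'   [DomainDataset-class].
#' @examples
#' dd <- generateDomainDatasets(2, 2, 3, phantomConfig(seed = 5L))
#' length(dd$easy); domainLabel(dd$hard)
#' @export
generateDomainDatasets <- function(nEasySubjects, nHardSubjects,
                                   slicesPerSubject, config = phantomConfig(),
                                   hardFractionRange = c(0.2, 0.7)) {
  stopifnot(nEasySubjects >= 1, nHardSubjects >= 1, slicesPerSubject >= 1)
  s0 <- config@seed
  make_domain <- function(domain, nSub) {
    dcode <- if (domain == "easy") 1L else 2L
    slices <- list()
    for (i in seq_len(nSub)) {
      geom <- subjectGeometry(config, mix_seed(s0, 0L, i))  # domain-agnostic
      sid <- sprintf("%s_%02d", domain, i)
      for (k in seq_len(slicesPerSubject)) {
        cfg_ik <- config
        if (domain == "hard") {
          set.seed(mix_seed(s0, dcode, i, 1000L + k))
          cfg_ik@infiltrationFraction <-
            stats::runif(1, hardFractionRange[1], hardFractionRange[2])
        } else {
          cfg_ik@infiltrationFraction <- 0
        }
        slices[[length(slices) + 1L]] <-
          generatePhantomSlice(cfg_ik, geom, mix_seed(s0, dcode, i, k),
                               subjectId = sid, sliceIndex = k)
      }
    }
    new("DomainDataset", slices = slices, domainLabel = domain)
  }
  list(easy = make_domain("easy", nEasySubjects),
       hard = make_domain("hard", nHardSubjects))
}
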