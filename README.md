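# muscleTranSeg

Segmenting the whole muscle compartment — fatty infiltrations included — in
T1-weighted thigh MRI is easy on healthy scans and hard on dystrophic ones:
infiltrated muscle has the same gray value as subcutaneous fat, so no
intensity rule can separate them, yet the clinical fat fraction
(infiltrated / total muscle volume) depends on exactly that mask.

`muscleTranSeg` implements a translate-then-segment pipeline for this
problem. An unpaired cyclic translation model learns two mappings between
the *hard* domain H (visibly infiltrated slices) and the *easy* domain E
(healthy-looking slices): F : H → E and G : E → H, trained with patch
discriminators D_H, D_E and the combined generator objective

    L = w_d · L_adv + w_c · L_c + w_r · L_r + w_i · L_i

where L_c is the L1 cycle-consistency term, L_i the identity term, and

    L_r = E_h[ r(F(h) − h) ] + E_e[ r(e − G(e)) ],   r(x) = max(0, x)

is a one-sided **directional intensity penalty**: mapping hard to easy may
only darken voxels (healthy muscle is darker than infiltrated tissue), and
easy to hard may only brighten them. A configuration is written `G_{w_r,w_i}`
with w_d = w_c = 1; `G_{0,0}` is the plain cycle-GAN. A hard slice is then
translated with F, segmented with a standard method — unsupervised
three-class Gaussian-mixture clustering (GMM), probabilistic graph-cut (GC),
shape-prior graph-cut (SPGC), or a small adversarially trained
encoder-decoder network — and the mask is paired with the *original* slice
unchanged. Evaluation uses the Dice similarity coefficient,
DSC = 2|A∩B| / (|A|+|B|), with subject-wise cross-validated grid search for
the segmenters' hyper-parameters.

Clinical MRI for this task is not publicly distributable, so the package
ships a synthetic thigh-phantom generator (fat ring / muscle / bone /
infiltration blobs with per-tissue ground truth) whose easy and hard domains
share one shape distribution while differing in intensity content — the
statistical assumption the method rests on. The conv-net machinery
(generators, discriminators, U-Net, manual backpropagation, Adam) is
implemented in the package itself on top of a compact im2col/GEMM engine
(R + Rcpp/RcppArmadillo); graph-cuts solve exact min-cuts via igraph.

## Worked example

```r
library(muscleTranSeg)

# unpaired training domains: 100 easy + 100 hard 64x64 phantom slices
cfg   <- phantomConfig(imageSize = 64, noiseSd = 0.03, seed = 101)
train <- generateDomainDatasets(20, 20, 5, cfg)

# hard slices from 8 unseen subjects for evaluation
held <- generateDomainDatasets(2, 8, 3,
          phantomConfig(imageSize = 64, noiseSd = 0.03, seed = 202))$hard

# train the G_{0.5,1} configuration at the tiny preset (~5 min, 1 CPU)
model <- trainTranslation(train$easy, train$hard,
                          lossWeights(wr = 0.5, wi = 1),
                          trainConfig("tiny", seed = 7))

# unsupervised GMM segmentation, with and without translation
oi <- sapply(datasetSlices(held), function(s)
  dice(gmmSegment(sliceImage(s)), muscleMask(s)))
tr <- sapply(datasetSlices(held), function(s)
  dice(gmmSegment(translateToEasy(model, sliceImage(s))), muscleMask(s)))
median(oi); median(tr)
```

On this configuration the run prints

```
[1] 0.7827041   # median DSC, original hard slices (OI)
[1] 0.9656234   # median DSC, translated slices
```

i.e. translating before segmenting lifts the median Dice of the fully
unsupervised segmenter by ≈ 0.18: infiltrated regions, indistinguishable
from fat on the original image, are mapped back to muscle intensity and
recovered. On easy-domain inputs the same generator is a near-identity
(mean |F(e) − e| ≈ 0.004 on the [0,1] scale), as the identity loss intends.

A shell interface wraps the same functions
(`inst/cli/muscletranseg phantom|train-translate|translate|segment|evaluate|experiment`).

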