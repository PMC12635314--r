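# wcebleed

Detection and classification of gastrointestinal bleeding in wireless
capsule endoscopy (WCE)-style images, as one seedable R pipeline:

* **Preprocessing** — per-channel *clipped histogram equalization*
  (bins capped at a threshold `T`, excess `E` redistributed as `E/256`,
  CDF remap `I' = 255·C(I)`) followed by a *bilateral-filtered Retinex*
  decomposition `I = L·R`: the illumination `L` is a bilateral filtering
  of the image and the reflectance `R = I/(L+ε)` carries the
  illumination-invariant color and texture.
* **Enhancement** — Canny edges, Hough-space linking of broken edge
  segments (`ρ = x cosθ + y sinθ` accumulator), and Frangi vesselness
  `V = exp(−R_b²/2β²)·(1−exp(−S²/2c²))` on the Hessian eigenvalues
  (`R_b = |λ₂|/|λ₁|`, `S = √(λ₁²+λ₂²)`), blended as
  `α·(V·E) + (1−α)·E`.
* **Segmentation** — a compact encoder / atrous-convolution pyramid
  (dilation rates 1, 2, 4 plus a pooled branch) / decoder network with a
  per-pixel softmax, trained from scratch on CPU (Adam, lr 1e-3 with
  cosine decay, batch 16, weight decay 1e-4).
* **Classification** — a small residual feature extractor
  (`F_{L+1} = F_L + R_f(F_L)`) pooled to a 64-dimensional embedding,
  fused with a Gaussian naive Bayes classifier
  (`P(C_i|h) ∝ P(C_i)·∏_j P(h_j|C_i)`, all in the log domain) over six
  classes: Active bleeding, Coagulated blood, Esophagitis, Normal,
  Ulcerative colitis, Vascular lesion.
* **Metrics** — PSNR, SSIM, mean gradient magnitude, color fidelity;
  Dice and mean pixel accuracy; accuracy, macro sensitivity/specificity,
  one-vs-rest AUC, Cohen's kappa.

Real WCE data cannot ship with a package, so a **synthetic phantom
generator** produces seeded, labeled frames with ground-truth masks
(circular field of view, illumination falloff, mucosal texture, specular
highlights, sensor noise, class-specific lesion archetypes), and the whole
pipeline trains and evaluates end-to-end on them. The audience is image
analysis researchers who want a fully inspectable, dependency-light
reference implementation of this pipeline family, with every stage unit
tested against brute-force oracles.

## Worked example

```r
library(wcebleed)

# one synthetic frame with ground truth
item <- generate_phantom(phantom_spec("Active bleeding", seed = 7))
item
#> <wce phantom> 64x64  label=Active bleeding  lesion px=410

# preprocess and enhance
pre <- preprocess_image(item$image)
en  <- enhance_image(pre)
range(en$vesselness)
#> [1] 1.005016e-05 8.603313e-01

# the full study: synthesize a stratified dataset, train the segmenter
# and the fusion classifier, evaluate on held-out phantoms
report <- run_demo(out_dir = tempfile("wcedemo"), seed = 42)
report$segmentation$dice        # mean held-out foreground Dice
#> [1] 0.8291139
report$classification$accuracy  # held-out 6-class accuracy
#> [1] 0.9583333
```

`run_demo()` writes the dataset, predicted masks, preprocessed images, a
training log and `report.json` under `out_dir`. The report's Dice is the
per-image foreground Dice of the predicted masks averaged over all
held-out phantoms; accuracy, AUC and kappa come from the classifier
running on those same predicted masks. Reruns with the same seed are
bit-identical.

A thin command-line front end over the same functions lives at
`inst/cli/wcebleed.R`:

```sh
Rscript inst/cli/wcebleed.R synth --n-per-class 10 --size 64 --seed 1 --out data/
Rscript inst/cli/wcebleed.R preprocess --in frame.png --out frame_pre.png
Rscript inst/cli/wcebleed.R demo --out runs/demo --seed 42
```

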