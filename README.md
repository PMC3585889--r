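# kuseg — kidney ultrasound segmentation with NLTV, DRLSE and a PCA shape prior

Segmenting a kidney from B-mode ultrasound is hard for exactly one
reason: speckle. Multiplicative, spatially correlated noise erases and
invents boundary fragments, so purely local methods either stall inside
the organ or leak into the background. `kuseg` implements a three-stage
framework for this problem, aimed at image-analysis researchers and
method developers who need a fully inspectable, dependency-light R
implementation with a ground-truthed synthetic test bed:

1. **NLTV denoising.** Minimize the nonlocal total-variation energy
   `F(u) = Σ_x sqrt( Σ_y (u(y) − u(x))² w(x,y) ) + (λ/2) Σ_x (u(x) − u₀(x))²`
   on a patch-similarity weight graph
   `w(x,y) = exp(−d(x,y)/h²)`, flattening homogeneous tissue while the
   weakly-coupled boundary survives.
2. **DRLSE.** Evolve a level-set function under
   `∂φ/∂t = μ div((1 − 1/|∇φ|)∇φ) + λ δ_ε(φ) div(g∇φ/|∇φ|) + α g δ_ε(φ)`
   from a seed box: the first term keeps `φ` a signed distance function
   (no reinitialization, ever), the second attracts the zero contour to
   the edge map `g = 1/(1 + |∇(G_σ*I)|²)`, the third balloons it
   outward. Thresholding `φ < 0` gives the binary segmentation.
3. **Shape prior, applied once at the end.** A statistical shape space —
   PCA over signed distance functions of aligned training masks,
   `φ̂ = φ̄ + W_p·x_pca` — is fitted to the binary result by alternating
   gradient descent of the contour energy
   `F_shape = ∮ φ̂²(x_pca, h_xT(x)) δ_ε(φ) |∇φ| dx`
   over pose (similarity transform) and eigencoefficients. When a
   result's sensitivity, specificity and positive predictive value all
   fall under 0.90, the alignment model absorbs a corrected mask and
   rebuilds the space, so the shape prior grows richer over use.

Everything is testable without any external data: a synthetic module
generates bean-shaped kidney phantoms and correlated multiplicative
speckle with known ground truth.

## Worked example

```r
library(kuseg)

# a shape space from 20 synthetic training masks
train <- generate_training_set(20, seed = 7)
space <- shape_space_from_masks(train$masks)
space
#> shape_space: 20 training shapes on a 128x128 frame; 10 components covering 98.9% of variance

# one speckled test image with known truth
truth <- generate_phantom(phantom_spec(axes = c(36, 22), bend = 0.004,
                                       notch_depth = 0.2, seed = 41))
img <- render_ultrasound(truth, speckle_spec(sigma_s = 0.4, seed = 5))

res <- segment_image(img, space, pipeline_config(),
                     seed_mask = seed_from_truth(truth, 0.3),
                     ref_mask = truth,
                     roi_area = 0.85 * bbox_area(truth))
res$metrics
#> SN 0.9917  SP 0.9888  PPV 0.9388  Dice 0.9645
```

`SN` is the fraction of true organ pixels recovered, `PPV` the fraction
of reported pixels that are organ, `SP` the fraction of background kept
clean; the quality gate recommends absorbing a corrected mask when all
three fall under 0.90. The raw level-set stage before the shape prior,
`evaluate_segmentation(res$drlse_mask, truth)`, prints
`SN 0.9905  SP 0.9880  PPV 0.9343  Dice 0.9616` on this case — the
prior smooths the speckled boundary and nudges every metric up.

A command-line front end for shell use is installed at
`inst/cli/kuseg.R` (subcommands `denoise`, `drlse`, `build-shapes`,
`absorb`, `fit-shape`, `eval`, `synth`, `run`).

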