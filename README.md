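# rssm — sparse-smooth foreground estimation for neuronal microscopy images

Quantifying neuronal images — counting somas, tracing neurites,
reconstructing neurons — starts with separating the signal from a bright,
uneven background. Thresholds that work on one fMOST or light-sheet stack
fail on the next, because foreground intensity varies wildly across stacks
and can even fall below the background elsewhere in the volume. `rssm`
addresses this with a parameter-free-in-practice decomposition: an observed
image `Y` is split as

    Y = Is + B + noise

by minimising the convex objective

    ½‖Y − Is − B‖² + λ₁‖Is‖₁ + ½λ₂‖∇^(k0) Is‖² + ½λ₃‖∇^(k1) B‖²,
    Is ≥ 0, B ≥ 0

where `∇^(k)` is the k-th order forward-difference operator along both image
axes. The two priors — the foreground `Is` is sparse and moderately smooth
(order `k0 = 2`), the background `B` is smoother (order `k1 = 5`) — are
enough to pull apart neurites and haze with one fixed set of weights
(`λ₁ = 0.1, λ₂ = 0.1, λ₃ = 0.5`). The program is solved by proximal gradient
descent with closed-form safe step sizes (`1/8.2` for the foreground,
`1/901` for the background at the defaults), a hard floor threshold standing
in for the sparsity penalty in the original update, and an optional exact
soft-shrinkage mode that carries full descent guarantees. The package is
aimed at people who run tracing/localization tools (NeuroGPS-Tree, neuTube,
Open-Snake, …) on diverse stacks and want their defaults to just work on the
estimated foreground.

Included alongside the solver: slice-wise processing of 3D stacks, tiling of
arbitrarily large volumes into 512³ sub-stacks with sequential stitching, a
synthetic neurite-image generator for benchmarking, the two ablation
variants of the model (sparsity term deleted / smoothness term deleted), and
point-set evaluation metrics (precision, recall, F1 at a 6 μm match radius).

## Worked example

```r
library(rssm)

# one synthetic neurite image: 6x80 px rectangle, excess intensity 15 over a
# flat background of 200, 7x7 mean blur, uniform noise on [-2.5, 2.5]
spec <- synthetic_spec(delta = 15, seed = 7, n_images = 1)
sim  <- simulate_image(spec, 1)

fit <- rssm(sim$image)     # default parameters, hard-floor prox
fit
#> Sparse-smooth decomposition (none model)
#>   image      : 128 x 128
#>   slices     : 1, all converged (total 19 iterations)
#>   foreground : 784 nonzero pixels (4.8%), max 12.9
#>   background : mean 200
```

The fit converged in 19 iterations; the estimated foreground occupies 4.8%
of the pixels (the true rectangle plus its blur skirt — sparsity holding),
its peak (12.9) sits just under the blurred true excess of 15, and the
estimated background mean recovers the true level 200. How faithful is the
foreground along the neurite?

```r
mid <- spec$rect$rows[3]    # central row of the rectangle
pearson_correlation(fit$foreground[mid, ], sim$truth_foreground[mid, ])
#> [1] 0.9794
```

A profile correlation of 0.98 against the clean ground truth: the noise is
gone and the signal remains. Point-set evaluation works on detected vs
gold-standard coordinates (μm after voxel scaling, strict 6 μm radius):

```r
match_points(rbind(c(64, 30), c(64, 90), c(20, 20)),
             rbind(c(64, 31), c(64, 88), c(100, 100)), radius_um = 6)
#> Point matching: TP 2, FP 1, FN 1
#>   precision 0.6667, recall 0.6667, F1 0.6667
```

For 3D stacks pass an array (slices are decomposed independently); for
volumes that exceed memory, `plan_tiles()` + `rssm_tiled()` process 512³
sub-stacks in sequence. `benchmark_ablation()` reruns the synthetic
ablation study (full model vs sparsity/smoothness ablations across contrast
levels) and returns the mean profile correlations as a table.

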