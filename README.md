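# morphedge

Noise-robust morphological edge detection for 8-bit grayscale images, built
for MRI-like data where impulse ("salt and pepper") noise and low contrast
defeat derivative-based detectors. The package is aimed at image-analysis
researchers who need an edge operator that does not fire on noise, together
with the evaluation machinery (MSE / PSNR / SSIM, precision–recall against
ground truth) and a seeded synthetic phantom generator to benchmark it on.

## The method

For an image `g` and a flat structuring element `J` containing its anchor,
the morphological ordering chain

```
g ⊕ J  ≥  g ∗ J  ≥  g  ≥  g ∘ J  ≥  g ⊖ J
```

(dilation, closing, original, opening, erosion) makes six classical
gradients nonnegative, e.g. the full gradient `p3 = g⊕J − g⊖J`. These all
respond to impulse noise. The cascaded anti-noise pair prefilters before
differencing:

```
q1 = (g∗J)∘J − (g∗J)⊖J        q2 = (g∘J)⊕J − (g∘J)∗J
Q  = κ·max(q1,q2) + λ·min(q1,q2),   κ + λ = 1
```

`Q` is computed with eight one-sided directional elements (half-lines
N, NE, …, NW) and blended with image-driven weights derived from squared
gray differences in the 3×3 neighborhood (`v1..v8`, summing to 1). A scale
loop evaluates elements of size 3, 5, 7, 9, gates each scale on the PSNR of
an impulse-filtered rendering, and fuses the per-scale responses by their
pointwise mean (the multiscale operator `MuQ`). Full details and all design
decisions are in `vignettes/morphedge-methods.Rmd`.

## Worked example

```r
library(morphedge)

ph <- generate_phantom(phantom_spec(seed = 42))   # 128x128, 5% salt+pepper, sigma 5
quality_report(ph$noisy, ph$clean)
#>       mse psnr_paper psnr_standard      ssim
#> 1 1158.31   17.52655      17.49256 0.3714111

res <- adaptive_detect(ph$noisy, fusion_config(psnr_threshold = 25),
                       reference = ph$clean)
res$per_scale
#>   m scale     psnr
#> 1 1     3 30.45268          # gate passed at the first scale
res$stop_reason
#> [1] "threshold_met"

precision_at_recall(res$fused, ph$edge_truth, target = 0.9)
#> precision    recall
#>     0.888     0.902
```

The noisy phantom starts 17.5 dB from its clean reference; the adaptive
loop accepts the 3×3 scale (30.5 dB > 25 dB gate) and the fused edge map
recovers 90% of the true boundary pixels at 0.89 precision. The cascade is
the point: at the same matched recall on this phantom, the plain gradient
`p3` manages only 0.36 precision against 0.99 for `Q`, because `p3` fires
on every surviving impulse:

```r
se <- make_structuring_element(3, "isotropic")
precision_at_recall(combined_Q(ph$noisy, se),    ph$edge_truth, 0.9)["precision"]  # 0.990
precision_at_recall(gradient_p(ph$noisy, se, 3), ph$edge_truth, 0.9)["precision"]  # 0.361
```

The concordance utility reproduces a typical MRI-vs-surgery classification
check — 36 cases typed complete/partial/marginal (19/11/6 reference), two
complete cases read as partial:

```r
tab <- confusion_table(matrix(c(17, 2, 0,
                                 0, 11, 0,
                                 0,  0, 6), 3, 3, byrow = TRUE),
                       c("complete", "partial", "marginal"))
accuracy(tab)
#> [1] 94.44444
```

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/morphedge`:

```sh
morphedge detect scan.png --out results/ --kappa 0.5 --m-max 4 --psnr-threshold 30
morphedge simulate --seeds 50 --out sim/
morphedge evaluate processed.png reference.png --dialect paper
```

Exit codes: 0 success, 2 validation error, 3 I/O error. Outputs are PNG
edge maps, a JSON manifest (scales visited, weights, gate values, stop
reason), and CSV metric tables.

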