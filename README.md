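# iimt

Multilevel thresholding segmentation of 8-bit grayscale images — aimed at
axial brain MR slices, where background, skull, CSF, gray matter and white
matter occupy distinct intensity bands — built around an
**interval-iteration refinement of Otsu's criterion** with an
edge-preserving layer decomposition and a similarity-weighted label fusion
around it. It is written for image-analysis work that needs a fast,
fully deterministic, histogram-based segmenter with exact search guarantees
and built-in quality measures, rather than a trained model.

## The method

Otsu's multilevel criterion picks thresholds
`t_1 < … < t_K` maximizing the between-class variance

    σ_B²(t_1, …, t_K) = Σ_{i=1}^{K+1} ω_i (μ_i − μ_T)²

over the image histogram (class weights `ω_i`, class means `μ_i`, global
mean `μ_T`). `otsu_multilevel()` solves this exactly for any K by dynamic
programming over histogram prefix sums, with lexicographically smallest
tie-breaking.

Because the global criterion is biased toward high-variance classes, the
package refines each threshold locally (`iimt_thresholds()`): threshold
`T_i` is re-estimated by single-threshold Otsu restricted to the interval
between its two adjacent class means, the interval shrinks to the two
within-interval class means, and the cycle repeats until consecutive
thresholds differ by less than `δ` (default 0.01 — with integer thresholds,
"unchanged"). Intervals are nested, so the iteration terminates.

The full pipeline (`segment_image()`) additionally:

1. splits the image into a piecewise-smooth **base layer** and a residual
   detail layer by minimizing a hybrid L1–L0 gradient objective
   (`hybrid_l1_l0_decompose()`, ADMM with an exact FFT quadratic step;
   `base + detail` reconstructs the input bit-for-bit);
2. thresholds the original image and the base layer independently;
3. **fuses** the two label maps (`fuse_labels()`): agreeing pixels keep
   their label, disagreeing ones are re-voted by a spatial-plus-intensity
   similarity kernel over their agreeing neighbors within radius `r`.

Quality is measured by the uniformity score `U`, misclassification error,
Hausdorff distance and Jaccard index (`segmentation_metrics()`), and a
seeded phantom generator (`generate_phantom()`, `add_gaussian_noise()`)
provides brain-like ground-truth fixtures so everything is testable without
external data.

## Worked example

```r
library(iimt)

# a 5-class brain-like phantom with additive Gaussian noise (σ ≈ 8 gray levels)
ph    <- generate_phantom(phantom_spec(96, 96, c(15, 71, 128, 184, 240), seed = 1))
noisy <- add_gaussian_noise(ph$image, 0.001, seed = 2)

res <- segment_image(noisy, pipeline_config(K = 4), truth = ph$labels)
print(res)
#> iimt_segmentation: 96 x 96 pixels, K = 4
#>   thresholds (original): 42, 99, 155, 212 (2 iterations)
#>   thresholds (base)    : 43, 98, 153, 209 (4 iterations)
#> U  = 0.9922
#> ME = 0.0002   H = 2.2868   J = 0.9988
```

The two threshold sets are the interval-iteration solutions on the noisy
image and on its denoised base layer; both land inside the inter-class
gaps, so the fused map recovers the ground truth up to a 0.02%
misclassification error confined to region boundaries (Jaccard 0.999,
class-averaged Hausdorff ≈ 2.3 px), with uniformity 0.992 on the noisy
input. Dropping `truth` skips the supervised metrics; `decompose = FALSE,
fuse = FALSE` gives plain interval-iteration thresholding, and additionally
setting `max_iterations = 1` gives classic global Otsu.

A command-line front end mirrors the library:

```sh
Rscript inst/cli/iimt.R phantom --height 128 --width 128 \
    --means 20,90,160,230 --seed 7 --out ph.png --labels truth.png
Rscript inst/cli/iimt.R segment ph.png --k 3 --truth truth.png \
    --out seg.png --report report.json
```

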