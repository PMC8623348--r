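---
title: "Interval-iteration multilevel thresholding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-iteration multilevel thresholding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iimt)
```

## The segmentation problem

An axial brain MR slice is, to a first approximation, a piecewise-constant
gray image: background, skull, cerebrospinal fluid, gray matter and white
matter occupy distinct intensity bands. Multilevel thresholding segments
such an image by picking $K$ gray-level cut points $t_1 < \dots < t_K$ from
its 256-bin histogram, which partition pixels into $K+1$ classes (class $i$
holds the pixels with $t_{i-1} < g \le t_i$, $t_0 = -1$, $t_{K+1} = 255$).

Otsu's criterion chooses the thresholds maximizing the between-class
variance

$$\sigma_B^2(t_1,\dots,t_K) \;=\; \sum_{i=1}^{K+1}\omega_i(\mu_i-\mu_T)^2,$$

with class probabilities $\omega_i$, class means $\mu_i$ and the global
mean $\mu_T$, all computed from the histogram probabilities
$P_j = n_j/(MN)$. `otsu_multilevel()` solves this *exactly* by dynamic
programming over prefix sums of $P_j$ and $jP_j$: each class contributes a
score $S(a,b) = (\sum_{j=a}^b jP_j)^2 / \sum_{j=a}^b P_j$, and maximizing
$\sum_i S$ is equivalent to maximizing $\sigma_B^2$ because the two differ
by the constant $\mu_T^2$. Ties are broken by the lexicographically
smallest tuple (the reconstruction takes the first maximizer at every
stage), and candidate thresholds are capped at the top occupied bin plus
$K$ — a provably lossless restriction, since larger thresholds only delimit
empty classes and can be remapped downward without changing the partition.

A global Otsu search weighs every class against the global mean, which
biases thresholds toward classes with large variance. The
interval-iteration refinement (`iimt_thresholds()`) counters this by
re-solving locally: after the global search, each threshold $T_i$ is
assigned the interval $[\mu_i, \mu_{i+1}]$ between its two adjacent class
means, single-threshold Otsu is re-run on the histogram restricted to that
interval, the interval shrinks to the two within-interval class means, and
the cycle repeats until $|T_{s,i} - T_{s-1,i}| < \delta$. Because
thresholds are integers and the published $\delta = 0.01 < 1$, convergence
means "threshold unchanged between consecutive sweeps". Restricted class
means always lie inside the interval that produced them, so the intervals
are nested and widths are non-increasing; together with the iteration cap
this guarantees termination.

Two details are worth making explicit:

* **Per-track independence.** After initialization each threshold refines
  inside its own interval with no cross-talk; the narrative of classes
  $C_1, C_{K+1}$ growing every iteration is bookkeeping — the final label
  map depends only on the final thresholds under the boundary convention,
  so `apply_thresholds()` rasterizes once at the end.
* **What the stopping rule guarantees.** At convergence, the Otsu step run
  on the interval that *produced* the final threshold reproduces it; the
  package records that interval (`src_lower`/`src_upper` in the returned
  state) and the test suite re-checks the property. The stronger reading —
  stability on the *updated* interval — is false for the method as
  specified: probing random histograms shows roughly 8% of thresholds would
  still drift if refinement continued, because the rule stops on threshold
  change, not interval change.

`K = 1` is supported even though the iteration is usually presented for
$K \ge 2$: the published experiments include single-threshold results, and
the first iteration simply yields one interval.

## Hybrid L1–L0 layer decomposition

Noise corrupts histogram valleys, so the pipeline first extracts a
piecewise-smooth *base layer* $I^B$ and segments it alongside the original.
The decomposition minimizes, on the $[0,1]$ intensity scale,

$$\sum_{i,j}\big(I^D_{i,j}\big)^2
  + \lambda_1\!\!\sum_{k\in\{H,V\}}\!\big|\partial_k I^B_{i,j}\big|
  + \lambda_2\!\!\sum_{k\in\{H,V\}}\!F\big(\partial_k I^D_{i,j}\big),
  \qquad I^D = I - I^B,$$

where $F$ indicates a nonzero gradient. The L1 term flattens weak texture
and noise in the base while keeping strong edges; the L0 term forces the
detail layer's edges to be sparse. Defaults are $\lambda_1 = 1$,
$\lambda_2 = 0.1\lambda_1$, 15 solver sweeps.

The solver is an ADMM on the augmented Lagrangian with auxiliary gradient
variables: $c_1$ receives a soft-threshold (L1 proximal) step, $c_2$ a
hard-threshold (L0 proximal) step with keep-threshold
$\kappa = \sqrt{2\lambda_2/\rho}$, the base layer solves its quadratic
subproblem exactly in the frequency domain (circular boundary, so the
gradient's normal operator diagonalizes under the FFT), and the duals
ascend on the constraint residuals. Eliminating $d = i - b$ in the
quadratic step keeps reconstruction exact by construction:
`base + detail == image` holds bit-for-bit on the rounded 8-bit output.

Numerical choices:

* **Intensity scale.** The decomposition runs on $[0,1]$; the weights above
  are only meaningful on that scale (the noise model $N(0, 0.001)$ likewise
  refers to unit intensities). The returned base is rounded to 8 bits for
  downstream thresholding.
* **Penalty parameter.** $\rho = 1$, fixed across sweeps and configurable.
* **Best-iterate safeguard.** The L0 term makes the objective nonconvex and
  the iteration nonmonotone. The solver therefore scores every iterate —
  including the $b = i$ initialization — with the model objective, counting
  gradient entries below $\kappa$ as zero ($\kappa$ is the model's own edge
  resolution: any smaller entry is cheaper to zero than to keep), and
  returns the best. This guarantees the decomposition never hands back a
  base layer worse than the input itself under the model's merit, and makes
  degenerate configurations exact: $\lambda_1 = \lambda_2 = 0$ returns the
  identity decomposition, as does a clean two-level step image, whose
  optimum *is* $b = i$.
* **Boundary handling.** Circular. The wrap-around column/row of the
  gradient is a modeling convenience that buys an exact $O(MN\log MN)$
  quadratic solve; on brain slices the border is background on all sides,
  so the wrap seam carries no signal.
* Divergence (non-finite iterates) aborts with the offending sweep index;
  with the FFT solve and finite inputs it is not reachable in practice.

## Segmentation fusion

The pipeline segments both the original image (map A) and its base layer
(map B) and merges them. Pixels where the maps agree keep their label;
each *controversial* pixel $p$ is re-voted between its two candidate
labels $l_a = A(p)$, $l_b = B(p)$ by comparing similarity sums over the
agreeing neighbors within radius $r$:

$$SIM(p,q) = \exp\!\left(-\frac{Dis(p,q)^2}{2\alpha^2}
  -\frac{|I(p)-I(q)|^2}{2\beta^2}\right),$$

with $l_a$ winning only on a strictly greater sum — ties and empty
neighborhoods fall to $l_b$, reading the "otherwise" branch literally.
Defaults $r = 12$ pixels, $\alpha = \beta = 1$ ($\alpha$ in pixels, $\beta$
in gray levels; with $\beta = 1$ the intensity factor decays within a
couple of gray levels, so the vote is dominated by neighbors whose
intensity matches the contested pixel almost exactly — appropriate for
piecewise-constant tissue bands). Design choices: the neighborhood is a
Euclidean disc ($Dis \le r$, center excluded, clipped at borders;
configurable to a square window), and only *uncontested* neighbors vote,
since controversial labels are undefined at voting time and letting them
vote would make the result depend on scan order. Label correspondence
between the maps is by construction: both come from threshold sets with the
same $K$, so label $k$ means "$k$-th darkest class" in both.

## Evaluation measures

* **Uniformity** $U = 1 - 2K\sum_j\sum_{i\in S_j}(I_i - \overline{S_j})^2
  / \big(MN(I_{max}-I_{min})^2\big)$: the squared dynamic range keeps $U$
  dimensionless and in $[0,1]$; a first-power variant is available via
  `squared_range = FALSE` for comparability with sources that print it that
  way. A constant image is defined to have $U = 1$.
* **Misclassification error, Hausdorff distance, Jaccard index** are binary
  measures; for multilevel maps the package reports the unweighted mean of
  one-vs-rest scores over classes (background optionally excluded). This
  aggregation is a declared convention, not a reproduction claim. The
  Hausdorff distance operates on region pixel sets as given and is computed
  through an exact Euclidean distance transform; a class empty in one map
  is skipped in the aggregate with a warning, and a class empty in both
  maps scores $J = 1$ and $H = 0$.

One property of these measures deserves emphasis, because it bounds what
any pipeline can achieve: with the same image and the same class count, the
*exact* multilevel Otsu segmentation globally maximizes $U$. Minimizing
within-class sum of squares over scalar gray values admits an optimal
partition whose classes are intervals of the gray axis (the 1-D $k$-means
contiguity property), and every interval partition is representable by
integer thresholds — which the exact search enumerates. Decomposition and
fusion can therefore *tie* plain Otsu's uniformity (and do, whenever the
phantom's class structure is clean enough that all routes land in the same
histogram gaps) but cannot exceed it; their value shows up instead in the
spatial coherence of the label map (isolated-speckle removal) and in
supervised measures against ground truth. Published comparisons in which a
fused method strictly beats "Otsu" on $U$ are only consistent with an
approximate multilevel Otsu implementation.

## The synthetic phantom

`generate_phantom()` builds brain-like piecewise-constant rasters: nested
concentric ellipses (or rectangles) standing in for background, skull-,
CSF-, GM- and WM-style bands, with strictly increasing class means,
equal-area band spacing, and a guarantee that every class holds at least 1%
of the pixels. Within-class jitter (uniform, bounded below half the
smallest mean gap so class ranges stay disjoint) and the Gaussian noise
model (variance on the $[0,1]$ scale, then rescaled, clipped to $[0,255]$
and rounded — clipping before rounding) are both seeded explicitly; no
hidden global RNG state is consumed.

The phantoms emulate exactly the features the thresholding pipeline relies
on: well-separated intensity bands, closed-curve region topology, additive
sensor noise. They deliberately do *not* model bias fields, partial-volume
averaging at tissue interfaces, Rician noise statistics, or anatomical
shape variability. Passing the phantom suite therefore demonstrates the
algorithmic contracts (exact search, convergent refinement, exact
reconstruction, vote correctness, perfect recovery when gaps exceed the
noise), not clinical segmentation accuracy on real MR data.

Default validation conditions used by the test suite and the acceptance
script: class means evenly spaced from 15 to 240 (gaps of at least 45 gray
levels down to $K = 5$, comfortably above the 20-level separation the
recovery contracts assume), 96×96 rasters for pipeline-level checks and
48–64 pixel rasters for fusion/decomposition fixtures, noise variance
0.001, ten noise seeds for the uniformity comparison, and a corpus of 1000
random histograms with 16–64 occupied bins for the search/refinement
properties. The histogram corpus confines its support to gray levels 0–95
so that the independent exhaustive-enumeration oracle (all
$\binom{\sim 99}{3}$ triples) stays tractable; the dynamic-programming
search under test runs on the full range regardless.

## Known limitations

* Strictly 2-D, single-channel, 8-bit. Volumes and multi-contrast inputs
  are out of scope.
* The fusion vote is $O(|controversial| \cdot r^2)$; with heavily
  disagreeing maps and large radii it dominates runtime.
* The ADMM is a fixed-sweep local solver for a nonconvex objective: it
  carries no global-optimality guarantee, only the best-iterate guarantee
  described above.
* Entropy-based criteria, 2-D histogram variants, and fusing more than two
  candidate maps are not implemented.
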