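---
title: "Methods: geometric-image synthesis of registered 3D faces and bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric-image synthesis of registered 3D faces and bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shapesynth)
```

## The problem

Statistical shape models of the human face and body work on *registered*
meshes: every scan is re-parametrized onto a common template so that vertex
$i$ marks the same anatomical location on every subject. Once shapes are in
correspondence, a population is a cloud of points in $\mathbb{R}^{3N}$ and
synthesis means sampling new, plausible points from it — for example to
replace a privacy-sensitive scan collection with a statistically equivalent
synthetic one.

The classical route is a linear PCA shape model: stack each scan into a
$3N$-vector, keep $k$ principal components, and sample scores independently.
Its known weakness is that the scores of real populations are *not*
independent — shapes concentrate on a curved manifold — so independently
resampled scores produce combinations that no real subject exhibits.

`shapesynth` implements an alternative pipeline: registered meshes are
converted to 2D **geometric images** (pixel channels store xyz
coordinates), a two-level vector-quantized autoencoder learns discrete
latent code maps over those images, an autoregressive prior over the codes
is sampled (top level first, bottom level conditioned on it), and sampled
images are mapped back to 3D. Synthetic populations are compared against a
held-out test set and the PCA baseline with the field's *diversity* and
*specificity* metrics.

## Shape distance, diversity, specificity

All metrics build on the weighted RMSE between corresponding vertices,

$$ d(V^1, V^2) = \left( \frac{\sum_i w_i\,\lVert v_i^1 - v_i^2
\rVert_2^2}{\sum_i w_i} \right)^{1/2}, $$

computed after rigidly aligning one scan onto the other (weighted Kabsch:
SVD of the weighted cross-covariance, sign-corrected to exclude
reflections; scale is deliberately *not* estimated, since similarity
alignment would deflate the metrics). Weights default to uniform;
per-template weights can be supplied.

* **Diversity** is $d$ for a random pair drawn from a set — its empirical
  distribution over e.g. 250 pairs describes the spread of a population.
* **Specificity** of a synthetic scan is its minimal $d$ to any training
  scan — zero means a copy, large values mean implausible shapes. Its
  distribution over e.g. 250 samples describes how "real" a synthetic set
  stays.

`diversity_distribution()` draws pairs without replacement (at $n = 250$
this is indistinguishable from i.i.d. pairs and avoids duplicate points);
`compare_distributions()` quantifies closeness with a two-sample
Kolmogorov–Smirnov test. The `align` flag defaults to `TRUE`; for
co-registered synthetic populations that share an exact frame it can be
disabled for speed.

## 3D to 2D and back

**Faces.** The face template is a regular `grid_h x grid_w` vertex grid, so
the conversion is a bijection: pixel $(r, c)$ stores the xyz of vertex
`vertex_index_of[r, c]`, and `image_to_face()` inverts it exactly. Each
pixel/channel is then normalized to $[0, 1]$ by its min/max over the
training images (`fit_ranges()`); the ranges are kept to denormalize
synthetic images. Degenerate pixels (`max == min`, e.g. the fixed x, y
channels of a pure height-field template) normalize to 0 and denormalize
back to their stored minimum; out-of-range synthetic values are clamped, so
reconstructed geometry is bounded by the training extremes. Mirror
augmentation negates x and reverses grid columns — an involution that keeps
template correspondence — and normalization ranges are fitted *after*
augmentation. Training-set images never trigger clamping by construction.

**Bodies.** A closed body cannot be unwrapped into one grid without large
distortion, so the package uses a non-bijective multiview representation:
three orthographic views (front along $-y$, back along $+y$, bottom along
$+z$; z up, y back-to-front, x subject's left, mm units). `build_atlas()`
rasterizes the *mean template* once: each pixel center is assigned the
front-most covering triangle and its barycentric weights (depth ties within
1e-6 mm break toward the lower triangle index; pixel centers sit at
half-integer offsets inside a world window fitted to the template with a 5%
margin). Rendering any registered scan through the atlas is then *exactly
linear* in the scan's vertices — pixel values are fixed barycentric
combinations — which is what makes the quadratic inverse problem below
exact. The three views are kept as three 3-channel canvases and packed
channel-wise into one H×W×9 tensor for the network (horizontal packing
would put seams inside one canvas).

The assignment matrix is exposed as the sparse registration matrix $G$
(one row per foreground pixel, three nonzeros summing to 1), and
`visibility_report()` flags vertices whose column of $G$ is empty. With the
default three views on the synthetic bodies, essentially all vertices are
visible; a single view leaves the far side unobserved.

**Inverse.** Given observed pixel positions $P$, vertices are recovered by
the closed-form minimizer of

$$ \lVert G V - P \rVert^2 + \alpha\, \lVert L V - L V_0 \rVert^2 , $$

where $L$ is the uniform (umbrella) mesh Laplacian — row $i$ is $e_i$ minus
the mean of its edge neighbours, a topology-only operator that vanishes on
constant fields — $V_0$ is the mean template, and $\alpha = 0.001$ for mm
units. The SPD normal equations $(G^\top G + \alpha L^\top L)V = G^\top P +
\alpha L^\top L V_0$ are solved by sparse Cholesky, one factorization for
the three coordinates. Unobserved vertices are filled smoothly by the
Laplacian term; a connected component with *no* observed vertex has a free
translation, so such components are softly anchored to $V_0$ (an entirely
unobserved mesh reconstructs exactly as $V_0$), and $\alpha = 0$ with
unobserved components is an error naming them. The uniform Laplacian was
chosen over cotangent weights because it is scan-independent and standard
for regularization; the render→solve round trip on 20 synthetic bodies
(2306 vertices, 256×256 views) has a mean vertex error of ~0.0014 mm,
comfortably within the 0.14 mm the method is expected to deliver.

## The synthetic populations

Real head/body scan collections are licensed, so the package ships seeded
generators whose outputs stand in for them. They emulate the properties the
pipeline needs — full correspondence, smooth low-rank shape variation,
human scale — and nothing else; passing tests on them says the *machinery*
is correct, not that it matches any real population's statistics
(anatomical realism, scanner noise, pose variation and demographic
structure are all absent).

**Faces** (`make_face_population()`) are smooth height fields on a fixed
grid spanning ≈160×200 mm: a bilaterally symmetric base profile plus $k$
smooth deformation modes (one deliberately asymmetric so mirroring is
detectable). The mode stack is orthonormalized to unit RMS and projected
off the rigid-motion tangent space of the height field, so one mm of factor
is one mm RMS of displacement and rigid alignment cannot absorb shape
variance. Latent factors start i.i.d. Gaussian (`factor_sd`, default 3 mm)
and pass through an *energy-regulation* nonlinearity: each factor vector is
rescaled to the shell of radius $\sqrt{k}\,\sigma$ with a lognormal jitter
(sd 0.04). Marginal factor variances stay at $\sigma^2$, but the joint
distribution lives on a curved shell — total deformation magnitude is
tightly regulated while its direction varies freely. This is the package's
concrete embodiment of "not every combination of PCA scores is a natural
shape": PCA recovers the modes and the score marginals perfectly, yet
independent eCDF resampling leaves the shell, which is exactly what the
diversity/specificity comparison detects (PCA samples show a wider
diversity IQR and higher median specificity than a matched test set). The
default $k = 6$ keeps that contrast strong and stable across seeds.

**Bodies** (`make_body_population()`) are watertight genus-0 tubes: `n_z`
rings of `n_theta` vertices whose polar radius field is a smooth p-norm
union (p = 10) of primitive lobes — torso/neck/head ellipses, two
arms-down circles, two leg circles joined by a thin bridge that keeps every
cross-section star-shaped — capped by pole vertices at the soles and
crown. The base body stands exactly 1700 mm. Four factors (sd 50 mm)
modulate stature, girth, arm and leg thickness; girth couples nonlinearly
with stature as $(h/1700)^{0.4}$, so bodies are also not an exact linear
family. Bodies are generated arms-down, so no pose normalization is
needed. The default resolution 48 gives 2306 vertices — enough for the
multiview round trip to be meaningful while keeping a reconstruction
problem that factors in milliseconds.

`split_dataset()` assigns whole subjects to train/validation/test
(largest-remainder rounding of the requested fractions, default
90%/5%/5%), so augmented copies can never leak across splits.

## The VQ model and its prior

The autoencoder follows the two-level vector-quantization recipe: an
encoder produces a bottom latent map at 1/4 and a top map at 1/8 of the
input resolution; each latent vector is replaced by its nearest of $K$
codebook prototypes (ties to the lowest index); the decoder sees codebook
vectors only. Gradients pass the quantizer by the straight-through
estimator; a commitment cost of 0.25 keeps encoder outputs near their
codes; codebooks are learned with exponential moving averages (decay 0.99,
Laplace-smoothed counts, initialized from encoder outputs of the first
batch so usage starts healthy). The bottom quantizer input and the decoder
are conditioned on the decoded top level, giving the coarse/fine hierarchy.

This is a compact CPU implementation: the convolutional blocks of the
full-scale recipe are realized as per-patch affine/ReLU maps (4×4 pixel
patches at the bottom, 2×2 feature blocks at the top) trained with Adam.
That choice keeps the whole train/sample loop in plain matrix algebra,
deterministic under a seed, and fast enough that the test suite trains
models in seconds. The full-scale setting (256×256 input, K = 512, D = 2,
batch 32, 420 epochs) is expressible via `full_scale_config()` but is a
GPU-scale undertaking; desk-scale defaults are 64×64 inputs with K = 64.
Grid searches at full scale found K = 512 with a small code dimension
D = 2 best, which is why D defaults to 2 here as well.

The latent prior is a causal autoregressive model in raster order: code
$t$ is predicted from codes before $t$ through a masked context kernel
(offsets up to 2 rows above / 2 columns around), a learned position
embedding, and a strictly causal single-head self-attention block; the
bottom prior is additionally conditioned on the (nearest-neighbour
upsampled) top map. Training maximizes per-code likelihood and reports
validation accuracy (fraction of codes whose argmax prediction is
correct). Sampling is ancestral with a temperature on the logits:
temperature → 0 degenerates to argmax (a memorized dataset is reproduced
exactly), higher temperatures raise per-position entropy and hence sample
diversity. At desk scale the prior's accuracies are those of a toy model —
the full-scale published accuracies require the real data and GPU budgets
and are out of scope here.

## Failure detection

Generated geometric images must place background exactly where the
template has background. `detect_failed_sample()` marks as background
every pixel whose channels all lie within `eps` of the background constant
(0 in normalized space; `eps` defaults to 1/255, the 8-bit quantum) and
compares that mask with the template background by IoU; samples below
`iou_threshold` (default 0.95) are flagged, and `generate_shapes()` reports
the flags rather than dropping samples. Two caveats: for the bijective face
template there is no background, so the check is vacuous there (IoU 1);
and at desk scale the compact decoder does not reproduce backgrounds to
within 1/255, so toy body runs flag most samples — the detector's
correctness is pinned by exact unit cases, and the demo reports the IoU
distribution honestly.

## Numerical choices and degenerate inputs

* Quantizer ties break to the lowest codebook index; rasterizer depth ties
  (within 1e-6 mm) to the lowest triangle index — both deterministic.
* Degenerate projected triangles (area below 1e-12 px²) are skipped.
* `max == min` normalization pixels map to 0 (backgrounds stay dark).
* Isolated vertices get zero Laplacian rows plus a warning.
* Collinear vertex sets make rigid alignment abort (the rotation is not
  identifiable).
* All stochastic entry points (`population_spec`, training configs,
  samplers, `split_dataset`, pair draws) take explicit integer seeds and
  restore the caller's RNG state.

## Problem sizes used by the checks

The test suite and the acceptance script run at sizes chosen so the full
battery completes in minutes on one CPU while still exercising every code
path at meaningful scale: bodies at resolution 48 (2306 vertices) with
256×256 views for the round-trip figure; faces at 16–64 px grids for the
VQ stack; 320-subject populations with 250 training / 60 test shapes and
250 samples for the metric orderings; 2000 draws for the eCDF marginal
tests. These are the package's documented study conditions; larger runs
only sharpen the same comparisons.

## Known limitations

* The autoencoder/prior are deliberately compact; at desk scale their
  reconstructions are coarse (normalized MSE ~1e-2 on toy bodies) and
  sampled backgrounds are soft, so failure rates on toy body runs are
  high. The architecture is the two-level VQ hierarchy, not a replica of
  the full-scale convolutional stacks.
* Synthetic populations are smooth and low-rank by design; none of the
  messiness of real registered scans (registration error, missing data,
  asymmetric noise) is modelled.
* The uniform Laplacian ignores triangle shape; cotangent weights could
  shift the round-trip figure slightly.
* Vertex weights for the metrics default to uniform; the distributions'
  shapes depend on that choice.
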