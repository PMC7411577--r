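---
title: "Quantifying vascular disorder in CE-NBI images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular disorder in CE-NBI images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenbi)
```

# Scope and model

Contact endoscopy with narrow-band illumination shows the sub-epithelial
vessels of the vocal folds as dark curvilinear structures on bright mucosa.
Benign lesions tend to present elongated, low-curvature vessels running
along the fold (longitudinal changes, LVC); papillomatosis and
(pre)malignant lesions grow perpendicular vessels that project into the
image plane as hooks, loops and dots (perpendicular changes, PVC). The
package turns this qualitative distinction into a fixed-length geometric
descriptor of *vessel disorder* and trains standard supervised classifiers
on it. This vignette records the models, every tunable parameter with its
default and rationale, the synthetic data model, the numerical choices, and
the known limitations.

# Vessel enhancement

## Scale-space Hessian

At scale $\sigma$ the second derivatives of the image are taken by
convolution with sampled Gaussian-derivative kernels and multiplied by
$\sigma^2$ ($\gamma$-normalization with $\gamma = 2$, the standard choice
for line-like structures, making responses comparable across scales).
Boundaries are handled by symmetric reflection. Two numerical details
matter:

* kernels are truncated at $4\sigma$; at tighter truncations the sampled
  second-derivative kernel loses up to 8 % of its response to a quadratic
  test pattern;
* the sampled kernels are calibrated: the second-derivative kernel is
  forced to zero DC response and unit response to $t^2/2$, the
  first-derivative kernel to unit response to $t$. After calibration a
  constant image yields exactly zero eigenvalues and
  $f(r,c) = r^2/2$ yields $\lambda_2 = \sigma^2$ exactly, which the test
  suite asserts.

The per-pixel symmetric $2\times2$ eigensystem is solved in closed form;
eigenvalues are reported in signed order $\lambda_1 \le \lambda_2$.

## Tubularity response

Inside a dark ridge the cross-sectional second derivative is positive, so
the driving eigenvalue for the default dark-vessel polarity is
$x = \lambda_2$ (for bright structures, $x = -\lambda_1$; the two are
images of each other under intensity inversion). Per scale, the second
eigenvalue is regularized with the uniformity parameter $\tau \in (0,1]$:
$\lambda_\rho = x$ where $x > \tau \max x$, $\lambda_\rho = \tau \max x$
where $0 < x \le \tau\max x$, and $0$ otherwise. The response is

$$
V \;=\;
\begin{cases}
0 & x \le 0 \text{ or } \lambda_\rho \le 0,\\[2pt]
1 & x \ge \lambda_\rho/2 > 0,\\[2pt]
x^2\,(\lambda_\rho - x)\,\bigl(\tfrac{3}{x + \lambda_\rho}\bigr)^3 & \text{otherwise,}
\end{cases}
$$

clamped to $[0,1]$ and fused over scales by a per-pixel maximum. With the
default $\tau = 1$, $\lambda_\rho$ is the per-image global maximum of $x$
wherever $x > 0$, which makes the response *ratio-free*: it depends on
$x / \max x$, not on absolute contrast. Two consequences shape the rest of
the pipeline. First, the response saturates at 1 along well-contrasted
centerlines. Second, on an image without vessels the normalization
amplifies whatever weak structure is present — the response is only
meaningful when true vessels dominate the image maximum. A floor of
$10^{-8}$ on $\max x$ keeps numerically flat images at exactly zero.

Default scales are $\sigma \in \{0.5, 1, 1.5, 2, 2.5\}$ in pixel units
(`pixel_spacing = 1`); a physical pixel spacing can be supplied, in which
case scales are interpreted in physical units and divided by it.

# Segmentation and centerline extraction

* **Hysteresis binarization** (`low = 0.05`, `high = 0.25`): pixels at or
  above the high threshold seed the mask; weaker pixels survive only if
  8-connected to a seed. Given the response function, the high threshold
  corresponds to structures at roughly 10 % of the image-maximum
  eigenvalue, the low threshold to roughly 4.5 %.
* **Cleaning** (`min_object_px = 30`): 8-connected components smaller
  than 30 px are noise at the default rendering scale; interior background
  holes of at most 4 px are filled.
* **Thinning**: Guo–Hall two-subiteration thinning, chosen over
  Zhang–Suen because it erodes line ends less (a $3\times50$ bar keeps
  48 of 50 midline pixels versus 47) and leaves fewer staircase artifacts.
* **Skeleton canonicalization**: thinning output still contains redundant
  staircase pixels (a pixel whose only two neighbors are mutually
  adjacent) and short spurs caused by mask-boundary wobble. Redundant
  pixels are removed, then spurs shorter than `min_segment_len` hanging
  off branch points are pruned; the two passes iterate to a fixpoint.
  Without this cleanup, every spur manufactures a branch point and the
  centerline of a 100 px vessel fragments into ~12 px pieces.
* **Tracing**: branch points are skeleton pixels with more than two
  skeleton neighbors after canonicalization; segments are maximal
  branch-free 8-connected paths, ordered from an endpoint (from the
  lexicographically smallest pixel for isolated loops), deterministic by
  construction. Branch pixels belong to no segment, so segments stop one
  pixel short of junctions and junction pixels are never double-counted.
* **Smoothing/resampling**: coordinates are smoothed with a centered
  moving average (`smooth_window = 5` points; the window shrinks
  symmetrically near the ends so endpoints are preserved exactly) and
  resampled at uniform `resample_spacing = 1` px arc length by linear
  interpolation. Segments shorter than the window are flagged and left
  unsmoothed. `min_segment_len = 10` px: below that, finite-difference
  curvature is dominated by discretization noise.

# The 24-feature disorder descriptor

Tangent angles come from central differences of the resampled coordinates,
unwrapped so consecutive samples differ by less than $\pi$; signed
curvature is $\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$ by central
differences. Per segment, six descriptors:

| descriptor | definition | family |
|---|---|---|
| `dir_var` | $1 - \lVert \mathrm{mean}\, e^{2i\theta} \rVert$ | direction consistency |
| `turn_rate` | $\sum \lvert \Delta\theta \rvert / L$ (rad/px) | direction consistency |
| `curv_mean` | mean $\lvert\kappa\rvert$ (1/px) | curvature level |
| `peak_density` | # local maxima of $\lvert\kappa\rvert$ above threshold, per px | curvature level |
| `tortuosity` | $L / \text{chord}$ | curvature level |
| `inflect_density` | # sign changes of $\kappa$ per px | curvature level |

Doubled angles make the direction statistic *axial*: a vessel tangent is an
orientation, not a heading, so $\theta$ and $\theta + \pi$ must coincide.
The curvature-peak threshold defaults to $0.15\,\text{px}^{-1}$ (turning
radius below ~6.7 px counts as a sharp turn). A curvature dead zone of
$10^{-6}$ suppresses sign changes of numerically-zero curvature; a closed
loop (zero chord) gets tortuosity $L/\text{spacing}$ and a flag.

Each descriptor is pooled over an image's segments with four statistics —
arc-length-weighted mean, arc-length-weighted population SD, maximum, and
unweighted 75th percentile with linear interpolation — in a frozen,
descriptor-major order (`feature_names()`). The order is part of the
package contract. An image with no segments maps to the all-zero vector
with a warning attribute rather than an error, so degenerate frames stay
in the sample.

Rotation behavior, verified in the tests: the continuous pooled means are
stable to better than 2 % under 90° rotation on non-crossing fixtures;
the two count-based densities can shift by one borderline event under
re-discretization, so their stability is asserted in absolute counts. The
segment partition itself is *not* rotation invariant at vessel crossings
(thinning is anisotropic), which is why the invariance fixture avoids
crossings.

# Classifiers

Four learners with the study's tuned hyperparameters as validated
defaults: polynomial-kernel SVM ($C = 1$, degree 3 — the kernel's degree
is not specified by the study, 3 is the customary default), RBF SVM
($C = 1$, $\gamma = 0.01$), kNN ($k = 5$, Euclidean) and a random forest
(depth 8, 55 trees, $\lfloor\sqrt{24}\rfloor = 4$ features per split).
Features are z-scored with training-set statistics (constant dimensions
get unit scale); the standardizer travels with the model. Distance- and
margin-based learners require standardization; the forest is indifferent
but receives the same inputs for uniformity.

`grid_search_cv()` re-tunes over the canonical grids — $C$ and $\gamma$
over $10^{-3}\dots10^{3}$ (7 values each), $k$ and depth over $1\dots20$,
tree count over $10\dots100$ in steps of 5 — scored by mean 10-fold CV
accuracy. Folds are grouped by patient and stratified by label: frames of
one patient are near-duplicates, and ungrouped folds would leak them
across the train/validation boundary (a flag restores ungrouped folds for
comparison). Ties go to the first grid point in documented order, i.e.
the smallest parameter values.

# Evaluation framework

Malignant is the positive class (label 1). Sensitivity and specificity
with zero denominators are reported as `NA`, never coerced. A patient is
counted as correctly classified iff **strictly** more than half of the
patient's images are correct — the literal reading of the aggregation
rule, under which an exact tie (even image count) counts as a
misclassification; `strict_majority = FALSE` gives the lenient reading for
sensitivity analysis. Observer agreement splits patients into category I
(all observers correct), II (some), III (none). The per-histopathology
misclassification percentages divide misclassification counts by
(observers × patients), patients, or (classifiers × patients)
respectively, and are rounded **half-up** to integer percents — the
convention is pinned by the printed cell in which 1 of 8 patients appears
as 13 %. `invert_eq2()` recovers the integer count behind a printed
percentage, which is what makes the printed per-classifier cells
recomputable without the private images.

# Synthetic data model

`generate_cohort()` renders labeled cohorts without clinical data. Paths
integrate a curvature sequence $\kappa(s)$ at unit steps: the LVC regime
uses a two-harmonic random profile rescaled so $\max\lvert\kappa\rvert$
is at most $0.02\,\text{px}^{-1}$; the PVC regime alternates low-curvature
runs (5–15 px) with high-curvature bouts (12–22 px at
$\lvert\kappa\rvert \in [0.15, 0.30]\,\text{px}^{-1}$, random sign),
starting and ending with a bout so that at least 30 % of arc length is
above $0.1\,\text{px}^{-1}$ by construction even after boundary
truncation. The two curvature scales are separated by construction; a
cohort generated with overlapping scales triggers a warning.

Rendering stamps each path as a dark tube with a Gaussian cross-profile
(depth 0.45, width $\sigma_w \in [0.8, 1.8]$ px — clinical vessels are
roughly 8–15 px wide at full frame size, and the default
$256\times320$ rendering is a quarter-linear-scale version of the
$1008\times1280$ clinical frame) on a bright background (0.85) with
smooth texture and sensor noise, then applies the optical/compression
blur (0.8 px). Numbers the renderer is calibrated by:

* texture amplitude 0.02 and fixed correlation length 16 px — the texture
  scale is a property of the mucosa at the fixed magnification, not of
  the crop size;
* noise SD 0.01, added *before* the final blur so it is spatially
  correlated, as in real video-derived still frames;
* with these levels, background perturbations stay below ~4 % of the
  vessel-driven image maximum, which is the regime the ratio-free
  response function and the default hysteresis thresholds presuppose.
  Stronger white noise or size-coupled texture makes the normalization
  treat background as vessel — an unphysical operating point for frames
  whose contrast is dominated by hemoglobin absorption.

Patients share an appearance jitter (width multiplier, background shift,
noise multiplier) across their frames, emulating the redundancy of
consecutive video frames; curvature is sampled per image and is *never*
jittered per patient. This is deliberate: with the study's split (2–5
held-out images of each patient, the remainder trained on), a per-patient
curvature signature would let a nearest-neighbour classifier identify the
*patient* rather than the class, and the leakage-guard experiment — in
which the two regimes are given identical curvature laws via
`equalize_curvature()` and every classifier must fall to chance — would
be impossible to pass honestly.

What the generator does not emulate: specular highlights, uneven
illumination, interlacing/JPEG artifacts, mucus, vessel caliber variation
along a path, true 3-D projection of perpendicular vessels (dots), or the
class-imbalanced histopathology composition of the clinical cohort
(synthetic patients cycle through the histopathology names only so that
manifests validate). Passing the synthetic recovery experiment therefore
shows that the geometry-classifier chain works when the morphological
signal is present; it does not certify clinical performance.

# Study conditions used by the heavy experiments

The end-to-end recovery experiment uses 40 patients × 10 images at
$256\times320$, seed 1, the patient-wise split
($k = \mathrm{clamp}(\mathrm{round}(0.2\,n), 2, 5)$ test images per
patient — the reconstruction of the "two to five randomly selected images,
≈20 %" subset rule), and all four classifiers at their defaults; each must
reach image-level sensitivity and specificity of at least 0.90. The
leakage guard repeats the experiment with equalized curvature laws and
requires every classifier's image-level accuracy to drop to at most 0.65.
Both experiments run inside the test suite on one CPU.

# Known limitations

* The response with $\tau = 1$ is normalized by the per-image maximum:
  images without well-contrasted vessels inflate weak structure.
  Per-image threshold adaptation is intentionally absent to match the
  published configuration.
* Thinning anisotropy makes segment partitions unstable at vessel
  crossings; pooled continuous features are stable, count densities move
  by whole events.
* The σ range is interpreted in pixels by default; the study states
  scales in millimetres without a published pixel spacing, so a physical
  conversion requires the user's `pixel_spacing`.
* The 24 features capture geometry only; intensity, caliber and color
  information is deliberately out of scope.
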