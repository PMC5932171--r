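---
title: "Detecting cell nuclei by iterative radial voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell nuclei by iterative radial voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radvote)
```

## The problem

High-throughput microscopy — serial-sectioning brightfield techniques such
as knife-edge scanning microscopy (KESM) as well as large confocal
fluorescence stacks — produces volumes in which every voxel of tissue is
packed with nuclei of varying size, shape and internal structure.
Locating each nucleus is the first step of almost any downstream
quantification (cell counting, segmentation seeding, tracking), and at
whole-organ scale it must run with essentially no per-image tuning.
Thionine-type stains make the task harder than classic blob detection:
nuclei are dark on a light neuropil, many neurons show a pale nucleus with
a dark nucleolus, and unstained microvessels punch holes through the
background, so detectors that assume one bright Gaussian blob per cell
either split cells or hallucinate.

`radvote` implements iterative radial voting for this setting, in 2D and
3D, with exactly one tuning parameter: the maximum cell radius $r$, given
in micrometers.

## The model

Let $I$ be the (optionally smoothed) image.  Every lattice site $t$ is a
*voter* with weight equal to the gradient magnitude $M(t) = |\nabla I(t)|$
and a direction that initially points along the gradient — oriented so
that, at a cell boundary, it points into the cell interior (the sign is
`polarity = "dark"` or `"bright"`).  Each voter casts its weight into a
*vote cone*: the set of sites $p$ with

$$\angle\big(p - t,\ \theta_t\big) < \phi/2
  \quad\text{and}\quad |p - t| < r ,$$

both evaluated in physical (micrometer) coordinates and both strict.  The
accumulated vote field $V$ therefore concentrates where many boundary
normals converge — centers of radial symmetry.  After each pass every
voter re-orients toward the maximum of $V$ inside its own cone (its
magnitude is untouched), the aperture is halved, and voting repeats; the
iteration stops at the first aperture below $\phi_t = 1/r_\text{px}$
radians, the aperture whose arc is narrower than one pixel at distance
$r$, after which no further refinement is representable on the lattice.
With $\phi_0 = \pi/2$ this takes $\lceil\log_2(\phi_0 r_\text{px})\rceil + 1$
iterations — five for a 10-pixel radius.  Local maxima of the converged
field, separated by at least $r$, are the detected centers, each scored by
its vote count.

Two equivalent formulations exist for the accumulation step: *collect*
(for every site, sum the magnitudes of voters whose cone covers it) and
*project* (for every voter, add its magnitude to every site in its cone).
The package's fast path is the project form with an exact axis-aligned
bounding volume around each cone; the collect form is retained as
`collect_votes_oracle()` and the test-suite holds the two equal to
floating tolerance on random fields.

### The bounding volume

The cone-plus-spherical-cap solid is a spherical sector and therefore
convex, so its extent along any axis has a closed form: the extreme along
a unit direction $e$ is $r\cos(\max(0, \theta - \phi/2))$ clamped below at
zero, where $\theta$ is the angle between $e$ and the cone axis.  The box
is exact (every member site is inside it) and tight per axis, and it is
what makes dense 3D voting affordable: at small apertures almost no
candidate site inside the naive $(2r+1)^3$ window is a member.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `radius_um` | — | µm | maximum cell radius; cone length, peak separation, and the matching criterion all derive from it |
| `pixel_size_um` | 1 | µm/px | per-axis physical spacing; anisotropic stacks are handled by evaluating all geometry in micrometers |
| `polarity` | `"dark"` | — | `"dark"` for brightfield (thionine-like), `"bright"` for fluorescence |
| `sigma` | 2 | px | Gaussian pre-blur on the finest axis, scaled per axis so the physical blur is isotropic; set `blur = FALSE` for high-SNR input |
| `phi0` | $\pi/2$ | rad | initial aperture; detection is insensitive to larger values, so the conservative maximum is the default |
| `shrink_factor` | 0.5 | — | per-iteration aperture multiplier (halving = binary search on the angle) |

The radius is deliberately the only parameter a user must supply.  When
the calibration is unknown, leave `pixel_size_um = 1` and give the radius
in pixels.

## Worked example

```{r example, eval = FALSE}
library(radvote)

truth <- generate_phantom(phantom_preset(
  "kesm_like", shape = c(128, 128, 128), n_cells = 50, seed = 1))

votes <- iterative_vote(truth$image, radius_um = 8, polarity = "dark")
dets  <- threshold_detections(find_local_maxima(votes, 8), "otsu_log")

match_detections(dets, truth, r_max_um = 8)
#> <match_report> TP 50, FP 0, FN 0 | precision 1.000, recall 1.000 (criterion 4.00 um)
```

## Score thresholding

`find_local_maxima()` reports every isolated vote peak, including small
clumps that coherent noise gradients form after several focusing
iterations.  True-cell scores grow with the amount of boundary evidence
(roughly the boundary surface times the edge contrast), so they span an
order of magnitude across a 3–8 µm radius range, while noise peaks sit
orders of magnitude lower.  On such multiplicative-range scores the
classical Otsu split on a linear 256-bin histogram can land *inside* the
true-cell score range, because nearly all noise peaks collapse into the
bottom bin.  The package therefore offers three operating points:
`"manual"`, `"otsu"` (linear histogram), and `"otsu_log"` — the identical
Otsu procedure applied to log scores — and uses `"otsu_log"` as the
recommended automated choice.  Downstream consumers that treat the score
as a posterior-like quantity can skip thresholding entirely.

## What the phantoms emulate — and what they do not

`generate_phantom()` renders anti-aliased spheres (1-voxel partial-volume
ramp) with rejection-sampled centers honoring a minimum separation, an
optional contrast-inverted core in a fraction of cells (the nucleolus that
makes brightfield neurons hollow-looking to blob detectors), additive
Gaussian noise, and clamping to $[0,1]$.  The `"kesm_like"` preset is
dark, dense (separation factor 2.2), 3–8 µm radii, 30% hollow;
`"fluor_like"` is bright, sparse and solid.  `generate_anisotropic_variant()`
re-samples a phantom as a coarser-z acquisition of the same physical
scene, which is how the anisotropy-independence of the physical-space
formulation is exercised.

Real tissue differs in ways the phantoms do not model: non-spherical and
touching somata, vessels and other elongated dark structures, intensity
inhomogeneity across the field, sectioning artifacts, and a point-spread
function rather than an ideal partial-volume edge.  Passing the phantom
suite therefore demonstrates the correctness and the resolution/anisotropy
behavior of the machinery, not field performance on any particular
instrument's data.

## Numerical choices

* **Strictness and ties.** Both membership inequalities are strict, and
  every argmax tie (direction updates, peak plateaus, cluster survivors)
  resolves to the first site in array storage order, making runs
  bit-reproducible across platforms.  The membership predicate is written
  identically (`dot > 0` and `dot^2 > \cos^2(\phi/2)\,|q|^2`) in the R and
  compiled layers so the two can never disagree.
* **Gradients.** Second-order central differences in the interior,
  first-order one-sided at boundaries, divided by the per-axis spacing.
  Magnitudes at or below $10^{-10}$ (the round-off left when smoothing a
  flat region) are treated as exact zeros: such sites carry a null
  direction and never vote.
* **Blur.** Separable Gaussian, kernels truncated at $4\sigma$, with
  half-sample symmetric reflection; the convolution matrix is symmetric
  with unit row sums, so constants and total mass are preserved.
* **Degenerate inputs.** A blank image produces a zero vote field and an
  empty detection set; voters whose cone holds no positive votes keep
  their direction; Otsu thresholding refuses empty or constant score
  lists rather than guessing.
* **Schedule.** The iteration count includes the first aperture below
  $\phi_t$ (the sequence for a 10-pixel radius is $\pi/2, \pi/4, \pi/8,
  \pi/16, \pi/32$), so the narrowest representable cone is actually used
  once before stopping.

## Validation protocol

A detection is a true positive when it lies within 50% of the maximum
radius of a still-unmatched truth center; matching is greedy by descending
score and one-to-one.  Precision-recall curves sweep the detection-score
threshold over all achieved values, and the area under the curve is the
trapezoid over recall anchored at the precision of the strictest
threshold.  The scale-normalized Laplacian-of-Gaussian detector
(`log_detector()`, default $\sigma = 4$ px) provides the baseline
comparison on identical inputs, sharing the peak-extraction machinery so
the comparison isolates the scoring transform.

Problem sizes used by the shipped checks — 50 cells in $128^3$ for the
dense scene, its $128^2 \times 64$ anisotropic variant, $64^3$ for mass
bookkeeping, $32^3$ for single-ball localization — were chosen as the
smallest scenes that still exhibit dense packing, hollow cells and
anisotropy at realistic cell-to-volume ratios.

## Known limitations

* Single radius: strongly heterogeneous populations (radii spanning more
  than ~3x) share one $r$; the largest radius governs separation, so very
  small adjacent cells closer than $r$ merge.
* No segmentation: output is seed points with scores, intended to
  initialize a segmentation stage, not to delineate nuclei.
* The voting kernels are single-threaded compiled code; terabyte-scale
  volumes need tiling above this package's scope.
* Elongated dark structures (vessels) accumulate ridge-like votes; their
  peaks score well below compact nuclei and are removed by thresholding,
  but they are not modeled explicitly.
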