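# radvote — cell nucleus detection by iterative radial voting

`radvote` locates cell nuclei in 2D grayscale images and 3D microscopy
volumes (multi-page TIFF stacks).  It targets the regime where classic
blob detectors struggle: densely packed tissue, nuclei of varying size,
and brightfield stains in which neurons appear as pale nuclei with dark
nucleoli.  Detection needs a single tuning parameter — the maximum cell
radius in micrometers — and is independent of sampling resolution and
voxel anisotropy because all geometry is evaluated in physical units.

## The algorithm

Every lattice site votes.  A site `t` has weight `M(t) = |∇I(t)|` and a
direction that points from boundaries toward cell interiors (`dark` or
`bright` polarity).  It casts its weight into a *vote cone*: all sites
`p` with

    angle(p − t, θ_t) < φ/2   and   |p − t| < r      (micrometer space)

After each pass, every voter re-orients toward the maximum of the vote
field inside its own cone and the aperture is halved, starting at
`φ₀ = π/2` and stopping at the first aperture narrower than one pixel of
arc at distance `r` (`φ_t = 1/r_px`).  Votes thereby converge onto
centers of radial symmetry.  Local maxima of the converged field,
separated by at least `r`, are the detections; each is scored by its vote
count, with manual or Otsu-style automated thresholding.  An exact
axis-aligned bounding volume around each cone prunes candidate sites,
which is what makes dense 3D voting affordable.

The package also ships a scale-normalized Laplacian-of-Gaussian baseline
detector, a synthetic phantom generator with ground truth (brightfield-
and fluorescence-like presets), and precision-recall validation under the
standard criterion that a detection is a true positive within 50% of the
maximum radius of an unmatched annotated center.

## Worked example

```r
library(radvote)

# a dense brightfield-like scene with known ground truth:
# 50 dark nuclei (3-8 um radius, 30% with nucleolus-like cores) in 128^3
truth <- generate_phantom(phantom_preset(
  "kesm_like", shape = c(128, 128, 128), n_cells = 50, seed = 1))

votes <- iterative_vote(truth$image, radius_um = 8, polarity = "dark",
                        verbose = TRUE)
#> iteration 1/5: phi = 1.5708 rad, vote mass = 3.56319e+06
#> ...
#> iteration 5/5: phi = 0.0982 rad, vote mass = 23004.4

dets <- threshold_detections(find_local_maxima(votes, 8), "otsu_log")
match_detections(dets, truth, r_max_um = 8)
#> <match_report> TP 50, FP 0, FN 0 | precision 1.000, recall 1.000 (criterion 4.00 um)
```

`iterative_vote` ran five passes (the halving schedule for an 8-pixel
radius), the vote mass shrinking as cones narrow; all 50 nuclei are
recovered with no false positives at the automated operating point.  The
score of each detection is its accumulated vote count — larger, sharper
cells score higher — and sweeping it yields a precision-recall curve:

```r
precision_recall_curve(find_local_maxima(votes, 8), truth, 8)$auc
#> [1] 1
log_detector(truth$image, sigma = 4, r = 8, polarity = "dark") |>
  precision_recall_curve(truth, 8) |> getElement("auc")
#> [1] 0.96
```

## Command line

A thin front-end over the same functions lives at `inst/cli/radvote.R`
(after installation: `system.file("cli", "radvote.R", package = "radvote")`):

```sh
Rscript radvote.R synth  --image phantom.tif --truth truth.csv \
    --preset kesm_like --shape 128x128x128 --n-cells 50 --seed 1
Rscript radvote.R detect --input phantom.tif --output dets.csv \
    --radius-um 8 --pixel-size 1 --threshold otsu_log
Rscript radvote.R eval   --detections dets.csv --truth truth.csv \
    --r-max-um 8 --report report.json --pr pr.csv
```

All CSVs use 0-based pixel coordinates in `(x, y, z)` order; `detect`
writes a resolved copy of its configuration next to the output for
reproducibility.

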