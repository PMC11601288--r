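---
title: "Methods: spot splitting with same-section protein imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot splitting with same-section protein imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotsplitr)
```

# The model

A deterministically barcoded spot $i$ collects the RNA of the cells under
its square footprint. Writing $x_{i,j}$ for the observed counts of gene $j$
in spot $i$, $\beta_{i,k}$ for the proportion of cells of type $k$ among the
imaging cells registered into the spot, and $\mu_{k,j}$ for the mean
expression of gene $j$ in type $k$ in a labelled single-cell reference, the
expected type-$k$ share of $x_{i,j}$ under a simple mixture view is
$\beta_{i,k}\mu_{k,j} / \sum_{k'}\beta_{i,k'}\mu_{k',j}$. The splitting
operation therefore allocates

$$\hat{x}_{i,j,k} \;=\; x_{i,j}\,
  \frac{\beta_{i,k}\,\mu_{k,j}}{\sum_{k'} \beta_{i,k'}\,\mu_{k',j}},$$

emitting one *sub-spot* per (spot, type) pair with $\beta_{i,k} > 0$. Two
structural properties follow directly and are enforced by tests: the
sub-spot values of a spot re-sum to $x_{i,j}$ wherever the denominator is
positive (mass conservation), and if $\mu$ is identical across types the
split reduces to proportional allocation $\hat{x}_{i,j,k} =
x_{i,j}\beta_{i,k}$.

The assumptions worth stating: every cell of a type contributes equally;
$\beta$ measured from imaging cells is an unbiased stand-in for the RNA
mixing weights; and the reference $\mu$ is on a comparable per-cell scale
across types. The last point is why `compute_reference_profiles()`
library-size-normalizes each reference cell to the median total before
averaging — per-gene *ratios across types* are what the formula consumes,
and they are distorted if one type's cells simply have deeper libraries.
`norm = "raw"` disables this for references that are already depth-matched.

Counts enter the formula raw; whether to normalize $x$ beforehand is not
determined by the model (any per-spot scale factor cancels within a spot),
and the choice is recorded in the output metadata.

## Zero denominators

When no type present in a spot expresses gene $j$ in the reference,
$\sum_{k'}\beta_{i,k'}\mu_{k',j} = 0$ while $x_{i,j}$ may be positive. The
default (`fallback = "beta"`) distributes such counts proportional to
$\beta_i$, which preserves conservation and discards nothing;
`fallback = "drop"` zeroes them. Either way the affected genes are listed
in the result's `log` so the choice is auditable. Genes absent from the
reference entirely are dropped from splitting and logged, as the formula is
undefined for them.

# Upstream: from images to composition

**Feature extraction and filtering.** Per-cell features are the channel
sums over each label's pixels; area is the pixel count and the centroid the
mean pixel coordinate (x = column, y = row, 0-based pixel centers). Cells
are kept when their area lies inside the [0.05, 0.95] quantile range
(inclusive) and their raw nuclear signal strictly exceeds its 0.1 quantile,
with all quantiles computed on the unfiltered table. Quantiles interpolate
linearly between order statistics (R type 7) — a convention that must be
pinned for reproducibility. A table in which every cell has identical
nuclear signal would be emptied by the strict inequality; that tie is
treated as degenerate: a warning is raised and the nuclear filter skipped
rather than silently discarding a dataset.

**Scaling.** Each marker is mapped affinely so its 0.05 quantile goes to 0
and its 0.95 quantile to 1, clipping outside; the anchors are stored with
the output. Markers whose two anchors coincide carry no usable contrast and
are set to zero with a warning. Area normalization (dividing each cell's
sums by its area before scaling) is controlled by `area_normalize`,
default `TRUE`: summed intensities otherwise scale with cell size, which
leaks morphology into every protein feature. Both behaviours are supported
because either can be preferable depending on the panel.

**Registration.** Tissue boundaries come from Gaussian smoothing (default
`sigma_px = 5`), Otsu's threshold on a 256-bin histogram, and binary hole
filling. The similarity transform (rotation, uniform scale, translation; no
reflection by default, since serial sections are not mirrored — an
`allow_reflection` flag tries both and keeps the lower loss) is fit by
minimizing the mean squared difference between the warped moving mask and
the fixed mask. Binary masks make that loss flat almost everywhere, so both
masks are float-rendered with a light Gaussian (sigma 1.5 px) before
comparison. The search is: closed-form initialization from mask centroids
and radii of gyration; a coarse grid over rotation (9° steps) and scale
(±10% around the moment estimate) evaluated on block-downsampled (~96 px)
masks; Nelder–Mead refinement of the two best grid cells at the coarse
level; and a final Nelder–Mead polish at full resolution. On noiseless
synthetic fixtures this recovers a (10°, ×1.2, (30, −15) px) warp to about
0.03° / 0.01% / 0.1 px — comfortably inside the package's acceptance
tolerances (±1°, ±2%, ±2 px) — and the fitted loss is never worse than the
loss at the generating transform. No optimizer or discretization is
canonical for this objective; this scheme is the package's own choice,
selected for determinism and robustness over speed.

The spot raster used as the fixed image renders each tissue-covered spot as
a square at 10 px per pitch. Because the spots are disjoint squares
(channels cover only `channel_width / pitch` of each axis), the raw raster
is a dot lattice; `solidify_spot_mask()` closes it into the tissue
silhouette (box kernel one gap wider than the inter-spot spacing, then hole
filling) before similarity fitting, since a solid blob cannot be matched to
a dot pattern under a squared-error loss without collapsing.

**Assignment and composition.** Spot $(i, j)$ (0-based) is the square of
side `channel_width` centred at `origin + (i, j) * pitch` with half-open
extents, so boundary behaviour is unambiguous: a cell exactly on the low
edge belongs to the spot, one on the high edge does not. Cells between
channels are unassigned. Assignment is centroid-in-square rather than
area-overlap — registration is applied to cell points, and each cell should
contribute to at most one spot. Spots with no cells have *undefined*
composition: they are absent from the table and skipped by splitting (with
a report), never zero-filled. The default pitch is `2 * channel_width`
(equal channel and gap widths, typical of these chips); the actual gap is a
required configuration item since fabrication varies.

**Label transfer.** Pivot cells — the ~10% of imaging cells that arrive
with high-confidence cross-modality labels from an external matching step —
train a linear multiclass SVM (`e1071`, cost 1) on scaled protein features;
the remaining cells take the argmax prediction. A stratified 20% holdout
from the pivots yields per-class precision/recall/F1 (`tidy()`) and overall
accuracy (`glance()`). Reported per-class scores are a softmax over the
summed one-vs-one decision values — a monotone calibration for auditing
only; labels always come from the SVM vote.

# Cross-section QC

Two adjacent sections are preprocessed identically, aligned by a
least-squares affine fit to (typically six) manually matched landmark
points — applied to section B's cell positions — then discretized into
square bins (`bin_size = 100` px by default). Per-bin marker means are
correlated (Pearson) over the bins present in both sections. At least 3
common bins are required; markers with zero variance over the common bins
are reported as undefined rather than given a spurious value. The affine
fit is exact for noiseless landmark pairs and equals the normal-equations
solution in general.

# The synthetic-data generator

The generator exists so that every stage has a ground truth. It emulates:

* a connected, hole-free blob tissue mask (a chain of overlapping disks,
  rescaled toward a 40% foreground fraction, always within 20–80%);
* cells placed uniformly on foreground pixel centres, typed from the truth
  proportions, with lognormal areas (meanlog `log(80)` px², sdlog 0.35 —
  wide enough that the size filter is non-trivial) and protein intensities
  that are mean-preserving lognormal perturbations (sdlog 0.25) of the
  type's mean panel;
* spot counts from a Poisson mixture: for spot $i$ with $n_{i,k}$ cells of
  type $k$, gene $j$ draws Poisson with rate $d_i \sum_k n_{i,k}
  \tilde\mu_{k,j}$, where $\tilde\mu$ row-normalizes the true type profiles
  and $d_i$ is set so the expected spot total equals the depth (default
  2,000 UMI). Draws are made per type and summed, so the realized per-type
  contribution of every spot is retained as ground truth;
* a rendered imaging section (label mask plus channel stack whose per-cell
  sums equal the tabulated intensities exactly) in a pixel frame related to
  the chip frame by a known similarity transform (default 8°, scale 1,
  small offset), plus an adjacent section and six exact landmark pairs.

Defaults are one coherent set of study conditions — 20 × 20 spots of 25 µm
on a 50 µm pitch, 4 types, 200 genes, 5,000 cells, depth 2,000 — chosen
once as a realistic desk-scale experiment; they are not tuned per test.
What the generator does **not** emulate: realistic tissue morphology,
segmentation errors (label masks are taken as given), spatial expression
gradients within a type, batch or cycle effects, and lateral RNA diffusion
between spots. Passing tests therefore demonstrate the *algorithms* —
conservation, recovery of known transforms and contributions, correct
filtering arithmetic — not robustness to those real-data pathologies.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) everywhere.
* Coordinates: 0-based pixels on the imaging side, micrometres in the spot
  frame, half-open intervals everywhere; the px↔µm scale is configuration,
  never inferred.
* Similarity loss: float-rendered masks, bilinear inverse-mapping
  resampling with zero outside the support; rotations reported in
  (−180°, 180°].
* Constant images are rejected by boundary detection (Otsu undefined);
  empty masks, empty types, unlabeled assigned cells, non-grid barcodes,
  and singular/collinear landmark sets are errors, not warnings.
* Sub-spot coordinates are the member cells' centroid — the natural point
  representation, though no convention is canonical.
* TIFF pages are stored as 32-bit floats rescaled to [0, 1] with per-page
  scale factors in a YAML sidecar: exact for binary and integer label
  masks, ~1e-7 relative for float intensities.
* All generators take explicit integer seeds and touch no global RNG
  state; a pipeline run is reproducible byte-for-byte from its
  configuration and seed (timestamps only in the log).

Problem sizes in the shipped tests and acceptance script (20 × 20 grids,
≤5,000 cells, 200 genes, ~10,000-draw Monte-Carlo checks) were chosen as
the smallest sizes at which the statistical assertions are stable; all
complete in a few minutes on a single CPU.

# Known limitations

* $\beta$ comes only from imaging-cell counts; a variant that re-estimates
  composition from the expression data itself (e.g. RCTD-style) is out of
  scope here.
* The closed-form split cannot create within-type heterogeneity: two cells
  of the same type in a spot are indistinguishable downstream.
* Similarity registration assumes the tissue silhouette is informative;
  near-circular tissues leave rotation weakly identified (the grid search
  will pick one of the near-equivalent optima).
* Downstream multimodal analysis (weighted-nearest-neighbour graphs,
  clustering) is intentionally external: this package produces its paired
  inputs (`export_wnn_inputs()`), nothing more.
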