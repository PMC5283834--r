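---
title: "Quantifying stromal images: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stromal images: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaquant)
```

stromaquant bundles three image-quantification procedures used in studies of
the desmoplastic tumor microenvironment, together with seeded synthetic-image
generators that carry machine-readable ground truth. This vignette explains
the science behind each procedure, the conventions and tunable parameters
that affect the numbers, and what the validation on synthetic data does and
does not establish.

## 1. The batch multi-mask/multi-marker quantifier

Simultaneous multi-channel immunofluorescence produces, per tissue sample,
one monochromatic image per channel. Channels play one of two roles:
*masks* delimit tissue compartments (stroma, epithelium/tumor, nuclei) by
thresholding, and *markers* are the channels whose staining intensity is
quantified inside compartments. A query such as

```
SNAKA under vimentin, NOTepi/tumor
```

asks for the statistics of the `SNAKA` marker (active α5β1-integrin)
restricted to pixels that are vimentin-positive (stromal) and not
epithelial/tumoral. The region grammar supports conjunction and negation
only — every query describes an intersection of (possibly complemented)
compartments, which keeps the semantics of "intersection areas" unambiguous;
a union can always be expressed through complements.

Conventions fixed by this implementation (the upstream descriptions leave
them open):

* **Positivity is inclusive**: a pixel is positive when its display
  intensity is `>= threshold` (0–255 scale), so threshold 0 selects every
  pixel.
* **Intensity statistics** (mean, median, sd, integrated intensity) are
  computed over *marker-positive pixels inside the region*;
  `total_intensity` sums every region pixel. Both sums are emitted so either
  reading of "total vs integrated" is recoverable downstream.
* **sd uses the population divisor** `n`.
* **Empty regions report missing values**, never 0 — a region with no
  positive pixel is a different observation from a region of zero-intensity
  pixels. Area coverages of an empty region are defined 0.
* **16-bit inputs** are mapped to the display scale by one global linear
  map, `round(v / 257)` with half-up rounding, so every channel of a run is
  scaled identically. The original workflow used an interactive
  levels/batch-conversion step that cannot be reproduced; a fixed
  deterministic map replaces it and is documented here rather than hidden.
* **Ambiguous filename tokens are an error.** If one channel token matches
  two files in a batch folder the run stops and names both files; silently
  picking one would corrupt every downstream statistic. Batches missing a
  declared channel are skipped with a logged reason by default
  (`on_missing: skip`), or abort the run (`fail`).

Every statistic is validated against a naive double-loop reference
implementation on hundreds of random small images (exact equality for
counts, 1e-9 for floats), and against fixture batches whose ground-truth
statistics are computed from the generated arrays *before* they are written
to TIFF — so the engine must reproduce them after the file round-trip.

XLSX output of the original workflow is not provided; tables are CSV
(RFC 4180, ≥ 6 significant digits, exact round-trip).

## 2. ECM fiber anisotropy

Cancer-associated fibroblasts deposit extracellular matrix whose fibers
align in parallel; normal fibroblasts produce isotropic matrix. The
anisotropy metric operationalizes this:

1. **Per-pixel orientation** by the structure tensor: Gaussian-derivative
   gradients $(I_x, I_y)$ at scale $\sigma_g$, tensor components
   $J_{xx} = \langle I_x^2\rangle$, $J_{yy} = \langle I_y^2\rangle$,
   $J_{xy} = \langle I_x I_y\rangle$ smoothed at scale $\sigma_T$. The fiber
   (structure) orientation is
   $\theta = \tfrac12 \operatorname{atan2}(2J_{xy},\, J_{xx}-J_{yy}) + 90°$
   wrapped to $[-90°, 90°)$ — the direction of least intensity variation,
   counterclockwise from the image x-axis. Energy is the tensor trace
   $J_{xx}+J_{yy}$; coherence is $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$,
   0 for no preferred direction, 1 for perfect orientation.
2. **Energy-weighted angle histogram** over 180 one-degree bins with integer
   centers $-90°\ldots 89°$. Pixels contribute their energy as mass if they
   pass a coherence gate (default 0.2) and an energy-quantile gate (default
   0.1, removing background). A border band of $\lceil 3(\sigma_g+\sigma_T)\rceil$
   pixels is excluded because those pixels' filter support extends past the
   image and boundary padding distorts their orientations.
3. **Mode normalization**: the histogram is circularly shifted (period 180°)
   so its maximal bin sits at 0°. The shift is a whole-bin permutation, so
   mass is conserved exactly. Ties break toward the smaller absolute angle,
   then the positive one.
4. **Percent within spread**: the percentage of total mass in bins whose
   centers lie in $[-15°, +15°]$ — 31 bins, so a perfectly uniform
   distribution scores $31/180 = 17.2\%$.
5. **Classification**: a field with at least 55% of its mass within ±15° of
   the mode is called *anisotropic* (aligned, desmoplastic-like); the
   threshold is inclusive. 47% is the canonical example of an isotropic
   (disorganized) matrix.

Defaults $\sigma_g = 1$ px and $\sigma_T = 2$ px are chosen to resolve
fibers a few pixels wide; the original plugin's settings were not recorded,
so all scales and gates are configurable and every run records the values
used. The hue-coded orientation map renders $\theta$ relative to the mode on
the HSV circle with the mode at cyan, saturation = coherence, value = scaled
energy; per-condition aggregation normalizes each image to its own mode
first and then averages relative-frequency histograms bin-wise.

### What the synthetic fibers validate — and what they do not

`make_fiber_image()` renders anti-aliased line segments whose orientations
are drawn from a von Mises distribution on the doubled angle (the natural
circular model for axial data; κ = 0 is uniform, larger κ is more aligned),
over Gaussian background noise. Defaults: 1024×1024 px, 600 fibers of
length 40–90 px and width 2 px, peak intensity 200, noise sd 8 — about 11%
areal fiber coverage, a sparse-to-moderate density at which individual
fibers remain resolvable. The sidecar records every drawn angle and length
and the exact length-weighted fraction of fiber mass within ±15° of the
planted mode.

On these fixtures the pipeline recovers planted grating orientations to
within a degree across the axial range, conserves mass through
normalization, reproduces the analytic uniform value at κ = 0 within a few
points, and tracks the planted ±15° fraction across κ. Two intrinsic
properties of the *statistic* (not implementation artifacts) limit how
tightly the planted fraction can be recovered:

* **Mode-centering noise.** The ±15° window is centered at the empirical
  maximal bin. Fibers are spatially coherent, so the effective sample size
  of the histogram is the number of fibers, not the number of pixels; at
  moderate concentration (κ ≈ 2) a direct simulation on drawn angles alone
  shows the gap between window-at-empirical-mode and window-at-true-mode
  has a standard deviation near 3 percentage points.
* **Crossing suppression.** The coherence gate removes pixels where fibers
  cross at wide angles. Fibers oriented away from the dominant direction
  cross it more often, so their mass is preferentially suppressed and the
  within-window percentage is biased slightly upward in aligned fields. The
  effect grows with fiber density; at high density (heavily overlapping
  matrix) the metric saturates and should be interpreted comparatively, not
  absolutely.

The fixtures do not emulate real ECM photophysics: no point-spread
function, no fiber curvature or branching, no depth integration, no uneven
illumination. Passing tests establish the correctness of the computation
and its behavior under controlled angular statistics, not performance on
real micrographs.

## 3. Adhesion morphometry

Cells in 3D matrices form elongated cell–matrix adhesions. The analysis
thresholds the adhesion-marker channel, labels 8-connected components
("internally thresholded objects"), and measures each component's
calibrated length; objects with length ≥ 6.5 μm are counted as bona fide
3D-adhesions. Conventions:

* **Length is the maximum Feret (caliper) diameter** over pixel centers
  (computed on the convex hull), chosen over the ellipse-equivalent major
  axis because adhesions are thin, sometimes curved streaks; the ellipse
  estimator is available behind `length_method = "ellipse"`. Pixel-center
  distances mean a bar spanning 70 pixels measures 69 pixel units along its
  axis (7.59 μm at the 0.11 μm/px calibration).
* **8-connectivity** for components — 4-connectivity would split diagonal
  streaks.
* **Line scans** sample one pixel per step along a 12 μm segment
  (`floor(length/step) + 1` samples, 110 at 0.11 μm/px), taking at each
  position the median of bilinearly interpolated intensities across a
  3-pixel transverse width; peaks are strict local maxima above the profile
  median.
* **Colocalization** is the A-referenced area-overlap fraction
  $|A^+ \cap B^+| / |A^+|$ of two thresholded channels (deliberately
  asymmetric: "fraction of αSMA-positive area on stress fibers"). An empty
  reference yields 0 with a warning flag.

Adhesion fixtures place non-overlapping bars by rejection sampling (a hard
cap of 10^4 attempts per bar turns an impossible packing into an error
rather than a silent density bias) and render them with solid ends so that
thresholding at half intensity under noise does not erode the planted
length.

## 4. Reproducibility machinery

All generators take a single integer seed and are byte-deterministic given
it. Every command-line run writes a JSON manifest carrying the tool
version, the fully resolved configuration, input file hashes, and the
parameters actually used; the statistics tables of a deterministic stage
are byte-identical across reruns. Validation runs use problem sizes chosen
to exercise the estimators at realistic statistical power — 200 random
images for the statistics oracle, 1024² fiber fields, 10 planted grating
angles — while completing in minutes on a single core.

## 5. Known limitations

* The 16→8-bit display map is a fixed substitute for an interactive
  rescaling step; absolute intensity comparisons across datasets acquired
  with different scalings remain the user's responsibility.
* The query grammar intentionally omits OR and parentheses.
* The anisotropy metric is pixel-mass-based; it does not trace or count
  discrete fibers, and its ±15° percentage saturates in densely overlapping
  matrix (see above).
* Orientation analysis is 2D; out-of-plane fiber tilt is invisible.
* No proprietary microscope formats or spectral unmixing: inputs are plain
  single-plane grayscale TIFFs.
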