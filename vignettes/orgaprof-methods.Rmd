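---
title: "Methods: radial organelle profiling and kymograph transport analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial organelle profiling and kymograph transport analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orgaprof)
```

## The measurement model

Organelle positioning is summarised per cell by the cumulative radial
intensity profile. Given a closed cell contour with vertices
$p_{\mathrm{periphery}}(i)$ and an interior center $p_{\mathrm{center}}$,
shell polygons at distance fractions $d = k/10$ are formed by scaling the
contour about the center,

$$p_{\mathrm{new}}(i, d) = p_{\mathrm{center}} + d\,\bigl(p_{\mathrm{periphery}}(i) - p_{\mathrm{center}}\bigr),$$

so `polygon(1.0)` is the contour itself and the shells adapt to the cell's
shape rather than being plain circles. Every pixel center inside
`polygon(1.0)` is assigned to the innermost polygon containing it; shell
sums are normalised by the total in-cell intensity, making the profile
invariant to overall brightness and exposure. The per-cell scalar is the
profile AUC (mean cumulative value): a delta of intensity at the center has
AUC 1, intensity concentrated in the outermost shell has AUC 0.1, and a
uniformly filled cell sits near the mean of $d^2$ (≈ 0.385), because the
shell at fraction $d$ encloses an area proportional to $d^2$.

Assumptions worth stating explicitly:

* The contour must be *star-shaped about the chosen center* for the shells
  to nest. Scaling is a similarity transform, so inner polygons are always
  simple; what fails for a concave cell is nesting. `build_shells()` runs a
  sampled star-shape test and flags (with a warning) cells that violate it;
  flagged profiles carry `flagged = TRUE` and should be reviewed rather
  than silently pooled.
* Pixels inside the cleaned cluster but left outside `polygon(1.0)` by
  contour-approximation slack are counted in the outermost shell, so no
  in-cell intensity is dropped.
* Zero total intensity yields an *invalid* profile (cumulative all 0,
  excluded from statistics) rather than NaNs.

Group comparison computes per-group mean curves on the shared fraction grid
and tests per-cell AUCs with Welch's two-sided t-test (two groups) or
one-way fixed-effects ANOVA (more). Both statistics are implemented from
the textbook formulas; the test suite checks them against `stats::t.test`
and `stats::oneway.test` to 1e-10. The AUC was chosen as the tested scalar
because cumulative curves are read by their left/right shift and the AUC is
the canonical one-number summary of such a shift.

## Segmentation front-end

The preprocessing chain is deliberately classical: binarisation (Otsu over
256 bins by default; fixed threshold or an external mask can be supplied),
morphological erosion by a disk (default radius 3 px) to sever thin
processes connecting neighbouring cells, 8-connectivity connected-component
labelling with components sorted by area, hole patching (4-connectivity
border flood on the complement) with removal of clusters below `min_area`
(default 500 px²), Moore-neighbour boundary tracing (counter-clockwise by
the shoelace sign), and closed-curve Douglas–Peucker simplification.

Douglas–Peucker details: the tolerance is *relative*,
$\varepsilon = 0.009 \times \text{perimeter}$. The bare factor 0.009 is the
default contour-fidelity parameter; treating it as a perimeter fraction
matches the widespread convention for polygon approximation of closed
curves and makes the result scale-free. The closed chain is seeded at its
two mutually farthest points (ties resolved to the lowest index pair), each
open half is simplified recursively, and the union of kept points is
returned in chain order. Every original boundary point is guaranteed to lie
within $\varepsilon$ of the simplified polygon; the suite checks this and
exact agreement with an independent recursive implementation on random
chains. If simplification leaves fewer than three vertices (a chain whose
every excursion is below tolerance) the contour is reported as degenerate
instead of silently returning a line.

Center selection: the interactive "click the cell center" step is replaced
by `--center x,y` (validated to be inside the contour), the polygon
centroid, or a nucleus-mask centroid. If a *computed* center falls outside
a non-convex contour the pole of inaccessibility (deterministic
coarse-to-fine grid search of the interior point farthest from the outline)
is substituted with a warning; a *manual* point outside is an error.

## Kymographs and transport events

`build_kymograph()` resamples the path at unit arc-length spacing and takes,
per sample and frame, the maximum over a perpendicular window (default
3 px, preserving punctate signal) of bilinearly interpolated intensities.
Columns are frames; anterograde motion (proximal → distal, increasing path
coordinate) appears as a left-to-right rising locus.

Track extraction from the kymograph (`trace_kymograph()`) is automated
plumbing for a step usually done by hand in ImageJ, and it is the one place
where the package needed a real algorithmic decision. Anterograde and
retrograde loci inevitably cross on a shared path; when two loci merge into
a single peak, any strictly frame-to-frame nearest-neighbour linker either
swaps identities or breaks both tracks, and exact event counting becomes
impossible. The implemented tracker therefore:

1. detects per-column 1D peaks above a robust threshold
   (`median + 5·MAD` by default) with an intensity-weighted subpixel
   centroid whose window is truncated at local valleys (so a neighbouring
   locus does not pull the position);
2. seeds tracks from triplets of detections in three consecutive frames
   with near-constant velocity (second difference ≤ 1 px), ranked by that
   residual;
3. grows each seed bidirectionally, claiming the nearest unconsumed
   detection within 3 px of a windowed least-squares prediction, *sharing*
   an already-consumed detection when none is free (the merged-peak case),
   and tolerating up to 5 missing frames;
4. trims end points inconsistent with the locally fitted motion (a merged
   peak claimed exactly at a track end would otherwise bias the net
   displacement), and discards tracks that are mostly shared claims or
   that have detections in less than 80% of their span — both signatures
   of duplicate or phantom chains rather than real loci.

The tracker assumes locally smooth, piecewise near-linear motion — what
motor-driven cargo looks like at a 1 s frame interval — and is not a
general curvilinear tracker. Measured on the synthetic world (30 puncta,
70 frames, ~100 crossings per movie): planted 10/10/10 counts are recovered
exactly in 40/40 noiseless movies and 39/40 movies at peak SNR ≈ 16, the
single failure being a stationary track whose endpoint noise crossed the
2 px classification threshold by 0.02 px. Event classification itself is
the stated contract: net displacement below `stationary_px` (default 2 px,
exposed, not asserted as ground truth) is stationary, otherwise the sign
decides anterograde vs retrograde; one classified track is one event.
Axon/dendrite labelling applies the "three times longer" rule with the
median of the remaining processes as the reference aggregate.

The EB3-comet tracker (`detect_spots()` + `link_spots()`) is kept minimal
on purpose: difference-of-Gaussians band-pass, strict 3×3 local maxima with
center-of-mass refinement, and greedy nearest-neighbour frame-to-frame
linking with no gap closing. Greedy linking equals optimal matching
whenever spots are separated by more than twice the linking radius, which
is the regime the speed statistics are validated in; reproducing a full
LAP/gap-closing tracker is out of scope.

## Synthetic data: what it emulates, what it does not

`generate_cell()` draws a star-convex outline (mean radius 80 px, 12%
radial roughness, 5 angular harmonics), places `n_puncta` puncta at
normalized radii from Beta(a, b) along uniform directions — Beta(1,3) for a
perinuclear, Beta(3,1) for a peripheral, Beta(1,1) for a uniform-in-radius
law — renders a Gaussian PSF (σ 1.5 px, amplitude 200) on a flat background
(100) with Poisson photon noise and Gaussian read noise (σ 3), peak
SNR ≈ 10. The Beta family was chosen because the profile operates on
normalized radius, so a one-parameter location family on [0, 1] is the
natural planted law. `generate_timelapse()` renders constant-velocity
populations (defaults ±2 px/frame, 70 frames at 1 s) with a minimum initial
separation of 5 px along the path; the path must be long enough that no
punctum exits, and the generator refuses otherwise, naming the punctum.

Real images differ in ways the generator does not emulate: organelles pause
and reverse rather than gliding at constant speed; puncta vary in size and
brightness; cytoplasmic background is structured, not flat; cells touch and
overlap. A green test therefore establishes that the *measurement chain* is
correct on data satisfying its assumptions — not that segmentation or
tracking is robust to every real-world pathology. The `concave = TRUE`
generator flag produces deliberately non-star-shaped cells (two notched
combs) to exercise the warning path.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, `x` = column, `y` = row, pixel centers at
  integers; all geometry uses the even-odd point-in-polygon rule.
* Erosion uses a digital disk ($dx^2 + dy^2 \le r^2$) with the image border
  treated as background; radius 0 is the identity.
* Otsu on a constant image warns and returns all-background instead of an
  arbitrary split.
* Welch's t with zero pooled variance resolves by the mean difference
  (statistic 0 or ±∞) instead of NaN.
* Tracks shorter than 2 points cannot be classified and raise an error
  carrying the track index.
* All generators accept a seed and restore the caller's RNG state; equal
  spec + seed gives bit-identical arrays, which the CLI inherits
  (byte-identical CSVs for fixed config + seed).
* TIFF support is implemented in-package (no R TIFF reader was available in
  the target environment): uncompressed grayscale or chunky multi-sample,
  8/16-bit, multi-page, both byte orders on read; compressed or tiled
  files are rejected with a format error naming the file. The test suite
  cross-checks the codec against an independent implementation.

## Known limitations

* The radial profile assumes one cell per contour; touching cells
  inadequately severed by erosion will be profiled as one.
* Shell assignment is pixel-center based; for very small cells
  (radius ≲ 20 px) the discrete shell boundaries bias the innermost
  fractions.
* `trace_kymograph()` counts one event per track; a cargo that reverses
  direction mid-movie is counted once with its net direction, because no
  segmentation rule into sub-excursions is defined.
* The greedy comet linker will swap identities for crossing comets closer
  than the linking radius; speed summaries should be read in the
  well-separated regime.
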