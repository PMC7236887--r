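---
title: "Morphometry of auricular arteries and nerves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of auricular arteries and nerves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cymbamorph)
```

## The problem

Percutaneous auricular vagus nerve stimulation places needle electrodes in
the cymba conchae, the one region of the external ear believed to be solely
vagally innervated. Optimising electrode placement needs quantitative
anatomy: how many arteries and nerves cross a given skin region, how large
they are, how much tissue they occupy, how far nerves run from the arteries
that are used as visual placement landmarks, and how far a cylindrical
stimulation field must reach to cover them. High-resolution episcopic
imaging (HREM) of resin-embedded skin yields aligned micrometre-scale image
stacks in which an anatomist can segment arteries, nerves, veins, cartilage
and dermis slice by slice. This package quantifies such multi-class binary
mask stacks.

The data model is a `mask_stack`: one binary raster per class per slice,
with a `voxel_geometry` tying indices to micrometres. The defaults describe
the analysed dataset: 1.48 x 1.48 um pixels, 3 um sections with every 5th
segmented, hence 15 um between masks and 1.48 x 1.48 x 15 um voxels. Within
a slice, `x` runs along columns and `z` along rows; the stack axis `y` is
the sectioning direction. Subsampling is treated purely as calibration —
whether analyses would change at full 3 um resolution is untested and only
reachable through `subsampling_factor`.

## Profile morphometry

One *profile* is one 8-connected component of one class in one slice.
Connectivity is a genuine free choice (nothing in the imaging fixes it); we
use 8-connectivity so that diagonal pixel contact — common on the rim of
thin oblique sections — does not split a vessel in two. Labelling wraps
`EBImage::bwlabel()` and merges diagonally touching 4-components with a
union-find pass; the test suite checks the result against a flood-fill
oracle.

Per profile we record the pixel count and area, the area centroid (first
moments — identical to the intersection of the moment-ellipse axes), the
full major/minor axes of the second-moment ellipse (`4 * sqrt(eigenvalue)`,
with a `pitch^2/12` pixel-extent term so single-pixel profiles get
pixel-sized axes), and the *equivalent diameter* `d = 2 * sqrt(A / pi)` of
the circle with the same area. Collapsed lumina and oblique sections make
the actual cross-section geometrically undefined, which is why the circular
fit is used; obliquity inflates apparent diameters and no correction is
applied — tubes nearly parallel to the sectioning direction (the dominant
wiring here) are the intended regime.

The *capillary exclusion* removes artery profiles with equivalent diameter
below 10 um (the threshold is closed: exactly 10 um is retained). It applies
to arteries only — the segmentation traces arteries down to arterioles but
cannot securely follow capillaries; nerves and veins are untouched.

The per-slice *region of interest* (ROI) is the convex hull of the pixels
of all retained artery and nerve profiles of that slice, after excluding
profiles that touch the raster border (edge elements cannot be verified
along the stack and are dropped). The hull is taken over pixel corners
rather than centres so every counted pixel lies inside it; occupied-area
fractions — class area over ROI area — are therefore bounded by 100% by
construction. Whether vein pixels should enter the ROI is not decidable
from the source material; the hull here is arteries + nerves only, and
veins are excluded from occupancy altogether because specimen processing
collapses their thin walls and corrupts their area. Volume occupancy
weights slices by their (uniform) spacing, so it reduces to the ratio of
summed areas; slices whose ROI is degenerate (fewer than three contributing
pixels) are skipped and reported as excluded.

Summary statistics are median, quartiles (linear interpolation between
closest ranks, `stats::quantile()` type 7 — the convention when none is
stated), IQR, mean and sample SD. Count histograms ("probability density"
of per-slice counts) are normalised pooled across slices; a per-slice
normalisation is meaningless for a scalar per slice, so the pooled reading
was adopted.

## Distances

Nerve–artery distances are Euclidean distances between centroids *within*
each slice plane — deliberately 2D, matching how the per-slide spatial
pattern is defined. Every nerve x artery pair contributes; per-slice minima
are summarised separately. Slices missing either class are skipped, never
imputed. True perimeter-to-perimeter distances are *not* computed from
contours — collapsed walls make them unstable. Instead
`perimeter_distance_bounds()` derives an interval arithmetically: from a
centroid distance `d` and the artery and nerve diameter IQRs, the mean
minimum surface separation lies between `d - (a_hi + n_hi)/2` and
`d - (a_lo + n_lo)/2`, clamped at zero. With the reported values (217 um;
30–71 um; 20–39 um) this gives 162–192 um.

## Radial coverage

Coverage asks: if a needle electrode inserted along Z at a grid point
generates a cylindrical field of radius `r`, which fraction of the distinct
elements does it reach? Elements, not per-slice profiles, are counted, so
profiles are first linked into tracks: footprint overlap between
consecutive slices joins profiles; any split or merge ends the parent track
and starts children, so each track is one contiguous, unambiguous element
segment. (Without the stack, mutual-nearest centroids within a linking
radius — default 30 um, about one artery diameter — are used instead.)

The grid spans the X–Y plane (slice width x stack length) at 1 x 0.5 mm
spacing, inset half a spacing from the boundary so points represent
interior needle placements; how the original 17-point grid followed from
the sample extents is not derivable, so the construction is parameterised
rather than hard-coded. A track is covered at radius `r` for point `g`
when any of its per-slice centroids lies within `r` of `g` in the X–Y
plane (`y = (slice - 1) * 15 um`; the depth coordinate is ignored, per the
needle model). Fractions are tabulated in `dr = 100 um` steps per class and
pooled; curves are non-decreasing and reach 1 at the default maximum
radius. `radius_at_fraction()` reads the smallest tabulated radius reaching
a target fraction from the *mean* curve over grid points — whether the 50%
reading refers to one point, the mean, or the best point was left open; the
mean is the least placement-dependent choice and the other readings are
recoverable from the per-point curves.

## Fiber extrapolation

With the cymba conchae assumed 100% vagally innervated, the sampled nerve
area extrapolates to myelinated fiber counts of the auricular vagus nerve.
Three relations define the model:

1. `A_AN = (A_CC / A_S) * A_SN` — the nerve area `A_SN` found in the
   sample of area `A_S` scales to the whole cymba+cavity area `A_CC`,
   modelled as an ellipse with full axes 20 x 15 mm (semi-axes 10 and
   7.5 mm; the full-axis reading of "major axis 20 mm" is the standard one
   and both axes are configurable);
2. `N_Adelta = (50/20) * N_Abeta` — A-delta and A-beta fibers make up 50%
   and 20% of myelinated axons, so their count ratio is 2.5 exactly;
3. `A_AN = N_Abeta * A_Abeta + N_Adelta * A_Adelta` — the extrapolated
   area closes over the two populations, with per-fiber areas from mean
   diameters 8.5 um (A-beta) and 3.5 um (A-delta).

Substituting (2) into (3) gives
`N_Abeta = A_AN / (A_Abeta + 2.5 * A_Adelta)`; the closure reconstructs
`A_AN` to machine precision and all outputs are linear in `A_SN`. Counts
are reals; display truncates (`floor(2.5 * 423) = 1057`, matching the
printed medians). What `A_S` denotes — the full image frame or the
per-slice ROI — cannot be determined from the source text; the ROI is the
default (consistent with `A_SN` being measured inside it) and the frame is
selectable via `area_basis = "frame"`. `occupancy_check()` computes the
share of `A_AN` filled by a reference population (370 A-beta fibers of
8.5 um): applied to the area reconstructed from the printed medians it
gives 61%, and because the epineurium (outer border) was segmented rather
than the axon bundle, nerve areas — and hence counts — are potential
overestimates.

```{r fibers}
m <- fiber_model()
solve_fiber_counts(34172.7, m)         # ~423 / ~1057.5
perimeter_distance_bounds(217, c(30, 71), c(20, 39))
occupancy_check(423 * m$a_abeta_um2 + 1057 * m$a_adelta_um2)
```

## The phantom

The imaging data behind the original study are not publicly deposited, so
the package carries a synthetic phantom generator whose defaults encode the
reported study conditions: 22 arteries and 15 nerves per cross-section,
artery diameters lognormal with median 41 um and log-SD 0.64 (reproducing
the 30–71 um IQR via the lognormal quartile relation
`q75/q25 = exp(2 * 0.6745 * sdlog)`), nerve diameters median 28 um with
log-SD 0.50 (20–39 um IQR), and companion nerves wired parallel to their
artery at a uniform 217–274 um centreline offset — the reported range of
minimum nerve–artery inter-centroid distances. Eight veins are added as
collapsed ellipses (axis ratio 4:1, area-preserving) since no vein counts
or sizes are reported; they carry no diameter contract. The default field
is 1024 x 768 px (1515.5 x 1136.6 um) over 200 slices — the stack size
used throughout the parameter-recovery tests — and tubes are straight and
axial by default (`tortuosity = 0`, `branching_probability = 0`): the
reported wiring ran mostly along the sectioning direction, and straight
tubes make ground truth exact. A low-frequency sinusoidal wander (shared
between companions, so wiring stays parallel) and a single Murray-law
bifurcation per artery are available as options.

Two floors keep the phantom out of measurement-uncertainty bands chosen
before any recovery test was run: artery diameters are truncated at 12 um —
the modelled population is arteries/arterioles strictly above the 10 um
capillary threshold, and the 2 um margin (~1.4 pixel pitches) keeps
rasterization noise from pushing a true arteriole below the filter — and
nerve diameters at 5 um. Packing is rejection sampling (100 retries per
element, then an explicit failure naming the class) with a 2 um surface
clearance, which also guarantees the class-disjointness invariant of the
masks.

What the phantom does *not* emulate: grayscale HREM texture, segmentation
error, obliquely running or truly tortuous vessels, capillary beds, and the
much larger real field of view (5522 x 3060 um). Consequently the phantom's
absolute distance, occupancy, coverage-radius and fiber-count statistics
sit at desk scale and are *not* comparable to the published sample values;
passing recovery tests show that the measurement pipeline is unbiased at
pixel resolution, not that the phantom is anatomically realistic.

## Numerical choices and limitations

* Rasterization counts pixels whose centres fall inside the tube; a radius
  under half a pixel pitch degrades to a single marked pixel with a
  warning, and an element centred outside the field rasterizes to nothing.
* Recovery tolerances in the tests are two pixel pitches (2.96 um) for
  diameters and centroid-derived distances — the worst-case band for a
  disk's pixelated area and centre at these radii.
* Problem sizes in the test suite: oracle comparisons run on random rasters
  up to 128^2 and phantoms of up to 20 tracks; the recovery test runs the
  full 1024 x 768 x 200 default phantom once.
* Ties in `radius_at_fraction()` resolve to the smallest tabulated radius;
  coverage fractions at untabulated radii are not interpolated.
* `summary_stats()` refuses empty input rather than returning NA — every
  empty summary upstream is a logic error, not missing data.
* Determinism: the generator consumes RNG in a fixed element order, so
  identical `phantom_config` (including `seed`) gives bit-identical masks,
  ground truth and downstream reports; `run_pipeline()` is tested to be
  byte-reproducible.
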