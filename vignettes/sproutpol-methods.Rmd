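---
title: "Quantifying directed migration, polarity and vessel morphometry with sproutpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directed migration, polarity and vessel morphometry with sproutpol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutpol)
```

# Scope

sproutpol quantifies the cell-biology readouts of scratch-wound migration
assays and 2-D vascular morphometry: per-cell migration statistics from
time-lapse tracking, nuclear-shape and organelle (Golgi/MTOC) polarization
angles, wound-closure kinetics, skeleton-based vessel branch-point counts,
vascular density, staining-intensity normalization, and the
set-intersection/sign-concordance step used to define co-regulated gene
sets from two differential-expression contrasts. Every estimator is paired
with a synthetic-data generator that produces inputs with known ground
truth, so the whole pipeline is testable without microscope data.

# Conventions

All physical quantities are in micrometres and minutes. Images use 0-based
pixel indices with a pixel-centre origin: x to the right, y downward in
image space. Angles are always computed after flipping to the y-upward
mathematical convention; directional angles live in [0, 360) measured
counter-clockwise with the migration direction at 0 degrees, and axial
angles (a nuclear long axis has no arrow) live in [0, 180). Sector
membership is boundary-inclusive, which keeps the statistic symmetric
under reflection about the sector centre.

The standard calibration is a 1784.22 um field imaged at 1920 px, i.e.
0.93 um/pixel at the conventional 2-decimal report; the unrounded value is
used internally (`pixel_size()`, `format_pixel_size()`).

# The trajectory model

`simulate_tracks()` draws biased persistent random walks on a frame grid
of 91 frames at 10-minute intervals (15 h), the standard imaging schedule
of the assay. At each step,

* the mean heading is the direction of the vector mixture
  `w * previous_heading + (1 - w) * migration_direction`, with
  `w = persistence_weight` in [0, 1];
* the realized heading is a von Mises draw around that mean with
  concentration `bias_kappa` (Best–Fisher sampler; `kappa = 0` is uniform,
  `kappa >= 1e6` collapses exactly onto the mean — the ballistic limit);
* the step length is the frame interval times a speed drawn from
  N(`speed_mean`, `speed_sd`) truncated at zero. The defaults,
  0.5 ± 0.15 um/min, are typical endothelial monolayer speeds.

Cells seed uniformly in a 1784.22 × 1000 um arena and are not reflected at
its boundary: tracks may leave the field, which leaves every statistic
computed here unchanged and avoids boundary-induced anisotropy.

Two useful limits anchor the tests. In the ballistic limit every track is
a straight line and directional persistence (net displacement over total
path) is exactly 1. In the isotropic limit (`kappa = 0`, `w = 0`) the
walk is a plain 2-D random walk; with N steps of comparable length the
expected persistence is approximately sqrt(pi)/(2 sqrt(N)) — about 0.09
for N = 90 — and displacement angles are uniform, so any fixed 120-degree
sector holds one third of them on average. Because the generative heading
distribution is von Mises, the probability that a single-step displacement
falls inside the scored sector has a closed form, which the acceptance
tests invert to pick concentrations with sector probabilities of exactly
0.5 and 0.9.

The simulation presets used in the demo ("control-like" `kappa = 8`,
`w = 0.3`; "knockout-like" `kappa = 0`, `w = 0`) are illustrative
parameter choices that produce clearly directed versus random migration;
they are not fits to any measured genotype.

# Migration statistics

`summarize_track()` reports, per cell: total migrated path (sum of
consecutive-frame step lengths), net displacement (first to last
position), average speed defined as total path over elapsed time (the
path-based definition; the displacement-based rate is also emitted as
`displacement_speed_um_min` since the two are often conflated),
directional persistence = net/total (defined as 0 and flagged for
zero-path tracks), the displacement angle relative to the migration
direction, and instantaneous speeds and distance-from-origin sampled on a
30-minute grid (every third frame at 10-minute imaging; nearest-frame
snapping when the grids misalign).

`sector_fraction()` is the polar-plot statistic: the fraction of angles
within half the sector width (circular distance, boundary inclusive) of
the sector centre, conventionally a 120-degree window centred on the
direction perpendicular to the scratch. Cells with zero net displacement
have no angle; they are excluded from the sector count but reported in
`n_total`, so a population of frozen cells cannot masquerade as polarized.

`wound_closure()` implements the assay's closure arithmetic: closure
percent is (W0 − Wt)/W0 × 100 and the closure rate divides the 0-to-15-h
width difference by the elapsed 900 minutes. Wound width on a rendered
mask is measured as the mean background run between the two monolayer
margins across rows intersecting the gap; the mean (rather than the
minimum) is robust to single-row mask noise.

# Tracking

`detect_centroids()` thresholds a single channel and labels 8-connected
components (the 4-connected labeller underneath is augmented with a
union-find merge across diagonal adjacencies); each component above the
area cutoff yields an unweighted pixel-centre centroid. `link_tracks()`
uses greedy global nearest-neighbour linking: all candidate pairs between
consecutive frames, sorted by ascending distance in micrometres, accepted
while within `max_step_um` and unassigned. Unmatched detections start new
tracks; a track that misses a frame terminates (no gap closing, merging,
or splitting — the assay tracks well-separated cells). Ties break on the
lower (previous, current) index pair after a canonical within-frame sort,
so linking is deterministic and invariant to detection order. Greedy
linking is O(n log n) and coincides with the exact minimal-total-distance
assignment whenever the geometry is unambiguous, which the tests verify
against a brute-force assignment oracle on instances of up to six cells.

# Nuclear shape and polarity

`fit_nucleus()` reports orientation from the principal axis of the second
central moments of the pixel-centre cloud (with the 1/12-pixel variance
term, so small shapes are unbiased). Height is the caliper extent along
that axis and Width is the minimum caliper extent over all orientations
(0.5-degree grid, pixels treated as unit squares by adding one pixel size
to the centre-to-centre extent). For elliptical shapes — the regime of
real nuclei — the minimum caliper coincides with the extent perpendicular
to the long axis, so ellipticity = Height/Width is the classic long-axis
over maximum-perpendicular-extent ratio and is at least 1 by
construction. The rotating-calipers width was chosen over the literal
perpendicular extent because it keeps that guarantee for shapes with
ambiguous principal axes (for a square the two definitions diverge; the
caliper definition gives the diagonal-over-side ratio sqrt(2) rather than
the uninformative 1). When the second moments are isotropic the
orientation falls back to the direction of maximum caliper extent, with
the smallest such angle winning ties. Masks with a minimum caliper below
1.5 px are rejected as line-like degeneracies.

`nuclear_angle_first_quadrant()` folds the axial orientation into [0, 90]
as `90 − axial_distance(orientation, migration_direction)`: a long axis
aligned with the migration (filopodia-extension) direction maps to 90
degrees, one lying along the scratch to 0.

`organelle_polarization_angle()` is the direction of the vector from the
nucleus centre to the organelle centroid, counter-clockwise from the
reference. `polarized_fraction()` applies the sector statistic to those
angles; `front_rear = TRUE` also accepts the antipodal sector, the
"anterior **or** posterior of the nucleus" readout used for tip-cell Golgi
polarization, where a formal single-sided convention does not exist.

# Vessel morphometry

`vascular_density()` is the foreground fraction of the ROI as a
percentage. `radial_outgrowth()` splits the plane into equal angular
sectors about the optic-disc position (four by default, approximating
retinal leaflets, whose anatomical boundaries the mask does not encode)
and averages the per-sector maximum centre-to-foreground distance,
excluding empty sectors with a warning. `front_counts()`,
`area_fraction_metrics()` and `normalized_intensity()` are the standard
per-100-um front normalizations, leakage/tuft area ratios and
background-subtracted control-normalized intensity fold changes;
background subtraction clips at zero and a result where background
exceeds signal in every ROI is returned as 0 with a flag rather than a
negative fold change.

`branch_points()` counts junctions in three stages. The mask is first
thinned to a skeleton (Zhang–Suen, vectorized over the image). Each
skeleton pixel is then classified by counting the arcs in which the
vessel *mask* crosses a Euclidean annulus of radius `merge_radius_um`
(about twice the stroke width) around it: a plain stroke crosses such a
ring in exactly two arcs, a branching stroke in three or more. Arcs are
angular clusters of annulus pixels (connected to the centre pixel within
the window) separated by gaps wider than about two pixels of arc; an arc
must contain at least three annulus pixels, so stray fringe pixels where
a stroke cap grazes the annulus cannot register as branches. Classifying
on the mask rather than on the skeleton matters: thinning displaces
junctions into the wedge where strokes overlap and can merge two branches
tangentially, so skeleton-local degree tests (3×3 neighbour counts or
crossing numbers) both over- and under-count; ring arcs of the mask are
immune to those artifacts. Finally, flagged pixels within
`merge_radius_um` of each other merge into single branch points by
single-linkage clustering, and points inside the ROI are counted. The
method is reliable when junctions are separated by at least about five
stroke widths — the regime of the plexus images it emulates, and the
regime the synthetic generator guarantees. The original measurement was
manual, so these automation parameters are this package's own.

# The synthetic-data generators

Each generator emits the ground truth its downstream estimator needs, and
every generator takes an explicit seed (no global RNG state).

* Trajectories: the biased persistent random walk above.
* Polarity images: hard (un-anti-aliased) binary ellipses for nuclei and
  discs for organelles at stated angles and distances, so moment/caliper
  recovery has analytic expectations; Gaussian noise goes on a separate
  intensity channel and never on the masks (`noise_sd` default 0).
* Wound series: binary monolayer masks whose vertical gap narrows
  linearly at the programmed rate, both margins advancing symmetrically,
  clipped at closure.
* Vessel networks: junction points placed by rejection sampling with a
  minimum separation, connected by their Euclidean minimum spanning tree
  (non-crossing by construction), with short stubs added until every
  junction has degree >= 3. Layouts with incident edges closer than 45
  degrees are rejected (shallow wedges displace skeleton junctions), stub
  directions need 60 degrees of clearance, and whole stubs must keep
  clear of non-incident strokes. The stroke width is solved from the
  requested foreground fraction and must stay below one eighth of the
  junction separation, so a 512×512 px field at 2 um/px supports
  densities of roughly 2–7% with 12 junctions; the recorded ground-truth
  density is the exact rendered foreground fraction, whatever the
  request. Within that regime branch-point recovery is exact.
* DEG tables: two tables over a shared gene namespace whose significant
  sets intersect in exactly `n_common` genes, of which exactly
  `n_concordant` share the fold-change sign. A zero log fold change is
  treated as neither up nor down, so it can never count as concordant.

What the generators do **not** emulate: optics (no point-spread function,
shot noise, or illumination gradients), cell division, death, contact
interactions, out-of-focus organelles, 3-D structure, or vessels of
varying calibre. Passing recovery tests therefore demonstrates the
correctness of the estimators' geometry and statistics, not robustness to
real microscopy artifacts; on real data the detection and thresholding
steps carry assumptions (explicit global thresholds, well-separated
cells) that must hold for the downstream numbers to be meaningful.

# Numerical choices and degenerate inputs

* Orientation grid for calipers: 0.5 degrees; orientation errors from the
  grid are below the 3-degree recovery tolerance by an order of
  magnitude.
* Moment-isotropy cutoff for the orientation fallback: eigenvalue spread
  below 1e-3 of the trace.
* Zero-path tracks: persistence 0 with a `zero_path` flag; zero-net
  displacement tracks: angle NA, excluded from sector counts, kept in n.
* Empty masks: detectors return empty tables; `branch_points()` returns
  0; `radial_outgrowth()` errors (a front distance needs foreground).
* Ratios: zero sprouts with nonzero filopodia gives an NA per-sprout
  ratio with a flag; a zero-area denominator mask is an error.
* Frame grids must be consecutive for linking; gaps terminate tracks by
  design, not silently bridge them.

# Problem sizes

The test suite and the acceptance script use 1000 cells × 91 frames for
population statistics (binomial 3-SE bands), 200 rendered nuclei for
shape recovery (median errors), 20 vessel networks of 12 junctions at 4%
density for exact branch-point recovery, and 100 random DEG table pairs
against a nested-loop oracle. These sizes put Monte-Carlo bands well
inside the tolerances while keeping a full run in the low minutes on one
CPU.
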