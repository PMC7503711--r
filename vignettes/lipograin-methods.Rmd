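---
title: "Quantifying lipoprotein particles in positive-contrast electron micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipoprotein particles in positive-contrast electron micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipograin)
```

## The measurement problem

Plasma lipoproteins (HDL, LDL, IDL, VLDL and chylomicrons) are
nanoparticles of 10–80 nm whose size distribution carries clinical
information. In mixed-metal methylcellulose (MC) embedding — uranyl
acetate plus sodium silicotungstate in a thin MC film — particles appear
in *positive* contrast: a dark rim around a slightly darkened interior on
a bright background. Thin films additionally make the flattened
(oblate-spheroidal) particles lie *en face*, so each projected profile is
close to the particle's maximal cross-section.

`lipograin` packages the downstream computational workflow around such
micrographs:

* **morphometry** — calliper diameters, moment-equivalent axes, the
  spheroid orientation correction, binned size distributions,
  edge-contrast profiles and the SEC fraction trend fit;
* **sampling** — unbiased selection rules (central window with a 50 %
  area criterion, forbidden/acceptance scanning lines, systematic
  uniform random fields);
* **immunoquant** — antibody "blob" attachment, labelled fractions and
  saturation, aggregate censuses with chi-square comparisons;
* **segmentation** — a classical radial-symmetry instance segmenter that
  runs without trained weights;
* **seg_eval** — detection rate, false detections per 100, COCO-style
  mAP over IoU 0.50–0.95, Bland–Altman size agreement and
  overlapping-pair counts for *any* instance segmentation;
* **synth_scene** — a seeded simulator with complete ground truth, which
  is how every stage above is tested.

## Calliper measurement and the spheroid correction

Sizes are measured as the **horizontal calliper diameter**: the full
column extent of a particle mask (inclusive of both end pixels) times
the calibration. Because particles land with arbitrary in-plane
orientation, a fixed measurement direction is a random direction with
respect to each particle, which keeps pooled distributions unbiased and
the measurement fast and reproducible.

En-face adsorption means calliper values approximate *maximal* diameters.
To compare with methods sensitive to rotationally averaged size, the
package corrects a measured diameter $D$ to the mean axis length of the
corresponding oblate spheroid with the LDL reference shape (major
21.4 nm, minor 12.1 nm, ratio 1.77):

$$D_{eq} = D \cdot \frac{2 + r}{3}, \qquad r = \frac{12.1}{21.4},$$

i.e. the measured diameter supplies the two equal axes and $D\,r$ the
short axis. The wording "mean radius of a corresponding spheroid" admits
several readings; the arithmetic mean of the three axes is the one
consistent (to within one unit in the second decimal) with all four
corrected values the correction is known to produce, and it is linear
and exact for a sphere ($r = 1$). Note that with the *printed* reference
axes the factor is $0.85514$, which reproduces published corrected
values only to about $\pm 0.01$ nm — quotients in print were evidently
formed from unrounded means. The package computes, and its tests assert,
the values implied by the stated inputs.

```{r}
spheroid_equivalent_diameter(c(23.41, 23.82, 24.00))
glance(summarize_sizes(spheroid_equivalent_diameter(c(23.41, 23.82, 24.00))))
```

Summaries use the sample SD ($n-1$), CV in percent, and 2-nm half-open
bins labelled by their lower limit, with relative frequencies summing to
100 %.

## The synthetic scene generator

No public micrographs accompany this workflow, so the simulator *is* the
test bed. A scene is defined by `scene_params()`; its defaults are the
study conditions the rest of the package is validated under:

* **Sizes.** Each particle draws a calliper diameter from a normal
  distribution (default mean 23.7 nm, SD 2.5 nm) truncated at 14 nm, the
  lower limit at which particles are distinctly contrasted in these
  preparations. The drawn value is defined as the *horizontal extent* of
  the rendered ellipse: the natural-seeming alternative of drawing the
  major axis cannot make measured callipers recover the generating mean,
  because averaging a random in-plane orientation shrinks the mean
  horizontal extent of the major axis by ~11 % at ratio 1.29. Drawing
  the observable itself makes the generator emulate exactly the
  distributions that are reported from real micrographs.
* **Orientation/aspect.** The projected major/minor ratio is drawn from
  a truncated normal: mean 1.29, SD 0.08 in thin-film mode (particles
  near en face) and mean 1.42, SD 0.15 in thick-film mode. Only the mean
  ratios are empirically anchored; the distributional family was chosen
  for controllability.
* **Rendering.** Bright background (grey 200 of 255), interior 150, rim
  60 (thin mode; thick mode uses 190/165/110, giving the weaker edge
  contrast of thick films), antibody blobs 25, sub-14-nm clutter discs
  180 at 100/µm². Gaussian blur (σ 1.2 px) then additive noise (SD 6)
  then rounding to 8-bit. Grey levels are free parameters of the
  simulator — no stain-physics model is attempted.
* **Geometry.** 1400×1400 px at 0.6 nm/px by default, which puts median
  particles near 40 px linear size, matching realistic annotation
  statistics. Particle centres are *continuous*, so the pixel
  quantisation of the calliper is unbiased; placement is rejection
  sampling with a minimum gap, except inside deliberately placed
  touching chains (default: 10 % of particles in chains of 2–4).
* **Labelling.** A chosen fraction of particles receives 1 + Poisson
  antibody blobs (7–22 nm, mean 13.37 nm, SD 3.55 nm truncated) attached
  at the rim with a ~1 px overlap.

Identical parameters (including the seed) give bit-identical scenes.

What the simulator does *not* emulate: stain granularity, contrast
transfer, support-film texture, extracellular-vesicle collapse
morphology, and the spatially varying background of protein-rich plasma
fractions. Tests passing on synthetic scenes therefore demonstrate
algorithmic correctness under the stated image model, not performance on
arbitrary real micrographs.

## The baseline segmenter

`segment_particles()` is a deterministic classical detector standing in
for a trained instance-segmentation model (the evaluation suite is
architecture-agnostic — any model's masks can be dropped in):

1. Gaussian smoothing (σ 1.5 px) and central-difference gradients.
2. **Radial-symmetry voting**: pixels in the top 8 % of gradient
   magnitude (with an absolute floor of 8 grey levels/px, so featureless
   images cast no votes) vote *down* their gradient at every radius in
   the expected range (default diameters 14–80 nm). Rim pixels thereby
   vote toward their particle's centre; the smoothed accumulator peaks
   near centres.
3. **Peaks**: local maxima above `detection_threshold` (0.8) of the vote
   mass an ideal minimum-radius circle would cast, with non-maximum
   suppression at 1.8 × the minimum radius (an ellipse's rim normals
   focus on its evolute, which can produce twin peaks ~0.8 radii apart —
   the suppression window absorbs them).
4. **Foreground**: pixels darker than 42 % of the way from the
   background level (median grey) to the dark level (0.002 quantile),
   holes filled, then eroded by 1 px. The threshold fraction and erosion
   were calibrated on synthetic scenes so that the mask boundary falls
   on the outer rim transition: 2-D blur otherwise bleeds darkness
   outward at the high-curvature ends of each ellipse and inflates
   calliper measurements by ~1 px per side. After calibration the pooled
   calliper bias of segmented masks is below 0.1 nm.
5. **Instances**: distance-map watershed (tolerance 4) splits merged
   blobs; each region must contain a vote peak (regions without seeds —
   clutter, debris — are dropped); regions with several seeds are split
   by nearest seed. Masks failing the area floor or whose area-equivalent
   diameter leaves the expected range are discarded (hard filter).

Each instance's confidence is its normalised vote mass, which gives the
score ordering mAP needs. On default scenes (200 particles, 10 %
aggregated) the detector achieves ~98 % detection, ~2.7 false detections
per 100, and mAP ≈ 0.9 against ground truth.

Numerical caveat: the pipeline is deterministic, and structurally
equivariant under 90° rotations, but FFT-based blurring and watershed
tie-breaks can move single boundary pixels, so rotation equivariance is
exact for counts and holds to within a few percent for individual areas.

`detect_blobs()` finds antibody densities as the darkest compact
components outside particle masks, keeping components whose
area-equivalent diameter lies in 7–22 nm (±1.5 nm margin for rim
occlusion) and whose fill fraction against their bounding circle is at
least 0.4 (which rejects rim-halo fragments). Under single-hit
labelling, blob recall against simulator truth exceeds 90 %; at ~3 blobs
per particle neighbouring blobs can coalesce into one component — a
known limitation.

## Selection rules

* `window_filter()` keeps instances with ≥ 50 % of their area inside the
  central evaluation window (default 820 px); predictions and ground
  truth pass through the same rule before evaluation.
* `band_select()` implements the forbidden/acceptance-line rule: events
  strictly between the lines or touching the acceptance line are
  counted; anything touching the forbidden line is excluded, *including*
  events that touch both (the standard unbiased counting-frame
  convention; the tie case had to be decided here). "Touching" means the
  mask intersects the 1-px line row. The expected count is proportional
  to the line separation and independent of particle size, which the
  test suite verifies by Monte Carlo.
* `sur_sample_positions()` lays a field grid with one random phase and
  takes every $\mathrm{round}(1/f)$-th field from a random start —
  systematic uniform random sampling.

## Immunolabel and aggregation quantification

A blob attaches to a particle when the masks lie within `max_gap_px`
(default 2 px, minimum Euclidean pixel distance); each blob goes to its
nearest qualifying particle and unassigned blobs are reported as
unbound. Aggregates are connected components of the "touching" relation
(Chebyshev distance ≤ 1 px by default), categorised as {1, 2, 3, ≥4}
component particles. Census pairs are compared with a 2×4 Pearson
chi-square (df 3); zero-expectation categories are pooled tail-first
(≥4 into 3, then 3 into 2) so the sparse tail is preserved longest.

`redistribution_percent()` reports antibody-induced aggregation as the
drop (percentage points) in the share of particles found as singles or
in 2–3-particle aggregates. The share is *particle-weighted* (a
category-k event contributes k particles, ≥4 events their recorded
sizes): "percent of particles redistributing" implies particle
weighting, but since the computation is an interpretation the
event-weighted figure is attached as an attribute.

## Evaluating a segmentation

`match_instances()` performs greedy one-to-one matching in descending
IoU (ties: higher prediction score, then lower index), `detection_stats()`
reports the percentage of truths matched and unmatched predictions per
100 predictions ("per 100 detections"; the denominator choice is
documented because usage varies), and `mean_ap()` computes COCO-style
average precision — score-ordered greedy matching, precision-envelope
(all-point) interpolation — averaged over IoU 0.50 to 0.95 in steps of
0.05. The mean is the default aggregate; `aggregate = "median"` is
available since the phrase "median average precision" also circulates
for this metric. Overlapping-pair counts dilate each mask by 1 px
(8-connected structuring element — connectivity had to be fixed here)
and count intersecting pairs. Bland–Altman agreement uses differences
`a − b`, bias ± 1.96 sample SD.

Degenerate inputs are reported as not-a-value rather than errors where
the statistic is genuinely undefined (no truths → detection rate `NaN`;
constant response → trend R² `NaN`).

## Problem sizes used in the shipped checks

The packaged tests validate the full pipeline on 20 simulated scenes of
200 particles (thin film, mean 23.7 nm) for recovery of detection rate
(≥ 95 %), false detections per 100 (≤ 5) and mean calliper (within
0.5 nm of truth); labelled-fraction recovery pools 1000 particles at a
generating fraction of 36.6 % against the exact binomial 95 % interval;
distributional recovery uses 1000 particles at 0.3 nm/px so pixel
quantisation stays below the Kolmogorov–Smirnov resolution. Oracle
comparisons (optimal assignment, union-find, brute-force dilation
overlap) run on scenes small enough for exhaustive enumeration.

## Known limitations

* The simulator's image model is stylised; none of the calibrated
  thresholds are claimed to transfer to real micrographs unchanged.
* The baseline segmenter assumes dark-rimmed convex particles on a
  bright background; it does not handle sub-14-nm material, heavily
  overlapping rouleaux, or negative-stain contrast.
* Blob coalescence limits per-particle density counts at high labelling
  multiplicity.
* The spheroid correction presumes every measured profile is en face
  with the LDL aspect ratio; particles imaged edge-on or with other
  aspect ratios are corrected with the wrong factor.
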