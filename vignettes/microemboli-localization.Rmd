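---
title: "Localizing microemboli from serial block-face images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing microemboli from serial block-face images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Injecting ~20-µm fluorescent microspheres into the carotid circulation of a
mouse lodges beads in small penetrating vessels, modelling brain-wide
microembolism. Characterizing where each of the hundreds of retained beads
ends up is the scientific payload — regional microinfarct load — but doing it
from mounted histology is slow and error-prone. Block-face imaging sidesteps
most of that: a camera photographs the cut surface of the ink-darkened tissue
block before every vibratome section, so the brain keeps its native geometry
and each bead is imaged in place. This package implements the complete
downstream computation: from raw image series to a per-structure count,
proportion and density table over a hierarchical brain ontology, plus the
statistics used to validate such a workflow against human raters.

## The model, stage by stage

**Geometry and calibration.** A `blockface_stack` is an ordered, anterior-first
series of 8-bit images with in-plane calibration $s$ (µm/px; default 6.5) and
section thickness $T$ (µm; default 100). $T$ is the axial resolution of the
whole method: nothing downstream can localize a bead more precisely than the
section it was cut away with.

**Orientation and alignment.** The user draws the brain midline on one
section; the whole stack is rotated by the single angle that makes that line
vertical, on an expanded canvas so nothing is clipped. Sections are then
registered to their neighbours under a rigid-body model (rotation +
translation only — the tissue block does not scale or shear between
photographs). The translation is estimated by phase correlation (FFT
cross-power spectrum, 3-point parabolic sub-pixel refinement) and the
rotation by a bounded search (0.5° grid, then golden-section refinement)
maximizing the correlation peak. Pairwise transforms are chained to the
middle section, which halves accumulated drift relative to chaining to an
end. On synthetic perturbations the residual is below 0.1 px / 0.15°; the
test suite requires 0.5 px / 0.2°.

**Detection.** Beads are segmented by a fixed threshold on the green channel:
intensities in $[140, 255]$ of the 8-bit range are bead signal, below 140 is
background. The printed band boundaries in this field place 140 in both
classes; we classify $\ge 140$ as signal (`threshold_low` is a parameter).
Manual annotations (clicked points) are dilated to 20-µm disks so both
sources run through identical downstream logic.

**z-resolution by serial subtraction.** Beads are visible through up to
$D \approx 400$ µm of tissue, so one bead appears in up to
$\lceil D/T \rceil = 4$ consecutive images before it is cut away. The bead's
true section is the *last* image it appears in. Implementation: a connected
component in section $i$ survives iff no component of section $i+1$ lies
within `match_radius_px` (default one bead diameter) of its centroid. The
"any match suppresses" rule is deliberate: under noise the dimmest, deepest
appearance of a bead can shatter into several fragments, and all of them must
be absorbed by the brighter appearance one section deeper — a one-to-one
assignment would leave orphan fragments behind as false beads. A literal
pixelwise mode (`mode = "pixel"`, $m_i \wedge \neg m_{i+1}$) reproduces the
classic mask subtraction. Chains longer than $\lceil D/T \rceil$ sections are
split from the deep end with a warning. The whole construction is validated
against an independent brute-force oracle (`label_sphere_chains_3d()`):
26-connectivity labelling of the stacked masks, whose component maxima are
the true z-planes by definition.

**Atlas mapping.** Each section receives a linear 2D→3D mapping
$p(x, y) = o + \frac{x}{W}u + \frac{y}{H}v$, where $o$ is the atlas position
of the image's top-left corner and $u, v$ span the image width and height
(the QuickNII convention; coordinates are continuous 0-based voxel indices,
pixel-corner convention $x \in [0, W)$). Users anchor a handful of sections;
`propagate_anchors()` interpolates each component of $(o, u, v)$ linearly in
section index between anchors, extrapolates the nearest segment's trend
outside the anchored range, and with a single anchor advances $o$ along the
anterior-posterior axis by $T$ per section. Interpolating $u, v$ as well as
$o$ is a choice — whether anchoring tools interpolate angles between anchors
is not standardized — so `mode = "ap-only"` holds the in-plane vectors at the
nearest anchor instead. Hemispheres come from per-section midline polylines:
signed horizontal offset at the detection's $y$, ties broken to "right" so
output is deterministic, and undelineated sections inherit the nearest
delineated polyline.

**Ontology assignment and reporting.** The annotation volume is an integer
label array (isotropic voxels; label 0 = outside the brain). Lookup is
nearest-voxel; coordinates outside the volume or on label 0 are
*unaccounted*, which is a reported category, not an error. Counts roll up the
ontology (level 1 = root, level 2 = gray matter / fiber tracts / ventricular
systems, down to level 12). Terminal reporting branches follow the
minimum-count criterion: a structure is subdivided only while it holds at
least `min_count = 5` beads (the criterion is applied to the node being
expanded; a flag applies it to each child instead). The resulting frontier is
mutually exclusive and exhaustive, so terminal counts plus unaccounted always
equal total detections — the package recounts by walking each detection up
the tree, making conservation true by construction rather than by arithmetic
luck. Densities divide counts by structure volume (cumulative voxel count ×
voxel volume, both hemispheres). In the totals row, counts and proportions
are sums and the density is the mean of per-region densities, matching the
convention of printed regional tables. Proportions use total detections
including unaccounted as the denominator.

**Validation statistics.** `agreement_by_level()` compares two allocations of
the same beads at every ontology level: *agreement* if both level-$k$
ancestors exist and match, *not at this level* if the reference structure
does not extend to level $k$, else *disagreement*; *sum of agreement* is the
first two. Note that the sum of agreement is guaranteed monotone
non-increasing with depth only when beads whose reference branch terminates
early agreed at their terminal level (true in rater data of this kind);
agreement alone is always non-increasing and not-at-level always
non-decreasing, which is what the property tests assert. Percentages round
half-up to one decimal, matching printed tables (base R's round-half-even
would turn 88.46% into 88.5% but 93.85% into 93.8%). Pearson correlation and
t tests delegate to `stats::cor.test()` / `stats::t.test()`; the independent
t test uses pooled variance (Student's) because that is the named test in
this literature, with Welch available via `welch = TRUE`. Tests of these
wrappers compare against closed-form hand computations, not against the same
library call.

## The synthetic-data generator

Everything above is testable without any atlas download because the package
generates its own ground-truthed world.

* `generate_toy_atlas()` builds an ellipsoidal brain in a label volume
  (default 96 × 80 × 96 voxels at 25 µm) with a rooted ontology: level 2
  splits into gray matter / fiber tracts / ventricular systems, deeper levels
  subdivide boxes along alternating axes down to `depth = 7` by default.
  Children tile their parent exactly, so volumes are additive. Some branches
  terminate early — one ventricular subregion always does, others at random —
  so "not at this level" is exercised. Two deliberate geometric choices make
  the generator's ground truth *attainable* by a section-resolved method:
  the brain outline is held constant within each 100-µm slab along the
  cutting axis (exactly what a volume reconstructed from serial sections
  looks like), and region boundaries along that axis fall on section
  boundaries. Each section's mapping anchors it at its mid-plane. Without
  these, a bead near the curved surface or near an axial region boundary
  could be unassignable from section-level data by *any* method, including
  the one being modelled.
* `generate_scene()` samples bead positions uniformly over labelled voxels
  (or weighted per region), jittered within the central 60 % of their voxel
  and with a 60-µm minimum in-plane separation between beads within 500 µm
  of each other axially — beads lodge in distinct vessels and essentially
  never overlap in projection. The default bolus is 2000 beads, a typical
  injected dose.
* `render_blockface_stack()` draws, for every section, the dim tissue
  foreground (intensity 40) on black, then each bead visible from that
  surface: full green intensity 255 when surfaced, attenuated linearly to
  140 (the detection threshold) at the 400-µm visibility depth, with the
  disk widened by 10 % per 100 µm of depth as a scatter halo. An exponential
  attenuation curve is available; both reach exactly the threshold at the
  visibility depth, so noise-free renders are fully detectable by
  construction — the generator makes no claim about real intensity
  histograms, only about satisfying the threshold contract. Per-section
  integer translation jitter, rotation jitter and Gaussian pixel noise are
  applied after rendering; the ground-truth table is never touched by
  either.
* `generate_chain_stack()` + `label_sphere_chains_3d()` are the dedicated
  oracle pair for the serial-subtraction logic: random disk chains (≤ 4
  sections, ≤ 2 px drift per section, integer-aligned centres so adjacent
  appearances always overlap) versus brute-force 3D connectivity labelling.

What passing these tests shows — and does not. They demonstrate that the
pipeline's logic is correct wherever its assumptions hold: high-contrast
beads on a dark background, rigid inter-section motion, beads separated by
more than a diameter, and an annotation consistent with the imaged geometry.
They do not demonstrate robustness to autofluorescence, uneven illumination,
tissue deformation, beads in optically deep white matter, or anchoring error
by the human operator, none of which the renderer emulates.

## Numerical choices and degenerate inputs

* Interpolation: bilinear for intensity images, nearest-neighbour for masks
  (masks must stay binary; component counts are preserved under rigid
  motion).
* Brain-area segmentation for volume: foreground is max-over-channels > 15
  of 255; the embedding is black by design and any small threshold works —
  15 clears sensor noise while keeping dim tissue.
* Detection area band: 0.25–4 × the nominal disk area of one bead at the
  given pixel size; oversize blobs are flagged merged and split by a
  watershed on the distance map (tolerance 0.5 px, low enough to separate
  twin beads whose distance-map saddle is shallow). The band is
  configurable and can be disabled; whether any size filter was used in the
  original workflows is unstated.
* Phase correlation on an all-black section is meaningless: such sections
  get an identity transform and a warning, never an error.
* Paired t test on identical samples returns $t = 0, p = 1$ (the defensible
  limit); constant *nonzero* differences are a zero-variance error.
* Empty scenes, empty masks, empty count tables and zero-bead regions all
  return empty/zero results rather than failing; a nonzero count in a
  zero-volume region is an error because the density is undefined.

## Problem sizes used by the test suite

The packaged simulations are sized for a thorough but quick run: the
end-to-end recovery tests use one 500-bead scene in a depth-7 toy atlas
rendered to 24 sections of 370 × 308 px (noise-free, and with noise
SD 10 / ±1 px jitter), and the oracle-equivalence test sweeps 200 random
mask stacks of up to 20 sections and 50 chains. These sizes keep the whole
suite under a few minutes while leaving every code path exercised at
realistic per-section bead densities (~10–20 visible beads per image, as in
real injections).

## Known limitations

* Registration is rigid by design; slide-mounted histology with tissue
  deformation needs elastic registration, which is out of scope.
* Anchoring quality is the accuracy ceiling: mappings are linear per
  section, so operator anchoring error translates directly into assignment
  error, and nothing in the package can detect it.
* Sub-resolution localization is not attempted: a bead's axial position is
  its section, full stop.
* The toy atlas is a geometric stand-in with box-shaped regions; it shares
  the real ontology's *structure* (hierarchy, early-terminating branches,
  label volume semantics) but not its anatomy.
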