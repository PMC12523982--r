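---
title: "Phase-image morphometry, tube networks and potency estimation: models and design"
author: "qpihuvec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-image morphometry, tube networks and potency estimation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpihuvec)
```

# The measurement model

Quantitative phase imaging delivers, per pixel, the phase shift of
light through the specimen. qpihuvec stores images as optical path
difference (OPD) in micrometres,

$$\mathrm{OPD}(x, y) = \frac{\phi\,\lambda}{2\pi} = (n_o - n_m)\, t(x, y),$$

where $n_o$ and $n_m$ are the refractive indices of cell and medium
and $t$ the physical thickness. Three phase-specific metrics follow:

* **Dry mass.** Biomass concentration raises the refractive index
  linearly with the specific refractive increment $\alpha$, so the
  nonaqueous mass of a segmented object is
  $M = \sum \mathrm{OPD} \cdot A_{px} / \alpha$ (pg). The instrument
  vendor does not publish its $\alpha$; we default to the
  literature-standard protein value 0.18 mL/g (= 0.18 µm³/pg),
  configurable in `optics_config()`.
* **Optical thickness.** The OPD itself, reported per object as mean
  and maximum over object pixels. Which convention the commercial
  analysis tool uses is unpublished; the mean is our headline field.
* **Sphericity.** The thickness map $t = \mathrm{OPD}/(n_o - n_m)$ is
  a 2.5-D surface. With object volume $V = \sum t\,A_{px}$ and upper
  surface area $S = \sum \sqrt{1 + |\nabla t|^2}\,A_{px}$
  (central-difference gradient), sphericity is
  $\Psi = 2\pi r^2 / S$ with $r = (3V/2\pi)^{1/3}$ — the curved
  surface of the *equal-volume hemisphere* over the measured surface.
  A hemispherical (fully rounded, substrate-attached) cell scores
  exactly 1; a flat spread endothelial cell scores far lower. We use
  the hemisphere reference deliberately: it is the stated convention
  of the assay this package models, and it makes the upper bound
  attainable by an adherent cell. $\Psi$ is clipped to $(0, 1]$
  because discretisation of near-hemispherical caps can overshoot the
  ideal surface slightly. Note $\Psi$ is **not** invariant to the
  assumed refractive contrast $\Delta n = n_o - n_m$ (volume and
  surface scale differently), so $\Delta n$ must be held fixed within
  a study; the defaults are 1.377/1.337.

Shape descriptors that do not need phase: object area (pixel count ×
pixel area, no subpixel correction), and the length/width ratio from
the second-order central moments of the binary footprint (equivalent
ellipse, with the 1/12 px² pixel-extent correction). Moments rather
than bounding boxes make the ratio rotation invariant, which the test
suite checks at 37°.

# Segmentation

The commercial segmentation used in the original assay is
unpublished, so `segment()` is a documented, reproducible stand-in
honouring the same contract:

1. Gaussian smoothing of the OPD topography (default σ = 2 µm).
2. Otsu threshold on the smoothed raster → confident **core** pixels.
3. **Support** mask: raw OPD above a small floor (default 1e-4 µm).
   Support components containing at least one core pixel become
   objects; the rest are discarded. This hysteresis recovers the
   faint rim of each cell, which matters because the dry-mass
   integral is dominated by no single pixel: a plain global threshold
   clips enough rim to violate mass conservation at the 1% level.
4. Touching cells are split by an h-maxima watershed on the smoothed
   topography (`watershed_tolerance` = minimum OPD prominence of a
   seed, default 0.05 µm; `min_seed_separation` default 10 µm).
   Watershed labels are **intersected with the support components**:
   the watershed may split a component but never fuse two, since its
   neighbourhood search can bridge narrow background gaps.

Limitations worth knowing: the single global Otsu threshold assumes
the field's objects have broadly comparable peak OPD. A field mixing
very flat cells with much taller objects can push the threshold above
the flattest cells' peaks; for synthetic studies we therefore render
mixed-size populations at a uniform apex height (1 µm), and for real
data the support floor should be raised to ~3× the background noise
SD. The debris gate (`apply_size_gate()`) keeps objects strictly
*over* 400 µm² by default, reading the protocol's wording as a strict
inequality; a flag switches to `>=`.

# Tube networks

`make_tube_mask()` binarises (smoothed Otsu, hole filling below a
configurable area, removal of sub-400 µm² specks), and
`skeletonize_and_graph()` converts the mask into a planar graph in
the field's vocabulary: **segments** (edges), **junctions** (nodes of
degree ≥ 3), **extremities** (free endpoints, degree 1) and
**branches** (segments with at least one extremity).

Numerical choices, each of which was forced by a measurable failure
of the more obvious alternative:

* **Thinning: Guo–Hall, not Zhang–Suen.** Zhang–Suen leaves 2-pixel
  staircases on diagonal strokes; the neighbour-count classifier then
  misreads entire diagonal tubes as junction pixels. Guo–Hall keeps
  diagonals one pixel wide and is idempotent on already-thin
  skeletons (tested).
* **Arc length: resampled Euclidean, not chain steps.** The classic
  1/√2 chain metric overestimates a straight tube at intermediate
  angles by up to ~8% — a 100 µm Y-arm at 30° measures ~107 µm. Edge
  lengths are instead the Euclidean length of the traced pixel path
  resampled every 5 px, which is orientation-unbiased for straight
  tubes and biased only O((s/R)²) for curvature radius R; a ring of
  radius 80 µm measures within 0.1%.
* **Junction refinement.** The medial axis of a thick T- or
  Y-junction genuinely meets ~0.8 tube radii inside the joining arm,
  which shortens short segments noticeably (−14% on an 80 µm lattice
  tie at 16 µm tube width). Each junction node is therefore moved to
  the least-squares intersection of its incident branch axes, with
  branch directions fitted over a window just outside the junction
  blob (blob radius from the distance transform). After refinement
  lattice tie lengths are exact; the residual ~2% deficit on bent
  segments is genuine medial-axis corner rounding and is left as is.
* **Pruning.** Spurs (junction-to-extremity edges) shorter than
  `prune_length` (default 15 µm) are removed one at a time, shortest
  first — removing a spur can legitimise its siblings — and any node
  reduced to degree 2 is spliced back into a single segment.
  Increasing `prune_length` can then never increase the branch count
  (tested). Closed loops with no classified node become a single
  self-edge counted as one segment, zero junctions.
* **Boundary branches** are *flagged* (`flag_boundary_branches()`,
  default margin 2 px), never deleted: clipped tubes masquerade as
  branches, and the correct remedy is judgement over sequential
  frames, not silent auto-correction. `network_metrics()` can be
  computed with or without flagged branches.

Time courses are reported as percentages of the 1 h baseline frame
(`normalize_timecourse()`), the convention of the assay; the median
segment length is carried both raw and normalised.

# Concentration–response pharmacology

`fit_3pl()` fits the three-parameter logistic with unit Hill slope,

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}{10^{(\mathrm{LogEC_{50}} - X)} + 1},$$

by Levenberg–Marquardt least squares (self-starting from the data
range; up to 5 restarts with the initial LogEC50 jittered ±1
log-unit; standard errors from the Jacobian at the optimum; an
honest `converged` flag rather than an error on failure). Potency is
pEC50 = −LogEC50 and efficacy is span = Top − Bottom.

Because the Hill slope is fixed at +1, a descending response (e.g.
suppression of caspase activity by a survival factor) cannot be fitted
by the ascending equation with Top ≥ Bottom. Rather than free the
plateau order, `fit_3pl()` detects the orientation from the data
(sign of cov(x, y), overridable) and fits the mirrored curve
$Y = \mathrm{Bottom} + (\mathrm{Top} - \mathrm{Bottom})/(10^{(X - \mathrm{LogEC_{50}})} + 1)$
for descending data. In both orientations Top is the high plateau,
span ≥ 0, and the half-maximal point sits at LogEC50 — the same
convention as the standard agonist/inhibitor equation pair in
commercial curve-fitting software.

Experiment-level fits are aggregated by `derive_potency_table()` into
mean ± SEM of pEC50 and span per condition, mirroring the published
potency-table layout (curves are fitted per experiment, then averaged
— the convention the printed SEMs imply). `normalize_to_vehicle()`
(vehicle mean = 100%) and `percent_of_baseline()` (t = 0 = 100%)
implement the normalisations used for caspase activity and cell
counts.

# The phantom generator

The synthetic module exists so that every stage has inputs with exact
analytic truth; its defaults are the study conditions, not tuning
knobs.

* **Cells** are smooth solids on a substrate: spherical caps,
  ellipsoidal caps (a spherical cap stretched over an elliptical
  footprint) or truncated Gaussian bumps. Cap geometry is closed
  form: volume $\pi h(3a^2 + h^2)/6$, curved surface
  $\pi(a^2 + h^2)$, and analytic sphericity
  $2\,(k(3 + k^2)/4)^{2/3}/(1 + k^2)$ for $k = h/a$ — exactly 1 at
  $k = 1$. `cap_ratio_for_sphericity()` inverts this, so a
  population can be built at the baseline sphericity 0.24
  ($k \approx 0.056$: spread cells really are ~18× wider than tall).
  Stretched-cap surface truth comes from quadrature of the exact
  surface integral, checked in the tests against an independent
  adaptive-quadrature oracle.
* **Dry-mass calibration is exact by construction**: after
  rasterisation the OPD patch is rescaled so that
  $\sum \mathrm{OPD}\,A_{px}/\alpha$ equals the requested mass to
  machine precision; the measurement stage must then recover it
  through segmentation within 0.5%.
* **Fields** place phantoms by seeded rejection sampling (bounding
  circles + minimum gap, grid-bucketed; hard cap 10,000 attempts per
  object with an informative failure). Debris are small spherical
  caps with analytic area drawn uniformly below the 400 µm² gate;
  a field's truth debris percentage is exact bookkeeping. For the
  gate-recovery study we keep every area ≥ 30 µm² clear of the gate
  boundary so pixelation cannot flip a classification, and render at
  uniform apex height (see Segmentation).
* **Networks** are rendered from validated seed graphs (junction
  degree ≥ 3, extremities degree 1; degree-2 points live inside
  polylines and are auto-collapsed) as unions of stadium-shaped
  tubes, default width 16 µm — rounded ends put the medial-axis
  endpoints at the seed nodes within a pixel. Reference graphs: Y,
  straight line, ring (a pure loop), and a running-bond brick
  lattice whose interior nodes are all T-junctions.
* **Dose–response tables** come from the logistic above plus
  i.i.d. Gaussian well noise. The recovery studies use the published
  design: 8 concentrations spanning 100 fM–3 nM, duplicate wells,
  5–7 experiments, noise SD 15% of span for shape metrics (10% of
  vehicle for caspase), 200 simulation replicates.
* **Time-lapse** drift is deterministic: axis ratio and analytic
  sphericity move linearly per hour at fixed footprint area, with the
  cap ratio re-solved each frame, so frame-level truth is closed
  form (1.66 + 0.005/h × 36 h = 1.84).

All randomness flows from explicit per-call seeds through one
internal helper that restores the caller's RNG state; identical seeds
give bit-identical rasters and tables (tested), and the pipeline's
CSV outputs are byte-identical across repeated runs.

What phantoms deliberately do **not** model: ptychographic
reconstruction artefacts (halo, speckle), subcellular refractive
heterogeneity, cell–cell contact in monolayers (fields are
non-overlapping by construction), motility between frames, and any
receptor-level biology — dose dependence enters only through the
logistic. Passing phantom tests therefore validates the *measurement
chain*, not the biology; real phase images will additionally stress
the segmentation assumptions listed above.

# Problem sizes and defaults

The shipped studies run at desk scale, chosen to keep each quantity's
sampling error well inside the tolerances asserted for it: 50-phantom
shape populations (mean sphericity/axis-ratio SE ≪ 1%), a
10,000-object field for the debris gate (the printed percentage,
9.79%, is only expressible at that size), 128²–5200² px canvases at
0.5–1 µm/px, and 200 simulation replicates for the potency
recoveries (Monte-Carlo SE on the mean pEC50 ≈ 0.003 log units).
Every protocol threshold appears once, with its assay value as the
default, in `run_config()`: 400 µm² gate, 50 AU fluorescence
background, 0.25 sphericity boundary, 0/12/24/36 h morphology bins,
1 h tubulogenesis baseline, 4 h single-cell cutoff.
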