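---
title: "Quantifying wound re-epithelialisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound re-epithelialisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(woundquant)
```

## The problem

When a planar epithelium — such as the *Drosophila* pupal wing — is wounded,
the surrounding cells close the gap through three behaviours: they migrate
towards the wound, they change shape (elongating towards the wound margin and
later rounding up), and they divide, first less and then, late after wounding,
in a synchronised burst in an annulus behind the leading edge. woundquant
turns segmented time-lapse movies of such wounds (cell label images, wound and
tissue masks, nucleus tracks and division events) into spatiotemporal heatmaps
of each behaviour in a wound-centred frame of reference: value as a function
of *distance from the wound edge* and *time after wounding*. It also provides
the comparison machinery such studies need — tissue-area-weighted combination
of replicate movies, signal-to-noise maps, virtual-wound negative controls in
unwounded tissue, unwounded division baselines, and control-versus-perturbation
difference maps — plus a synthetic epithelium generator that supplies inputs
with known ground truth in place of confocal data.

## The statistics

### Cell shape: the q-tensor and dQ1

Each cell's shape is summarised by a symmetric, traceless, dimensionless
2×2 nematic tensor computed from its centred second moment of area
$S = \tfrac{1}{A}\int (x-c)(x-c)^T\,dA$:

$$q = \frac{S}{\operatorname{tr} S} - \frac{I}{2}.$$

Its eigenvalues are $\pm\sqrt{q_{xx}^2+q_{xy}^2}$ and lie in $(-1/2, 1/2)$;
the positive eigenvector is the elongation axis, and the orientation is
$\theta = \tfrac12\,\mathrm{atan2}(2q_{xy},\,q_{xx}-q_{yy})$, reported in
$[0,\pi)$. A disc gives $q=0$; a 2:1 ellipse gives eigenvalue 0.3. This
normalised-second-moment convention is one of several monotone traceless
conventions in use; because the shape maps are normalised by a robust maximum
before cross-condition comparison, the choice affects only the (recorded)
normalisation constant, not the structure of any map. Two evaluation paths
are provided and cross-checked to 0.01: exact Green's-theorem integration
over polygons, and pixel summation over label regions (with the 1/12
per-pixel variance so a pixel counts as a unit square, not a point).

The tissue mean $Q$ is the unweighted mean over all cells not flagged as
border-truncated; deviations $\delta q_i = q_i - Q$ remove the tissue's
global nematic order (a developing wing is itself anisotropic) and average
to the zero tensor by construction. The per-cell radial elongation is the
radial–radial component after rotating into the wound frame,

$$dQ1_i = \hat r_i^{\,T}\, \delta q_i\, \hat r_i,$$

with $\hat r_i$ the unit vector from the wound centre to the cell centroid.
Positive means elongated towards the wound; tracelessness makes the
tangential component $-dQ1$, so negative means elongated along the wound
margin. Cells touching the field border are excluded from $Q$ and from the
binned statistics (truncation biases elongation); the exclusion count is
logged.

### Migration: deviation velocities

Nucleus detections are linked frame-to-frame by greedy mutual nearest
neighbours with a maximum link distance (default 3 µm; no gap closing,
merging or splitting). Velocities are forward differences assigned to the
earlier frame — the simplest causal convention, fixed so heatmap time axes
are unambiguous. The per-frame mean velocity over all samples is subtracted
to remove the tissue's developmental drift; the deviation velocities are
zero-mean per frame by construction and the operation is idempotent. The
migration statistic is the towards-wound component $s_{toward} = -\,dv \cdot
\hat r$, positive towards the wound. The per-frame (rather than whole-movie)
mean is used because the background drift itself changes as the wing
develops; wound-adjacent samples are not excluded from the mean, since the
wound signal is a small fraction of all samples and any exclusion radius
would be arbitrary.

### The wound frame of reference

The wound mask's largest connected component defines the wound: its area
series, its per-frame centroid, and the Euclidean distance transform that
assigns every pixel its distance to the wound edge (zero inside the wound).
Wounds are classified by their mean area over the 9–10 min window — small
if within 200–400 µm², large if within 700–1100 µm² — and that window mean
is also the reference for closure: a wound is *closed* at the first frame
its area drops to 20% of the reference, after which the leading edge is too
noisy to segment. From closure onwards the frame of reference is a tracked
*wound site*: the point is advected each frame by the mean raw velocity of
nuclei within 30 µm (falling back to the global frame mean when none are
near), and distances and directions are measured from it. Raw rather than
deviation velocities advect the site — deviation velocities are zero-mean
by construction and would freeze it. In unwounded control movies a *virtual
wound* is placed at the field centre in frame 0 and advected identically,
behaving like a closed wound from the start.

Conventions fixed throughout: coordinates are pixel centres, origin at the
top-left pixel centre, x rightward, y downward, 0-based frames; public
quantities in µm and minutes; distance bands are half-open $[d_{lo},
d_{hi})$; Euclidean (not chamfer) distance transform.

### Heatmaps

Behaviours are binned on a (distance band × time bin) grid — defaults 10 µm
× 4 min, spanning 0–120 µm (the field limit for a 123.26 µm field with a
central wound); neither bin size is prescribed by the studies this mirrors,
so both are configuration, recorded in every output. Velocity and shape
bins hold the unweighted mean of their samples; division and cell density
bins hold counts divided by the tissue band area summed over the bin's
frames (units µm⁻² per time bin — the per-time-bin reading is recorded in
the metadata). Samples beyond the last distance edge go to an overflow
tally, never silently dropped, and total division counts obey the exact
identity `sum(counts) + overflow = events`.

Replicate videos are combined as weighted means with the video's tissue
band area in the bin as weight; for densities this equals pooled counts
over pooled areas. Signal-to-noise maps divide |across-video mean| by the
sample (n−1) standard deviation — appropriate for the few (4–9) replicates
typical of such experiments — flagging bins with fewer than two videos or
zero variance. Shape maps are normalised, after combination, by a robust
maximum of a designated large-wound control map: the 95th percentile of
|dQ1| over occupied bins. (The source descriptions of this step conflict —
a "5th percentile of the absolute value" in one place, the "maximum
absolute value" in another; the robust-maximum reading reconciles them and
both readings are recorded in the map metadata.) The constant is reused for
every condition being compared so difference maps remain on one scale.
Division maps can be corrected by subtracting an unwounded whole-tissue
division-density series (a function of time only), smoothed by a 3-point
centred moving average whose window shrinks at the series ends. Difference
maps are perturbed − control, missing wherever either side is missing.

## The synthetic epithelium

The generator emulates the acquisition this pipeline targets: a
123.26 × 123.26 µm field (512 × 512 px, 0.2407 µm/px) imaged every 2 min
for 3 h (91 frames), containing ~400 polygonal cells and a circular wound.
Because no quantitative closure law is published, wound area follows an
exponential decay with floor, $A(t) = A_0[(1-\phi)e^{-t/\tau} + \phi]$,
with $\tau$ and $\phi$ exposed as parameters. The defaults are anchored to
the published healing timings: a large wound ($A_0 = 1400$ µm², $\tau = 20$
min, $\phi = 0.05$) has ~900 µm² at the 9–10 min classification window and
closes to 20% of that reference at ~50 min; the small-wound parameter set
(970 µm², $\tau = 8$ min, $\phi = 0.02$) gives ~300 µm² at the window and
closure at ~25 min.

Two statistically coupled layers share this wound and one set of imposed
fields:

* **Nuclei** start at the rendered cell centres and are advected by the
  inward radial field $v(d,t) = v_0\,e^{-d/L_d}\,e^{-t/T_v}$, with $d$ the
  distance to the analytic wound-disc edge (using the analytic disc removes
  pixelisation noise from the ground truth). Detections add isotropic
  Gaussian jitter (default 0.05 µm, a realistic sub-pixel centroid
  localisation error ≈ 0.2 px). Defaults $v_0 = 0.3$ µm/min, $L_d = 30$ µm,
  $T_v = 30$ min reproduce the reported qualitative structure: migration
  extending tens of µm back from the edge, a fast phase over the first
  ~30 min.
* **Cell shapes** are the image of a static, isotropic, jittered hexagonal
  reference tessellation (jitter 0.10 of the lattice spacing — a fairly
  regular epithelium; per-cell elongation noise ≈ 0.05) under a radial warp
  constructed so that its local radial:tangential aspect ratio is exactly
  $(1+e)/(1-e)$ at every point, where $e(d,t) = e_0\,e^{-d/L_e}\,e^{-t/T_e}$
  (defaults $e_0 = 0.1$, $L_e = 15$ µm, $T_e = 15$ min: elongation reaching
  ~30 µm back and resolving within ~25 min). The warp $u(s)$ solves
  $du/ds = u/(k(s)\,s)$ anchored at the far field and is integrated with
  midpoint steps on a 0.25 µm grid; a cell rendered through it measures
  $q_{rr} = e/(1+e^2)$ by construction, which is what makes recovery
  testable without a mechanical model.
* **Divisions** are an inhomogeneous Poisson process, sampled by thinning:
  base rate $1.5\times10^{-5}$ µm⁻²min⁻¹ (≈ 40 divisions per unwounded
  movie, a plausible pupal-wing figure), suppressed by 80% within 40 µm of
  the wound until 80 min, and boosted by amplitude 4 in the 20–70 µm annulus
  during 90–150 min — the published suppression-then-burst spatiotemporal
  pattern. Each event is recorded at its parent nucleus and splits both the
  parent nucleus and the nearest reference seed into two adjacent children,
  so the cell count rises by exactly one per division; no cell death,
  extrusion or intercalation is modelled.

One RNG with a single seed drives all draws in a documented order, so equal
parameters give bit-identical movies.

### What the generator does and does not emulate

The two layers are statistically faithful but mechanically decoupled: label
identities are not nucleus identities, the shape layer is warped rather
than advected, and the wound disc simply occludes the reference cells
beneath it, revealing intact cells as it shrinks. Three consequences
matter when interpreting tests:

* In the first 10 µm band the generator's own ground truth is invalid:
  cells crossed by the disc edge are truncated by the mask (a tangential
  crescent bias), and nuclei reaching the edge stall against the boundary
  (crowding). Recovery checks therefore evaluate bands from 10 µm outward;
  in real data the first band genuinely reflects leading-edge biology, and
  this pipeline reports it — it is the *simulator's* truth that stops
  there.
* The label-count conservation law (one new cell per division) holds
  exactly for unwounded movies; around closing wounds the visible label
  count can additionally rise as occluded cells are revealed.
* Cell-density gradients from the converging flow live in the nucleus
  layer; label-image cell density stays near-uniform. Passing recovery
  tests therefore demonstrates the analysis machinery on data with the
  assumed statistical structure — not that a mechanical wound model has
  been fit.

## Numerical and design choices

* Distance transforms are computed once per frame and shared by all
  consumers; post-closure distances to the tracked site are analytic.
* Regions smaller than 9 px are dropped (and counted) before shape
  analysis; smaller regions make tr(S) ill-conditioned.
* The classification window mean (not the first frame) is the closure
  reference, because the earliest frames after wounding are typically
  obscured.
* Wound centres on frames with no clean mask are filled from the nearest
  valid frame.
* Degenerate inputs error loudly with the offending cell, file or row
  named; skipped samples (e.g. coincident with the wound centre) and
  overflow events are counted in the run log rather than silently lost.
* Test problem sizes: the study-condition fixtures are 5 replicate
  91-frame, 512 px, ~400-cell videos per condition — enough that binned
  velocity errors sit near 5% and binned elongation errors near 10% where
  the imposed signals are appreciable ($v > 0.05$ µm/min, $e > 0.02$),
  while a full condition simulates and quantifies in about two minutes on
  one CPU. Null (virtual-wound) maps are checked bin-wise against twice
  their replicate standard error; with five replicates that bound is
  t-distributed, so the check requires ≥ 85% of occupied bins inside it
  plus a video-level global mean within 2 SE, rather than every bin.

## A worked example

```{r example, eval = FALSE}
library(woundquant)

movie <- simulate_epithelium(sim_params(rng_seed = 1))
q <- run_quantify(movie)
q$model               # wound class, reference area, closure frame
plot(q$heatmaps$velocity)
plot(q$heatmaps$shape)

# negative control in unwounded tissue
null_movie <- simulate_epithelium(sim_params(
  rng_seed = 2, wound_initial_area_um2 = 0, v0_um_per_min = 0, elong0 = 0,
  div_suppression_depth = 0, burst_amplitude = 0))
q0 <- run_quantify(null_movie, virtual_wound = TRUE)
plot(q0$heatmaps$velocity)   # statistically flat
```

## Known limitations

* Tracking is 2D; movies with substantial out-of-plane motion need an
  external 3D tracker, whose track tables can be supplied directly.
* The linker is deliberately simple (mutual nearest neighbour, no gap
  closing); it is accurate at the default fixture's jitter-to-spacing
  ratio but is not a general-purpose tracker.
* No statistical hypothesis tests are attached to the heatmaps; difference
  maps are descriptive, as in the studies this mirrors.
* Segmentation, boundary detection and division detection are out of
  scope: label images, masks and event tables are inputs.
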