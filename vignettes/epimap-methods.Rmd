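---
title: "Learned electrocardiographic imaging with geometric electrode registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned electrocardiographic imaging with geometric electrode registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimap)
```

## The problem

Electrocardiographic imaging (ECGi) reconstructs the electrical activity of
the heart's surface from potentials recorded non-invasively on the torso.
The forward relationship is linear — at every instant the body-surface
potential vector is a transfer matrix times the epicardial potential vector,
`phi_T = A phi_H` — but the inverse is badly ill-posed: `A` smooths
aggressively, so classical approaches regularize (Tikhonov and relatives)
and require a patient-specific `A` computed from imaged anatomy.

`epimap` takes the learning route instead: train small neural networks to
map body-surface potentials directly to epicardial potentials, using paired
recordings (an electrode vest on the torso, a multi-electrode sock on the
ventricles, sampled simultaneously at 2 kHz). No transfer matrix is ever
formed or inverted at inference time. The package covers the full pipeline:

1. **Preprocessing** raw multi-beat electrograms into one clean cycle.
2. **Part I — within-subject models.** A tanh fully connected network (one
   time step at a time) and an LSTM (whole cycles), trained per subject on
   that subject's raw lead vectors.
3. **Registration.** Subject-independent 2D representations: torso leads
   unwrapped onto a cylinder and rasterized to 30 x 90 images; sock leads
   projected onto a normalized disk and resampled at a fixed 165-node
   template.
4. **Part II — a cross-subject CNN** from torso images to template vectors,
   applicable to a subject never seen in training because shapes no longer
   depend on the electrode layout.
5. **Evaluation**: per-lead electrogram correlation, activation-time maps
   from the maximal negative `dV/dt`, pacing-site localization error, and
   the two leave-one-out cross-validation designs.
6. **A synthetic data generator** that produces paired geometries and
   potentials with the statistical structure the method assumes, so the
   whole pipeline is testable without any data download.

## Preprocessing

Paced recordings repeat one beat 5-20 times. `synchronized_average()` takes
reviewed beat onsets (segmentation is an input, not a contract — a
threshold-based helper `detect_beats()` exists for convenience), truncates
all beats to the shortest, and averages sample-by-sample, attenuating
uncorrelated noise by `1/sqrt(n_beats)`. `moving_mean()` then applies a
trailing 20-sample window (10 ms at 2 kHz; the window shrinks at the left
edge so constants and length are preserved), and `baseline_align()` shifts
every lead synchronously by one scalar so that the mean over all leads in
the first `onset_window` samples (default 1) is exactly zero. Averaging
before smoothing is the order implemented; the reverse order is available
by composing the functions directly.

Vests lose 10-20% of their leads in practice. Whole leads, not samples, go
bad, so `interpolate_bad_leads()` replaces a bad lead's entire series by
spatial (barycentric) interpolation of the good leads at the bad lead's own
registered position on the torso cylinder. Linear-in-plane fields are
restored exactly; filled leads are re-flagged `"interpolated"`.

## Torso registration

`center_nodes()` subtracts the cloud centroid; `cylinder_project()` assigns
each lead an azimuth `theta` (degrees from the +y axis, increasing toward
+x, wrapped to [0, 360)) and height `h` (the z coordinate in mm). The sign
conventions are frozen so that anterior/posterior electrode bands land in
reproducible image columns.

`rasterize_torso()` interpolates lead potentials onto a fixed 30 x 90 pixel
grid. "Bilinear" interpolation from scattered electrodes is realized as
barycentric-linear interpolation on a Delaunay triangulation — bilinear
interpolation is undefined off a regular grid, and the barycentric form is
the standard reading that reproduces affine fields exactly. Three numerical
commitments:

* the lead set is replicated at `theta +/- 360` before triangulation, so
  the raster is seamless across the wrap (column 0 and column 89 are
  physically adjacent);
* pixels outside the convex hull take the nearest lead's value;
* weights are assembled once into a sparse matrix, so rasterizing a whole
  recording is a single sparse product — and linearity in the potentials
  holds to machine precision by construction.

Column centers sit at `(j + 0.5) * 4` degrees; row centers span the
subject's own lead height range (top row = largest h). Per-subject height
scaling mirrors per-subject cylinder projection; a global scale would let a
tall subject's image clip a short subject's leads.

## Epicardial registration

The sock leads live on a roughly ellipsoidal shell. With the apex electrode
at the origin and the apex-base axis along z (`project_to_disk()` performs
this alignment from the labelled apex node via a Rodrigues rotation of the
apex-to-centroid direction), each node at position `p` maps to the planar
direction of `(p_x, p_y)` stretched to the node's full 3D distance from the
apex. Angle encodes orientation around the heart; radius encodes distance
from the tip; stacked nodes on the steep sides are disambiguated. Off-axis
nodes preserve `||output|| = ||p||` to 1e-12.

Because hearts are oval and differently sized, `normalize_segments()` cuts
the disk into `360/arc` angular segments (12 at the default 30 degrees) and
shrinks each segment concentrically so its furthest node lands exactly on
the unit radius. The scale factor is `R/L` — the shrink that brings the
furthest node (radius `L`) onto `R`. Angles never change, no radius ever
exceeds `R`, and a second pass is the identity. Empty segments (possible
only for very sparse socks) are skipped with a warning.

`build_template()` freezes the fixed sampling layout: one center point and
7 concentric rings at radii `k/7`, populated proportionally to `k`
(area-uniform density) with largest-remainder rounding — 6, 12, 18, 23, 29,
35, 41 points, 165 in total — each ring traversed clockwise from angle 0.
Any fixed deterministic layout with this ring structure would serve; this
one is frozen for reproducibility, and the ordering (center outward,
clockwise) is what gives every subject's template sequence the same
geometric meaning. `sample_to_template()` / `sample_from_template()` move
potentials between sock leads and template nodes with the same
barycentric-linear + nearest-fallback contract as the torso raster; both
maps are linear and exact on affine fields at interior points, and a round
trip on smooth fields stays within a few percent RMSE at interior leads.

## The inverse solvers

All three networks are implemented natively (dense matrix algebra in R,
with the convolution gather/scatter in compiled code) and trained with Adam
on mean squared error. Native training keeps every run bit-reproducible
from `model_spec(seed = )`: two trainings with the same spec and data give
identical per-epoch losses and parameters.

* **FCN** (Part I): torso vector at one time step -> hidden tanh layers
  (default 256, 256; the cross-validation harnesses use 128, 128 at desk
  scale) -> linear readout to 239 leads. Trains on pooled time steps;
  minibatches with a late-stage learning-rate step-down.
* **LSTM** (Part I): one recurrent layer (default width 128) consuming the
  whole cycle, linear readout per step. State carries within a recording
  and resets between recordings; one Adam step per recording per epoch.
* **CNN** (Part II): three blocks of [3 x 3 convolution, depth 32, tanh,
  2 x 2 average pooling] followed by a linear readout to the 165 template
  nodes. Convolutions pad **circularly along the width** — the torso angle
  axis — because column 0 and column 89 are neighbours on the cylinder;
  cyclically shifting an input image cyclically shifts the pre-pooling
  feature maps. Height padding is zero.

Inputs and targets are standardized over the training set (inverted at
prediction); without this, tanh units saturate on mV-scale data. The loss
recorded in `tidy(model)` is in those standardized units. Layer widths,
epochs (default 500), learning rate (1e-3 default; the harnesses pass
their own), batch size and an optional decoupled weight decay are all
`model_spec()` fields; the architectural commitments (tanh, three
convolution layers of depth 32, average pooling) are fixed.

## Evaluation

* `cc_time()` — Pearson correlation between measured and reconstructed
  electrograms across time, per lead. Undefined (NA) for constant series;
  such leads are excluded from medians and counted in `n_cc_defined`.
* `activation_time()` — the sample maximizing the one-step drop
  `-(V[t+1] - V[t])`, reported at the first sample of the drop, in ms.
  Ties break to the earliest sample; the `dt` divisor cannot change the
  argmax. `activation_map()` applies it per lead and marks the
  earliest-activating node (lowest index on ties) — the predicted pacing
  site.
* `cc_activation()` — Pearson correlation between two activation maps
  across leads.
* `localization_error()` — Euclidean distance between the earliest nodes
  of the measured-derived and reconstruction-derived maps. The measured
  map is the ground truth.
* `smooth_at()` — inverse-distance-weighted neighbourhood smoothing
  (weights `1/(d + radius/4)`, self included). Off by default as an
  operation. The cross-validation harnesses do smooth the *reconstructed*
  map (radius = 3 x mean sock spacing) before the map correlation and the
  earliest-node search, mirroring the experimental practice of smoothing
  activation fields before locating a source: a learned reconstruction
  recovers the activation sequence at the scale of a few electrodes, and a
  raw single-node argmin rewards noise. The measured side is never
  smoothed.

`loocv_recordings()` implements the within-subject design (K recordings ->
K folds -> K models), `leave_one_subject_out()` the cross-subject design
(S subjects -> S folds; every recording of the held-out subject is scored
in its own native lead space after resampling predictions back from the
template). `summarize_folds()` pools per-recording scores into medians and
quartiles (linear interpolation of order statistics, R type 7), overall and
per subject. The cross-subject harness can also score a
predict-the-training-mean baseline — the per-time-step mean template
sequence over the training recordings — which any model exploiting the
torso data must beat.

## The synthetic generator

`make_corpus()` emulates the *structure* of a paced-mapping animal study,
not its physics:

* **Geometry.** 239 sock leads on a quasi-ellipsoidal shell (half-axes
  around 26 x 26 x 40 mm, jittered per subject, 2% radial roughness, apex
  labelled), offset inside a quasi-cylindrical vest of 150-171 leads. The
  vest radius is 70 mm — wrapped close to the chest — chosen so that the
  forward projection keeps enough spatial information for the inverse task
  to be well-posed at the sock's own resolution; with a distant vest the
  synthetic task collapses into pure ill-posedness and would test nothing
  but regularization.
* **Activation.** A paced wavefront spreads at 1.5 mm/ms of Euclidean
  distance from the pacing node (a convex-shell simplification of geodesic
  spread). Pacing sites are spread over the shell by farthest-point
  selection, emulating a protocol that paces all regions.
* **Electrograms.** Each lead's waveform is a sum of three logistic terms:
  an R-wave rise (20 mV, tau 4 ms, leading by 6 ms), a dominant downstroke
  (33 mV span, tau 2.5 ms — an intrinsic deflection of realistic width)
  centred at the lead's activation time, and a slow recovery (tau 12 ms,
  delayed 30 ms) returning to baseline. The downstroke's peak slope
  dominates every other term everywhere, so the steepest one-step drop of
  the sampled waveform falls within one sample of the true activation time
  — this is what makes the generator an *oracle* for the activation-time
  estimator rather than just a data source.
* **Forward model.** `A[i, j] = (1/d_ij^2) / sum_j (1/d_ij^2)` — an
  inverse-square kernel, row-normalized so uniform epicardial potentials
  pass through unchanged. A fixture standing in for volume conduction, not
  a boundary-element solution; documented as such.
* **Noise and artifacts.** Seeded Gaussian sensor noise (default 0.05 mV,
  a post-averaging residual level) and a configurable fraction of torso
  leads (default 15%, matching the 10-20% seen on real vests) replaced by
  baseline noise and flagged bad.

Everything is a pure function of `(seed, subject, recording)`; the same
configuration yields byte-identical corpora and container files.

What passing tests on this generator shows: the registration maps, the
training loops, the metrics and the cross-validation plumbing do what they
claim on data with the assumed structure (a linear smooth forward map, a
single propagating wavefront, smooth waveforms). What it does not show:
performance on real tissue — no fibrillation, no scar, no repolarization
heterogeneity, no inhomogeneous conductivity, no geodesic propagation, no
electrode motion. Accuracy numbers from real animal data are out of scope
here and are not claimed.

## Numerical choices and degenerate inputs

* Scattered interpolation clips barycentric weights in [-1e-9, 0) to zero
  (points numerically on an edge) and renormalizes rows to sum to 1.
* A lead exactly on the cylinder axis has no azimuth: `degenerate-node`
  error. Collinear lead layouts cannot be triangulated:
  `degenerate-layout`. A non-apex sock node exactly on the z axis maps to
  the disk center with an `axial-node` warning.
* Constant electrograms have undefined correlation: NA, excluded from
  medians, counted per fold.
* Activation-time ties (constant or monotone series) resolve to the
  earliest sample; earliest-node ties to the lowest index.
* The container stores floats as `%.17g`, which round-trips IEEE doubles
  exactly; write-then-read is bit-identical.
* Training determinism relies on R's own RNG stream under a fixed seed and
  single-threaded accumulation order; BLAS vendor differences can perturb
  results at the last few ulps but not the recorded seeds or shuffling.

## Desk-scale problem sizes

The test-suite and acceptance runs use reduced sizes chosen as the
package's own desk-scale defaults: one subject, 12 pacing sites, 160 torso
leads and 90 ms cycles for the within-subject design (about 2000 training
time steps per fold); three subjects with 4 recordings each and 60 ms
cycles for the cross-subject CNN, training on a time-strided subset of
frames (the registered frames are heavily redundant in time) for 25
epochs. These sizes keep a full end-to-end study in minutes on one CPU
while leaving every stage of the method exercised at its real
dimensionality (30 x 90 images, 165 template nodes, 239 sock leads).

## Known limitations

* Euclidean propagation and a monopole-kernel forward model are fixtures;
  they preserve the inverse problem's *shape*, not its physics.
* The epicardial disk projection assumes a roughly star-shaped ventricular
  shell around the apex axis; strongly non-convex geometries (atria,
  outflow tracts) are out of scope.
* Segment normalization guarantees per-segment radial coverage but can
  distort relative areas between subjects with very different sock
  coverage.
* The LSTM consumes whole cycles and is therefore sensitive to cycle
  alignment; it assumes preprocessed, baseline-aligned input.
* Pacing-site localization is resolved only to the sock's electrode
  spacing; the harness's activation-map smoothing trades single-node
  precision for robustness, which is the right trade at that resolution.
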