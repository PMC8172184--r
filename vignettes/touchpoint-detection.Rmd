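---
title: "Detecting surface touch-points in thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting surface touch-points in thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotouch)
```

## The problem

When a warm hand touches an indoor surface it leaves a transient thermal
signature: a small region a few degrees above ambient that cools back over
seconds to tens of seconds. A fixed thermal camera watching a room therefore
records, implicitly, a map of where people have touched — information
directly useful for targeted cleaning and infection-control surface
monitoring. The difficulty is that the same camera also sees the people
themselves (much larger, warmer, moving blobs), and that a touch signature
overlaps the human's intensity range, so simple per-pixel thresholds cannot
separate the two. `thermotouch` implements a full detection pipeline for
this problem, plus a synthetic scene simulator with exact ground truth so
every stage can be trained and tested without camera data.

## The model

Frames are 8-bit grayscale images $I_1, \dots, I_N$ at 15 frames per second
(recordings at 30 fps are decimated by keeping every second frame), with a
fixed linear calibration mapping intensity 0–255 onto 20–35 °C. A
human-free reference frame $I_0$ is captured first. The pipeline computes

$$I^{mask} \;=\; f_{thresh}\!\Big(\sum_{i=1}^{N} f\big(I_i - I_0\big)\Big),$$

where:

* $I_i - I_0$ is pixel-wise background subtraction with negative
  differences clamped to zero (both targets are strictly warmer than the
  static background, so sub-background pixels carry no signal);
* $f(\cdot)$ is a per-frame three-class segmenter labelling each pixel
  background (0), touch-point (1) or human-subject (2); only the
  touch-point indicator enters the sum;
* the summation produces a **cumulative map**: per pixel, the number of
  frames carrying the touch label — a touch duration in frames, usable as a
  confidence score;
* $f_{thresh}$ keeps pixels whose count reaches the duration threshold
  (default 50 frames, i.e. a signature persisting at least
  $50/15 = 3.3$ s), yielding the binary touch mask.

The mask is then post-processed into *effective touch-points*: 8-connected
components; components below $\tau_1 = 100$ px² removed; components whose
centroids lie within $\tau_2 = 30$ px grouped transitively, plus a
containment pass merging any region whose centroid falls inside another's
bounding box, iterated to a fixed point. Evaluation matches predicted and
labelled regions one-to-one greedily by centroid distance under
$\tau_3 = 30$ px; matched pairs are TP, unmatched predictions FP, unmatched
labels FN. True negatives are undefined at region level and never computed.
Reported metrics are precision, recall, F1, and their complements FDR
($1-$ precision) and FNR ($1-$ recall); segmentation quality is measured by
the per-class Dice coefficient $2|A\cap B|/(|A|+|B|)$.

## The segmenter

Two interchangeable segmenters stand behind $f(\cdot)$:

* **U-net** — an encoder–decoder convolutional network with skip
  connections, built from scratch in this package (compiled im2col/GEMM
  kernels, hand-derived backpropagation verified against finite
  differences in the test suite). Depth 4, first stage 64 channels at full
  scale; inputs are reflect-padded to a multiple of $2^{depth}$ and cropped
  back. Training follows pixel-wise multi-class cross-entropy at learning
  rate 0.0005 for 40 epochs, batch size 1, with a seeded 70/30
  train/validation split; weights are taken from the epoch with the best
  validation touch-class Dice (ties to the earliest epoch). The optimizer
  is plain SGD with momentum 0.9 — a conventional default, configurable,
  since nothing in the recipe pins it down. Cross-entropy is unweighted;
  the severe touch-class imbalance is a known limitation (see below).
* **Rule-based baseline** — pixels at or above an intensity threshold form
  8-connected components; components at or above an area threshold are
  labelled human, smaller ones touch-point. This encodes the one robust
  prior separating the classes — touch-points are small, humans are large —
  and gives the downstream stages a deterministic oracle that needs no
  trained weights.

## The simulator

`simulate_scene()` renders the scene type the pipeline targets: a static
surface at 25 °C; touch events as elliptical footprints whose excess
temperature ramps linearly to a peak during contact and then relaxes by
Newtonian cooling $\Delta T(t) = \Delta T_{peak}\, e^{-(t-t_{rel})/\tau}$;
an elliptical human subject with a radial temperature gradient from a 35 °C
core to a 25 °C rim that strictly occludes the surface wherever present;
Gaussian sensor noise added in intensity units; quantization to 8 bits.
Ground truth marks occluded pixels human, un-occluded footprints with more
than 1 intensity unit of excess as touch, the rest background, and records
each event's bounding box and touched duration.

Modelling choices, where the physics is only known qualitatively: the
exponential decay law is the single-parameter model consistent with
conductive dissipation and is analytically checkable (the residual one time
constant after release is $\Delta T_{peak}/e$, asserted in the tests within
one quantization step); the contact-phase ramp is linear; footprint excess
temperature is spatially uniform. Event defaults (peak 5 °C, $\tau$ 10 s,
sampled ranges 3–8 °C and 5–20 s) sit mid-range of plausible bare-hand
contact and are choices, not measured constants. What the simulator does
*not* emulate — and hence what green tests do not demonstrate about real
data: heat diffusion (footprints neither blur nor grow), emissivity
differences between materials, camera vignetting and drift, non-static
backgrounds, partial contact geometry, clothing. Results on synthetic
scenes are an engineering validation of the pipeline mechanics, not a claim
about field accuracy.

## Numerical and boundary conventions

* Coordinates are 0-based `(row, col)` with the origin at the top-left,
  matching the on-disk image layout; all reported centroids and boxes use
  this convention.
* Duration thresholding is inclusive (count $\ge f_{thresh}$ passes), so a
  signature persisting exactly the minimum duration is kept. The area
  filter is likewise inclusive (area $\ge \tau_1$ kept); centroid grouping
  is strict ($< \tau_2$), as is matching ($< \tau_3$).
* Centroid grouping is single-linkage (transitive): group size is
  unbounded by construction. The containment pass uses the rectangular
  bounding box, runs after distance grouping, and iterates to a fixed
  point; a merged region's centroid is recomputed from the union pixel
  set, never averaged from member centroids.
* Matching is greedy nearest-first with ties broken by lower prediction
  id, then lower label id — deterministic and order-independent. The tests
  compare it against exhaustive optimal assignment on small instances;
  where the two can differ, greedy is the defined behaviour. Labelled
  boxes use the box centre as centroid; predictions use the pixel-mass
  centroid (each per its available representation).
* Any 0/0 rate (no predictions, no labels, two empty masks in Dice) is
  reported as `NA`, never silently 0 or 1.
* Per-pixel argmax ties in segmentation resolve to the lowest class index.
* 8-connectivity is the default for components (diagonal splits of one
  diffuse thermal blob are artefacts); 4-connectivity is available.
* The intensity scaling of recordings is fixed to the single linear
  20–35 °C map; per-video automatic gain is deliberately out of scope.
* The cumulative sum uses hard labels (0/1), not class probabilities; the
  displayed "probability map" is counts normalised by $N$ for rendering
  only.

## Problem sizes used in the tests

The shipped test suite and acceptance script run everything at desk scale,
chosen as the package's own verification conditions: synthetic scenes of
120 × 160 px at 15 fps and ~12 s; the width-reduced U-net profile (first
stage 16 channels, depth 4) trained for 10 epochs on 18 labelled frames at
learning rate 0.01 — an appropriate rate for a short per-sample SGD run,
as opposed to the 0.0005 of the full 40-epoch recipe; and brute-force
oracle comparisons on masks up to 32 × 32 over up to 20 frames. On these
conditions the baseline-segmenter pipeline recovers 15/15 seeded touch
events with no false detections, and the short training run reaches
validation touch-class Dice above 0.5 — an engineering floor demonstrating
that the architecture and training loop learn, not a statement about
full-scale accuracy.

## Known limitations

* Temporal information is used only through the label summation; a touch
  and a slow-moving warm object of touch-like size are indistinguishable
  to the per-frame segmenter.
* Unweighted cross-entropy under extreme class imbalance can collapse the
  touch class early in training; the epoch-selection rule (validation
  touch Dice) mitigates but does not remove this.
* The static-background assumption is structural: periodically moving
  background objects would create persistent false accumulations.
* The 70/30 split applies to whatever pool it is given; the package does
  not prescribe how reference frames are drawn from videos.
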