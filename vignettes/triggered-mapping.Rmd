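---
title: "Swim- and stimulus-triggered mapping of hindbrain calcium activity"
author: "hindscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swim- and stimulus-triggered mapping of hindbrain calcium activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindscope)
```

## The experiment this package models

A head-restrained larval zebrafish, tail free, is shown a whole-field
moving grating (the optomotor stimulus) while a single hindbrain plane
is imaged by two-photon microscopy at 5.81 Hz. Each 315 s trial
alternates 10 s of grating motion with 5 s of static presentation — 21
motion presentations per trial. The tail is filmed from below at
250 Hz; the fish responds to motion with discrete swim bouts. Two
fluorescence channels are acquired: a green calcium indicator (GCaMP)
reporting neural activity and a red anatomical fluorophore, whose
emission leaks slightly into the green channel.

The analysis question is: which regions of interest (ROIs) in the
movie follow the *motor* events (swim bouts), which follow the *visual*
stimulus, what activity archetypes exist within each group, and where
in the imaged plane does each archetype live?

## Pipeline

1. **Tail kinematics** (`tailTraceFromPoints`, `findBouts`). Nine
   tracked points from swim bladder to tail tip give a signed bend
   angle per frame (angle between the resting body axis and the
   bladder-to-tip vector). Local extrema of the angle trace above an
   amplitude threshold are deflection peaks; runs of peaks separated by
   less than the intra-bout gap are one bout. Bouts overlapping
   tracking gaps or exceeding a struggle amplitude are flagged and
   excluded downstream.
2. **Preprocessing** (`estimateBleedthrough`, `correctBleedthrough`,
   `dff`, `spatialMeanFilter`, `extractRoiTraces`). The red-to-green
   bleed-through factor is the Theil–Sen slope of time-averaged green
   versus red pixel values over red-dominated pixels; the green movie
   is corrected by `max(green − factor × red, 0)`. ROI traces are
   footprint-weighted pixel means, converted to ΔF/F against a running
   10th-percentile baseline. Frames used for pixel maps are smoothed
   with a 2 × 2 uniform spatial filter.
3. **Event windows** (`selectEvents`, `extractWindows`). Swim windows
   span 2 s before to 5 s after bout start and admit only bouts
   beginning more than 0.5 s after the previous bout's end; stimulus
   windows span 5 s before motion onset plus the full 10 s of motion.
   Windows that would leave the trial are dropped rather than padded,
   which would bias averages.
4. **Classification** (`meanEventCorrelation`, `classifyTrace`). Each
   trace's consistency with an event class is the mean over events of
   the Pearson correlation between the individual event segment and
   the triggered average. A trace is swim-driven if its swim score
   exceeds 0.6 but its stimulus score does not, stimulus-driven in the
   opposite case, ambiguous if both exceed 0.6 (excluded from
   clustering), otherwise unclassified. The two scores are not
   independent — bouts are themselves stimulus-locked — and no
   decorrelation is attempted; this mirrors the assay's structure and
   is a known limitation.
5. **Clustering** (`clusterTraces`). Within each driven group, the
   triggered averages are z-scored and clustered by iterative centroid
   growing: seed with the most-correlated pair above the threshold
   (0.75), sweep in every waveform correlating at least 0.75 with the
   current centroid until stable, remove, repeat; clusters below the
   minimum size are dissolved. Ties in seeding go to the lowest index,
   which makes the procedure deterministic; permuting the input changes
   labels but not the partition on separable data.
6. **Pixel maps** (`clusterCorrelationMap`, `combineAcrossLarvae`).
   Each cluster centroid is correlated against every pixel's filtered
   intensity time series within each event window; per-event images are
   averaged into the final map. Raw filtered intensities are used
   rather than ΔF/F because Pearson correlation is invariant to the
   per-window affine ΔF/F transform. Zero-variance pixels are flagged
   undefined and excluded from averages; a pixel is undefined in the
   final map only if undefined in every event. Maps from several
   larvae, once registered externally to a common space, combine as a
   weighted mean with event-count weights.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| classification threshold | 0.6 | mean event-wise correlation above which a trace counts as driven |
| clustering threshold | 0.75 | minimum Pearson correlation with a cluster centroid |
| minimum cluster size | 50 (full scale); 8 in the desk-scale configuration | clusters below this dissolve |
| swim window | 2 s pre / 5 s post, > 0.5 s gap | segment around bout start |
| stimulus window | 5 s pre / 10 s during | segment around motion onset |
| spatial filter | 2 × 2 px, top-left anchor, replicated edges | pre-map smoothing |
| ΔF/F baseline | 10th percentile, 30 s sliding window | robust to activity-dense trials |

The "2 pixel mean spatial filter" is implemented as a 2 × 2 uniform
kernel anchored at the top-left pixel (a radius option exists); the
ΔF/F baseline has no canonical definition for this preparation, so the
sliding-percentile default can be overridden (`quiet_mean` uses frames
outside all stimulus and bout windows, `fixed` a supplied F0). The
baseline percentile is evaluated exactly at every frame by default;
`strideS` trades exactness for speed on long recordings.

## The synthetic-data generator

Every stage is validated against a seeded generator
(`simulateExperiment`) that emulates the study conditions: the 315 s
stimulus schedule; a 250 Hz tail trace whose bouts follow an
inhomogeneous Poisson process — static-period rate 0.05 Hz, sustained
motion rate 0.08 Hz plus an onset burst of 2.6 Hz decaying with
τ = 0.5 s (short-latency optomotor responses), 1.5 s refractory,
20 Hz tail beat, 30° amplitude, fast-attack envelope; and a two-channel
128 × 64 px movie with 20 ROIs per archetype. The full acquisition
geometry (512 × 249 px) is available, but the desk-scale default keeps
a full simulation around half a minute.

Four archetypes drive the planted ROIs through a shared
double-exponential calcium kernel (rise 0.05 s, decay 1 s, the order of
GCaMP5 kinetics; both configurable since indicator kinetics are a model
input):

* `swim_locked` — unit impulse at every bout onset;
* `stim_on` — boxcar over motion intervals (sustained);
* `stim_suppressed` — tonic drive minus the boxcar, floored at zero;
* `mixed` — a weak boxcar (weight 0.15) plus impulses at the *initial*
  bout of each motion period, to which each mixed ROI responds
  independently with probability 0.85.

Sustained responses are normalised to unit peak after convolution so
that the ΔF/F gain is comparable across archetypes (an unnormalised
boxcar convolution is ~5× a bout transient, which has no physiological
meaning). The `mixed` refinement — onset bouts only, probabilistic
recruitment — is a deliberate design choice: with a shared kernel and
one larva's bout train, a cell responding to *every* bout on top of a
visual drive has an event-averaged stimulus profile that is itself
plateau-shaped, and no weighting makes it simultaneously (a) classified
stimulus-driven under the 0.6 rule and (b) separable from the sustained
archetype at the 0.75 clustering threshold. Cells recruited at movement
onset are the natural sensorimotor reading of an "intermediate"
activity profile, and they satisfy both constraints.

Noise is Poisson shot noise on photon-scaled intensities (2
photons/unit) plus Gaussian read noise (σ = 2 intensity units), both
optional. The red channel carries static anatomy: a diffuse gradient
plus bright red-only blobs placed away from every green footprint.
Keeping red-dominated structures green-quiet is what makes the
bleed-through factor identifiable from the red-vs-green scatter; the
default factor is 0.15. Footprints are 2-D Gaussians (σ = 1.4 px,
truncated at 2σ) placed on a shuffled, jittered grid — at this density
a jittered grid guarantees non-overlap and capacity where rejection
sampling can stall.

What the generator does *not* emulate: motion artifacts (motion
correction is out of scope; the pipeline assumes registered movies),
source overlap and neuropil contamination (footprints are disjoint by
construction; demixing belongs to the upstream extractor), bleaching
drift, and inter-larva variability in bout kinematics. Passing the
recovery suite therefore demonstrates the correctness of the analysis
chain under its stated assumptions, not robustness to every
real-recording pathology.

## Numerical choices and degenerate inputs

* Pearson correlations are computed from moments; zero-variance inputs
  return an undefined (`NA`) value rather than raising. In
  `meanEventCorrelation` a zero-variance event contributes 0 and is
  counted (with a message); sets with fewer than two events are
  undefined and classify as `unclassified`.
* Event onsets are snapped to the nearest imaging frame; the planted
  impulse lands in the frame *containing* the bout onset. Behaviour
  runs on a 250 Hz clock, so sub-frame jitter of up to half a frame
  period (~86 ms) is inherent and accepted — the imaging rate cannot
  resolve onset-versus-offset recruitment anyway.
* Strict `>` at the classification threshold: scores exactly at 0.6 do
  not qualify. Raising the threshold is monotone (never resurrects an
  unclassified trace).
* Bouts whose padding would overlap are clipped at the midpoint so the
  bout table is always disjoint; missing tracking frames are carried as
  `NA` and never interpolated across more than 3 consecutive frames.
* The Theil–Sen fit caps its input at 400 quantile-spaced points along
  red intensity, keeping the pairwise-slope set small and the estimate
  deterministic.
* The clustering seed pair stays in its cluster even if a sweep pulls
  the centroid away, guaranteeing termination.

## Validation

`scripts/acceptance.R` (see the README) re-simulates 20 seeded
experiments at the conditions above, runs the full pipeline on each,
and reports per-archetype classification rates, the archetype-count
recovery rate, pixel-map AUC (in-footprint versus background pixels),
bout recall and precision at 50 ms tolerance, and the bleed-through
estimation error, plus an exact-partition check on a noise-free run.
The test suite additionally pins every operation to independent
brute-force oracles (direct-summation Pearson correlation, direct
convolution, hand-computed geometry) and property checks (rotation
equivariance of the bend angle, gain invariance of ΔF/F, affine
invariance of the maps, monotonicity of the classification rule).

## Known limitations

* One trial = one plane = one run unit; multi-plane volumes are
  analysed plane-wise and merged only at the map level.
* Brain registration across larvae is external; `combineAcrossLarvae`
  assumes maps already share a common space.
* The classification scores share the stimulus-locked bout structure;
  strongly mixed cells legitimately fall into the ambiguous class and
  are excluded, as the method intends.
* With a single event the triggered average equals the segment and no
  consistency score exists; such traces stay unclassified.
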