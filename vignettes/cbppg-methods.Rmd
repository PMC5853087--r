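---
title: "Homogeneity-driven ROI selection and tracking for camera-based photoplethysmography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homogeneity-driven ROI selection and tracking for camera-based photoplethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbppg)
```

## The problem

Camera-based photoplethysmography (cbPPG) extracts the blood volume
pulse from video of skin: cardiac activity modulates the light absorbed
in cutaneous vessels, so the spatial mean intensity of a skin region
oscillates at the heart rate. The modulation is tiny — on a 12-bit
intensity scale it stays within roughly ±15 units — so the choice of the
region of interest (ROI) decides whether a usable signal exists at all.
Two properties matter. The region must be *skin*, and it should be
*homogeneously illuminated*: inhomogeneous regions convert small motion
(including ballistocardiographic head motion) into intensity changes
that mask or mimic the pulse.

Classical ROI selection runs a face detector and takes fixed patches
(forehead, cheeks). That fails whenever the anatomy is partly invisible
— covered, taped, at an oblique angle — which is precisely the situation
in clinical recordings. `cbppg` implements the alternative: select and
track whatever skin happens to be visible and homogeneous, with no
anatomical model at all.

## Pipeline and models

### Skin classification

A histogram Bayes classifier over RGB color: two 3-D histograms (default
32 bins per channel, i.e. 12-bit values right-shifted to a 7-bit
resolution per axis) are filled from labeled skin and non-skin pixels
and normalized into class-conditional densities. A pixel of color $c$ is
skin when

$$\frac{p(c \mid \text{skin})}{p(c \mid \neg\text{skin})} \ge \theta,$$

with $\theta = 5$ by default; $\theta$ trades true-positive against
false-positive rate, and raising it only *under*-detects, which the
subsequent segmentation can recover (it cannot un-include background).
Colors unseen in both corpora are classified non-skin for the same
reason. Classification operates on a percentile contrast stretch of the
frame (1%/99% mapped to the full scale, per channel); the stretch
stabilizes the classifier under global illumination changes, and *only*
the classifier sees the adjusted image — every threshold elsewhere in
the pipeline (50-unit monitor, ±15-unit pulse bound) is defined on raw
12-bit intensities.

### Homogeneity segmentation

The skin mask initializes a two-phase level set: a field $\Phi$
partitions the image into $\Omega_1$ ($\Phi > 0$, the ROI) and
$\Omega_2$, and evolves by gradient descent on a region-competition
energy,

$$\frac{\partial \Phi}{\partial t} = H'(\Phi)\left[\,\sum_{j=1}^{M}
\log\frac{p_{1j}(F_j)}{p_{2j}(F_j)} \;+\; \nu\,
\mathrm{div}\frac{\nabla\Phi}{|\nabla\Phi|}\right],$$

where $p_{ij}$ is a Gaussian with the mean and standard deviation of
feature $j$ inside region $i$ (recomputed every iteration over the hard
masks $\{\Phi>0\}$ / $\{\Phi\le 0\}$, standard deviations floored at 1
intensity unit), and $H'$ is a smoothed delta function that confines
updates to a band around the contour. Features are the raw channel
intensities plus a texture image $J$ — the sample standard deviation of
each pixel's 5×5 neighbourhood, averaged over channels for RGB — so the
selected region is homogeneous both in brightness and in surface
structure. The curvature weight scales with the image,
$\nu = 0.001\,|\Omega|^{0.7}$. Because the energy is purely regional,
the ROI may be disconnected and may contain holes; darker or
non-orthogonally lit subregions of skin are expelled, which is the
entire point of the method.

### Numerical scheme

The descent is solved by forward Euler with exact reinitialization: after
every iteration $\Phi$ is rebuilt as the signed Euclidean distance to the
current region boundary (half-pixel offset, so boundary-adjacent pixel
centres sit at $\pm 0.5$ and the field crosses zero between them). Two
safeguards make this robust:

* **Bounded force.** Log-likelihood ratios of narrow Gaussians span
  several orders of magnitude across one image. If the Euler step is
  normalized by the largest raw update, every weakly attracted pixel
  receives a step far below the one-pixel threshold needed to change
  region under exact redistancing, and the contour freezes. The total
  force is therefore passed through $\tanh(f/s)$ with scale $s = 1$
  (log-likelihood units): decisive pixels saturate at ±1, ambiguous
  pixels stay proportional, and the curvature term can override only
  where the data term is weak — exactly where smoothing is wanted.
* **Adaptive step.** The update field is rescaled so its largest entry
  is `step_max = 1.2` pixels. The value must exceed 1: with exact
  redistancing the innermost band pixels sit at $|\Phi| = 0.5\ldots1.5$
  and flip only when their update crosses zero. A fixed sub-unit step
  (a conventional CFL-style choice) leaves the discretized contour
  provably immobile.

Iteration budgets follow the method's operating point: 300 iterations
for RGB detection, 100 for NIR detection (or fewer if the region stops
changing), and 50 during tracking with an early stop once the region
size changes by fewer than 50 pixels between iterations. The early stop
is a tracking device — inter-frame changes are minor — and is *not*
applied during detection, where the contour must first sweep from the
classifier mask to the homogeneity optimum.

Degenerate evolutions ($\Omega_1$ vanishing or filling the grid) are
returned as a status, never raised; callers treat them as "no usable
ROI" and redetect.

### RGB→NIR transfer

The NIR camera sees the same scene from a slightly different viewpoint
under its own illumination, and has no color for the skin classifier.
The RGB ROI is transferred by block matching: each 5×5 block of the
green channel (the least noisy) lying fully inside the ROI is matched
into the NIR frame over the inclusive displacement window
$d_x \in [-60, 0]$, $d_y \in [0, 10]$ (camera geometry known a priori),
minimizing the mean-adjusted MSE
$\sum[(I_G - \mu_G) - (I_N - \mu_N)]^2$ — mean adjustment removes the
photometric offset between the differently lit views. Ties resolve to
the smallest $|d_x|+|d_y|$, then by row-major order. The union of
displaced block footprints initializes the NIR segmentation; blocks are
matched independently (no smoothness constraint), since the subsequent
segmentation absorbs incoherent outliers. An ROI too thin to contain a
single block is a failed registration, reported as "no skin" for the
NIR stream only.

### Tracking and artifact monitoring

Each stream tracks independently: frame $k$'s segmentation starts from
frame $k-1$'s ROI. Two triggers force a re-detection: the ROI
collapsing (empty, degenerate, or under the 100-pixel viability floor),
and an intensity-instability monitor — the standard deviation of the
ROI's mean intensity (green channel for RGB, NIR for NIR) over the
trailing 10 s exceeding 50 units, evaluated every frame once a full
window exists. A triggered redetection runs the full detector chain on
the current frame pair, and the logged event is named by its *outcome*:

* `redetect_unstable` — the detector immediately found skin again; the
  tracked region was unstable but skin is visible (e.g. an illumination
  step).
* `redetect_no_skin` — the detector found no skin; an episode of absent
  ROIs begins and the detector is retried every frame (backing off to
  every 10th frame after 100 consecutive failures) until skin
  reappears (e.g. a full occlusion).

Outcome-based naming is the only mapping that keeps both canonical
artifacts clean: an occlusion first trips the intensity monitor (the
mean jumps as soon as the occluder covers the region), but what has
*happened* is that skin vanished. After every successful (re)selection
the monitor is paused for 10 s and its buffer is reset — a fresh region
means a fresh baseline, and without the reset the old region's
statistics would immediately re-trigger.

### Signal chain and evaluation

Per-frame spatial means over the ROI give four channel signals (R, G,
B, NIR) with explicit missing entries where no ROI existed. Signals are
cut into consecutive non-overlapping 10-s segments; any segment
containing a missing entry is discarded from the signal chain (but
counts as a false detection in the HDR). Each valid segment is
detrended (least squares), highpass-filtered — order-250 Hamming
windowed-sinc FIR, 0.5 Hz cutoff, applied forward-backward for zero
phase — zero-padded to $2^{13}$ points and Fourier-transformed. The HR
estimate is the largest amplitude in 30–200 bpm (ties toward lower
frequency); at 100 fps the bin width is $100/8192$ Hz ≈ 0.732 bpm. The
SNR compares spectral power within ±5 bpm of the reference HR and of
its first harmonic against the remaining band power, in dB, capped at
±80 dB for noise-free fixtures.

Study-level evaluation computes, per subject and channel, the
heart-rate detection rate (HDR: percentage of segments deviating *less
than* 5 bpm from the reference — strict inequality — with missing
segments counted false) and the median SNR over valid segments.
Channel combinations (G&B, G&R, G&NIR) assume the correct channel can
be chosen per segment, i.e. a per-segment OR of correctness.
Combinations are compared against the green channel by a one-tailed
paired Wilcoxon signed-rank test: exact null distribution by dynamic
programming for up to 25 pairs (ties handled through midranks, zero
differences ranked but excluded from the statistic, following Pratt),
normal approximation with tie correction beyond.

## The synthetic scene generator

Real intraoperative recordings cannot be redistributed, so the package
ships a scripted generator that emulates the *statistical* structure
the method relies on, not photometric realism:

* skin-toned elliptical regions whose color matches the synthetic
  corpus cluster (trivariate Gaussian around a typical skin tone,
  R > G > B); non-skin drawn from a broad uniform mixture plus a dark
  cluster;
* a raised-cosine pulse at the scripted heart rate added to skin
  pixels, per-channel amplitudes validated against the ±15-unit bound;
* a smooth spatial texture field *shared* between the RGB and NIR
  renderings — this shared structure is what makes intensity-based
  block matching across the two views meaningful — with the NIR stream
  displaced by an integer viewpoint offset and lit independently
  (optional radial spot-light falloff, off by default, since its real
  profile is unknown);
* additive Gaussian sensor noise (default sd 5), clipped to the 12-bit
  range;
* scripted events: full or rectangular occlusions (rendered as exactly
  constant, noise-free patches — an opaque matte object near the
  lens), global illumination steps, and scene translations;
* 3% deep-shadow and 3% specular-highlight speckles in the background.
  Natural scenes contain both extremes; without them a synthetic scene
  spans only a fraction of the scale, the 1%/99% stretch becomes a
  large affine distortion, and the classifier is probed far off its
  corpus — a degenerate-scene artifact, not a property of the method.

Ground truth (per-frame skin masks on both grids, the scripted HR, an
event log) is carried alongside. Identical script + seed give
bit-identical frames; frames render lazily so long recordings need no
storage.

What passing tests on these fixtures shows: the implementation of
classifier, segmentation, registration, tracking and signal chain is
correct against independent oracles and scripted ground truth. What it
does not show: performance on real skin (BCG motion, specular drift,
sensor nonlinearity, real NIR optics are not modeled). The headline
clinical numbers of the underlying study are therefore not claimed
here.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `theta` | 5 | — | classifier ratio threshold |
| `bins_per_channel` | 32 | — | histogram resolution (bin width 128 of 4096) |
| `adjust_saturation` | 0.01 | fraction | percentile stretch before classification |
| `iters_detect_rgb/nir` | 300 / 100 | iterations | detection budgets |
| `iters_track` | 50 | iterations | tracking budget |
| `early_stop_px` | 50 | pixels | tracking early stop on region-size change |
| `nu_coef`, `nu_exp` | 0.001, 0.7 | — | curvature weight $\nu = c\,|\Omega|^e$ |
| `epsilon` | 1.5 | px | smoothed-delta width |
| `sigma_floor` | 1.0 | intensity | Gaussian region-model floor |
| `min_roi_px` | 100 | px | viability floor; smaller = no usable ROI |
| `search_dx`, `search_dy` | [−60, 0], [0, 10] | px | block-match window |
| `monitor_window_s`, `monitor_sd_max`, `monitor_pause_s` | 10, 50, 10 | s / intensity / s | artifact monitor |
| `segment_s` | 10 | s | analysis window |
| `fir_order`, `fir_cutoff_hz` | 250, 0.5 | —, Hz | highpass design |
| `fft_pad` | 8192 | samples | zero-padding length |
| `hr_band_bpm` | [30, 200] | bpm | HR search band |
| `snr_halfwidth_bpm` | 5 | bpm | SNR signal bands |

The `min_roi_px` floor is this package's own addition: "the ROI
disappeared" must be operational, and a region under ~100 pixels cannot
deliver the spatial averaging the signal model assumes. The FIR design
(windowed sinc, zero-phase application), the delta smoothing
$H'_\varepsilon(\phi) = \varepsilon/(\pi(\varepsilon^2+\phi^2))$ with
$\varepsilon = 1.5$ px, the exact-EDT reinitialization, per-iteration
recomputation of region statistics, and the block-match tie-break are
design choices where the method description leaves the discretization
open; each default is recorded in `ppg_config()` and can be overridden.

## Problem sizes in tests

Tests and the acceptance script run the study conditions at desk scale:
frames of 60×80–80×100 pixels and 30 fps recordings of 40–190 s (the
nominal recording geometry, 320×420 at 100 fps, is the generator's
default). 30 fps is the smallest rate at which a 10-s segment (300
samples) still exceeds the 251-tap FIR warm-up; all physical thresholds
(±15-unit pulse bound, amplitude 10, noise sd 5, 50-unit monitor, 5-bpm
tolerance) are kept at their stated values.

## Known limitations

* Pure curvature flow on an exactly force-free (uniform) image can
  stall on small regions once the discrete curvature maxima lie outside
  the contour; the tracker does not rely on it — occlusions are caught
  by the intensity monitor and the no-skin detector outcome.
* The signed-distance property is checked with a 5×5
  steepest-descent-slope diagnostic (`sdf_slope`); axis-aligned central
  differences are not meaningful on a lattice EDT, whose kinks make
  them dip far below 1 at pixel scale.
* Block displacements are estimated independently per block; a
  smoothness prior would help at low texture but is deliberately
  omitted (the NIR segmentation absorbs outliers).
* The monitor channel for the RGB stream is green (the cbPPG workhorse
  channel); the method description does not name one.
* Whether the original pipeline re-ran registration at NIR redetection
  or reused the instantaneous RGB ROI is not documented; here
  redetection always re-runs the full detector chain.
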