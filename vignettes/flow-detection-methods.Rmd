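---
title: "Separating respiratory flow from motion in thermal video: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating respiratory flow from motion in thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflow)
```

## Why separate flow from motion

A thermal camera pointed at an infant sees respiration twice. Exhaled air
warms and cools the nostrils, the mouth and nearby textiles; thermal
diffusion spreads this into smooth, roughly circular oscillating regions —
the *respiratory flow* (RF) pixels. The breathing effort also moves the
body, which modulates image intensity wherever a sharp thermal edge exists
(head against sheet, blanket against face) — the *respiratory motion* (RM)
pixels. RM oscillations can be in phase or in anti-phase with the flow,
depending on which way the edge moves relative to its temperature
gradient, while RF regions always warm during exhalation.

A signal that pools both kinds of pixel (a *mixed respiratory*, MR,
signal) is fine for rate estimation but useless for detecting an
obstructive apnea, where the flow ceases and the effort continues: the
motion keeps the mixed signal oscillating straight through the event. The
detector implemented here finds the RF pixels automatically, with no face
or body landmarks, using only two physical properties: RF regions are
smooth 2-D blobs away from edges, and RM pixels sit on (possibly curved)
line-like edges and may be anti-phase.

## The per-window model

The video (merged camera views, one image plane) is resampled to a uniform
9 Hz by per-pixel linear interpolation and processed in 8 s windows of
N = 72 samples sliding in 1 s steps. Per window the detector computes:

* **Gradient `G`** — Sobel magnitude of the window-mean frame, thresholded
  at a fraction `tauG = 0.2` of its maximum and dilated by 1 px.
  Multiplying by `(J - G)` removes edge pixels — the primary RM defence.
* **Pseudo-periodicity `Q̃`** — per pixel, the amplitude spectrum of the
  band-passed window signal (zero-padded to 512 points) is normalized to
  unit sum and the height of its peak inside 30–110 BPM is taken; the map
  is normalized per window.
* **RR clusters `W̃`** — the fraction of the 5×5 neighbourhood whose
  dominant in-band frequency lies within 7.5 BPM of the pixel's own.
* **Correlation map `C`** — Pearson correlation of every pixel signal with
  the *core-pixel* (argmax of `Q̃·W̃·(J−G)`), binarized as `|C| > 0.6`
  into `Ĉ`. The absolute value keeps anti-correlated pixels: the sign
  distinction is deferred to the covariance map.
* **Covariance map `C̃_flow`** — the mean product of each (band-passed,
  zero-mean) pixel signal with the signal at the *previous window's
  flow-core-pixel*, normalized to [−1, 1] by the map's maximum absolute
  value, sign preserved; all ones in window 1. Covariance rather than
  correlation is used deliberately: it weights pixels by oscillation
  amplitude, and its kept sign rejects anti-phase motion, which the
  correlation gate alone cannot.

The flow map `FM = Ĉ·C̃_flow·Q̃·W̃·(J−G)` is binarized at the strict
threshold `FM > 0.2`. The binary map is convolved with a bank of Gabor
filters (wavelengths 3–8 px/cycle, orientations 10°–170° in 10° steps, 102
kernels) and the response magnitudes are multiplied elementwise: a smooth
blob responds at every orientation while a line drops out at some, so the
product's argmax — the *flow-core-pixel* — lands in the flow region even
when window 1's map still contains RM or noise pixels. Window 1
contributes only this pixel to the RF set; later windows contribute all
supra-threshold pixels, and when none passes, the previous window's set
and core are carried over (the detection conditions are strict by design,
and the covariance chain needs an anchor in every window).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `rateHz` | 9 Hz | uniform resampling rate (camera mean is ~8.7 Hz) |
| `bandBpm` | 30–110 BPM | infant breathing band (0.5–1.83 Hz) |
| `xi1` | 0.6 | correlation-map binarization threshold |
| `xi2` | 0.2 | flow-map binarization threshold (strict `>`) |
| `lambdas`, `thetas` | 3–8 px, 10–170° | Gabor bank grid |
| `tauG`, `dilate` | 0.2, 1 px | edge threshold fraction and dilation |
| `neighborhood`, `deltaFBpm` | 5 px, 7.5 BPM | RR-clusters window and tolerance |
| `shortStdS`, `longStdS`, `alpha` | 8 s, 15 s, 0.5 | cessation detector |
| `filterOrder` | 4 | Butterworth band-pass order |

The thresholds `xi1`/`xi2`, the band, the Gabor grid and the 8 s/15 s
cessation windows are the method's stated values. The remaining
realizations are this package's documented choices where the method leaves
them open:

* **Band-pass filter**: 4th-order Butterworth applied forward–backward
  (zero phase) per pixel over the *whole segment*, not per window —
  per-window filtering would ring at every window edge, and phase must be
  preserved because the covariance sign carries meaning. The per-pixel
  mean is removed before filtering so the large thermal offset cannot
  excite edge transients.
* **Gabor envelope**: Gaussian σ from λ via a one-octave half-response
  spatial-frequency bandwidth, aspect ratio γ = 0.5 — the canonical
  defaults of standard Gabor implementations; both configurable. Kernels
  are complex quadrature pairs and the response magnitude is the modulus,
  giving phase-invariant blob detection. Convolution uses reflective
  padding; a zero border would fabricate an edge and bias argmaxima near
  the frame boundary.
* **Numerical safety**: the product of 102 response maps underflows
  doubles, so it is accumulated in log space with a floor of 1e−30 per
  factor; a test confirms the argmax matches the direct product.
* **Normalizations**: `Q̃` and `W̃` are divided by their window maximum
  (not min–max scaled), so an all-coherent map stays all ones;
  `C̃_flow` is divided by its maximum absolute value, the simplest
  map-level rule consistent with the stated [−1, 1] range. Zero-variance
  pixels get correlation and covariance 0, never a division by zero.
* **RR-clusters counting**: the denominator is fixed at k²−1 = 24;
  out-of-grid or silent neighbours count as disagreeing, which naturally
  down-weights borders.
* **Core selection ties** break to the lowest row, then column — every
  argmax in the pipeline is deterministic.
* **Signal stitching**: window 1 contributes its full 72 samples, every
  later window its 9 new samples averaged over the current RF set —
  causal, no overlap weighting, one value per video sample. The
  flow-core is re-selected by the Gabor bank in *every* window (the
  covariance of window j+1 needs the core of window j); when the product
  map is flat the previous core is retained.
* **MR signal**: pixels with `|C| > 0.6` around the `Q̃·W̃·(J−G)` core;
  anti-correlated pixels are sign-flipped before averaging (otherwise
  anti-phase motion cancels in-phase motion and the "respiration signal"
  interpretation collapses); the flip is configurable off.
* **Cessation rule**: the short-term standard deviation uses the same
  8 s/1 s windowing as everything else; the long-term value is the
  *trailing* median of short-term values inside 15 s — trailing so the
  long window is not dominated by the event it should detect — and a
  window is flagged when `short < alpha·long` with α = 0.5, the simplest
  instantiation of "sudden amplitude drop". The rule is scale invariant,
  and an all-zero signal never fires (strict inequality).
* **RR estimator**: the maximum of the 512-point zero-padded magnitude
  spectrum inside the band, reported at the bin centre (~1.05 BPM
  spacing); parabolic refinement exists behind a flag but the default
  favours exact reproducibility. When the global spectral peak lies
  outside the band, the in-band peak is returned flagged as low
  confidence.

## The synthetic phantom

The clinical recordings behind the method are private, so the package's
evidence comes from a seeded phantom that reproduces the *statistical
structure* the detector relies on:

* a static background (smooth horizontal ramp, ~1 °C) plus a warm body
  ellipse (+4 °C) with a sharp boundary;
* one or more flow blobs `amp·exp(−r²/2σ²)·sin(φ(t))` (default amplitude
  0.4 °C, σ = 3 px) sharing a single global breathing phase, 48 BPM by
  default — one subject, one rate;
* a motion source at the body boundary: the edge band (within 1.5 px of
  the boundary, Gaussian-decaying from 0.4 °C) oscillates in phase or in
  anti-phase, and a weak diffuse halo (0.055 °C at 3–4 px outside the
  boundary, on one flank) models fabric shifting with the effort *near*
  but off the edge — in real recordings the gradient mask never covers
  every motion pixel, and this halo is what lets the MR signal keep
  tracking motion during an apnea;
* i.i.d. Gaussian sensor noise (0.05 °C, the NETD scale of a low-cost
  thermal core) and uneven sampling at mean 8.7 Hz with ±10% uniform
  interval jitter;
* during configured apnea intervals the flow amplitude is exactly zero
  while the motion persists — an obstructive apnea.

Ground-truth masks mark pixels receiving at least 20% of a source's peak
amplitude; a human annotation is emulated by the mask's bounding box plus
a 2 px margin (annotators box every visibly flickering pixel, and the
correlation gate detects flow somewhat beyond the 20% contour). The preset
scenes use a single 60×80 camera view — a single-subject scene needs one
view, and the merged 180×80 plane remains the default for multi-view
inputs. Scenes of 20–60 s keep the full test suite within minutes; the
acceptance checks run the two motion scenes at 60 s and ten 60 s apnea
seeds.

What passing phantom tests shows: the pipeline's selectivity (edge
removal, anti-phase rejection, covariance tracking, fallback) and its
detection chain work as designed under the assumed signal model. What it
does not show: robustness to gross body motion (the method applies to
still segments; re-initialization after motion is an explicit non-goal),
to non-sinusoidal breathing waveforms, to camera drift, or to the
geometric quirks of real infant scenes — the known hard case of nostril
flow seen edge-on is included as the `nostril_on_edge` stress preset, and
there the edge removal swallows the flow region exactly as reported for
real data.

## Degenerate inputs and edge cases

Constant frames produce an empty gradient map (exact spatial-domain Sobel,
no FFT noise); all-zero windows produce zero pseudo-periodicity, undefined
dominant frequency and an NA respiration rate; a window whose flow map has
no supra-threshold pixel inherits the previous RF set and core; a flat
Gabor product raises in window 1 (there is nothing to anchor on) and falls
back afterwards. Zero-height annotation boxes, non-monotonic timestamps,
mismatched view widths and too-short segments are rejected with explicit
errors.

## Known limitations

The covariance chain assumes the subject does not move between windows; a
`detectRfPixels()` call on a segment containing gross motion will track
whatever the flow-core drifts onto. PF/PM on the phantom are not
comparable to values measured on clinical recordings — the phantom's
annotation is exact by construction while human annotation is not, and the
phantom contains a single flow region. The cessation detector's α and the
obstructive-apnea simulator's low-frequency splice at 30 BPM are
documented free parameters; both matter only for the apnea proof of
concept, whose claim here is the *ordering* — the RF signal exposes the
simulated apnea, the MR signal hides it — not any particular percentage.
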