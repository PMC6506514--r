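---
title: "Measuring fish swimming kinematics from silhouette video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fish swimming kinematics from silhouette video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkin)
```

## The measurement problem

A fish swimming steadily against the current in a small water tunnel bends
its body in a periodic traveling wave. Neurotoxicological and biomedical
studies use the kinematics of that wave — how strongly the body bends, how
far the tail swings, how fast it beats — as a quantitative readout of motor
function: ataxia-like phenotypes show up as reduced bending angles and
tail-beat amplitude at an unchanged beat frequency. The raw data are
high-speed videos (typically 1000 frames per second) of a single fish
viewed side-on as a dark silhouette against a lighter, indirectly lit
background.

`gaitkin` turns such a video into per-frame posture measurements and
per-video endpoints. The processing chain is, per frame:

1. **Pre-processing** — intensities are normalized by a percentile
   contrast stretch and smoothed with a small Gaussian kernel.
2. **Motion clipping** — the user's region of interest is further clipped
   to the moving region, found by differencing against a static
   background estimate.
3. **Segmentation** — Otsu's threshold binarizes the clipped region; the
   8-connected blobs are measured and the one matching size/shape
   criteria for a fish silhouette is selected.
4. **Midline extraction** — the blob is thinned to a one-pixel skeleton
   (Zhang–Suen), the longest endpoint-to-endpoint path through the
   skeleton is taken as the dorsal curve, oriented head-first, and four
   points A, B, C, D are placed at arc-length fractions 0, 1/3, 2/3, 1.
5. **Kinematics** — the three segments AB, BC, CD yield the signed
   head–trunk angle $\beta$, trunk–tail angle $\gamma$ and head–tail
   angle $\alpha$; the tail-beat amplitude $a$ is the distance from D to
   the line through A and B.

Per-frame validity checks (exactly one qualifying blob; skeleton contained
in the blob; non-degenerate histogram; non-cyclic skeleton; distinct
points) guard every stage, and a whole-video rule admits a video into the
evaluation only when strictly less than 10% of its frames are invalid.

## Angle and summary definitions

With direction vectors $u_{head} = B - A$, $u_{trunk} = C - B$,
$u_{tail} = D - C$, each angle is the signed turning angle between two
vectors, computed as $\mathrm{atan2}(u \times v,\, u \cdot v)$ in degrees.
The sign convention is positive counterclockwise in image coordinates
(x right, y down); it is fixed and documented but immaterial downstream,
because the summaries use absolute values.

Per video, for each angle signal:

* **Half cycles** are the intervals between consecutive zero crossings of
  the mean-subtracted, low-pass-filtered signal (4th-order Butterworth,
  `smooth_hz = 25` Hz by default, applied forward–backward so it is
  zero-phase). Crossing positions are linearly interpolated, rounded to
  frame indices; intervals shorter than 3 frames are merged into a
  neighbor. A signal with $m$ crossings yields $m - 1$ half cycles.
* **Mean tail-beat frequency** counts full cycles (pairs of consecutive
  half cycles) and divides by the time spanned from the first to the last
  used crossing — a cycle-domain estimate using all cycles of the
  fragment. The discrete-Fourier peak is used as an independent oracle in
  the tests, never as the estimator.
* **Half-cycle curvature** is the time average of $|\text{angle}|$ within
  each half cycle, averaged across half cycles. For a sinusoid of peak
  $P$ this converges to $(2/\pi)P$, which the tests verify to 1%. The
  per-half-cycle *peak* is also reported (`curvature_peak_deg`) as an
  optional companion statistic, since "average over half a cycle" is a
  time average here by design.
* **Tail-beat amplitude** is summarized as the mean over half cycles (of
  the $\gamma$ signal) of the per-half-cycle maximum of the per-frame
  amplitude — amplitude conventionally means peak excursion per beat. The
  per-frame quantity is the D-to-AB-line distance; only the aggregation
  is a package choice. For a straight-swimming fish with no detectable
  half cycles the summary falls back to the mean per-frame amplitude
  (zero for a straight body).

Amplitudes are reported both in pixels and in body lengths (BL). The body
length defaults to the median midline arc length over valid frames;
`body_length_px` in the configuration can override it with a measured
standard length.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `low_pct`, `high_pct` | 1, 99 | percentile | contrast stretch anchors; saturating extremes suppresses faint fins |
| `gaussian_sigma` | 1.5 | px | noise smoothing; 0 disables (appropriate for clean synthetic video) |
| `diff_threshold` | 10 | intensity | motion-detection change threshold |
| `bg_frames` | 25 | frames | background median window |
| `margin_px` | 10 | px | dilation of the motion bounding box |
| `min_area_frac`, `max_area_frac` | 0.002, 0.25 | fraction of ROI | admissible blob size |
| `min_elongation` | 2.5 | – | fish silhouettes are elongated |
| `min_solidity`, `max_solidity` | 0.3, 0.95 | – | fins and bending make real fish non-convex |
| `smooth_hz` | 25 | Hz | half-cycle filter cutoff, far above tail-beat rates (~10 Hz at 2 BL/s) yet killing pixel jitter |
| `max_gap` | 20 | frames | longest invalid gap bridged by interpolation (20 ms at 1000 fps) |
| `max_invalid_fraction` | 0.10 | – | strict video rejection threshold |

Contrast enhancement is a global percentile stretch rather than histogram
equalization because it is monotone and predictable; whether a tile-based
local method would do better on unevenly lit tunnels is untested. The
motion-detection defaults (median background, threshold 10, margin 10) are
deliberately conservative; every value is exposed in the configuration and
the flat key-value config file.

Two conventions are fixed once, package-wide: blobs and skeletons are
**8-connected** (the connectivity Zhang–Suen thinning assumes), and the
default polarity is a **dark fish on a light background** (silhouette
imaging). Otsu ties are broken toward the smallest maximizing threshold so
the estimator is deterministic.

## The synthetic generator and what it does (not) show

`fish_model_config()` + `generate_video()` render a ground-truthed video
of an undulating silhouette. The midline's lateral displacement is a
single sinusoidal traveling wave
$y(s,t) = A(s)\sin(2\pi f t - 2\pi s/\lambda)$ with a linear amplitude
envelope $A(s)$ — the canonical first-order model of carangiform
swimming. The displaced curve is re-scaled axially so its arc length
always equals the nominal body length, which keeps BL-normalized outputs
well defined under bending. The body is painted as the set of pixels
within a tapering half-width profile of the midline (rounded snout, thin
caudal peduncle), plus optional i.i.d. Gaussian pixel noise; rendering is
a pure function of the configuration and frame index, so videos are
bit-reproducible.

Defaults describe the intended operating point: an adult zebrafish
swimming steadily at a mild-to-moderate speed — body length 200 px in a
512×160 frame, 1000 fps, tail-beat frequency 10 Hz, tail amplitude 15 px
(0.075 BL), wavelength 0.95 BL. One second of video at these settings is
the standard fragment analyzed in the tests and the acceptance script.

Crucially, ground-truth angles and amplitudes are produced by applying
the *same* geometry functions (`equidistant_points()`, `joint_angles()`,
`tail_amplitude()`) to the true midline — there is no second definition
that could drift from the pipeline's.

The generator emulates what the pipeline needs to be correct about:
silhouette contrast, body taper, traveling-wave bending, sensor noise,
and (via `corrupt_frames()`) dropouts, split silhouettes and speckle
clutter. It does **not** emulate fins, body texture, shadows,
reflections, out-of-plane rolling, hydrodynamic irregularity or multiple
fish. Passing the recovery tests therefore demonstrates that the
geometric and temporal estimators are correct and numerically stable on
clean-to-moderately-noisy single-fish silhouette video; it does not prove
robustness to the full messiness of real tunnel footage, where the
selection criteria and preprocessing settings carry that burden.

Because synthetic silhouettes have no fins, a nearly straight synthetic
fish is almost convex; analyses of synthetic video therefore relax the
solidity ceiling to 1 (`selection_criteria(max_solidity = 1)`), while the
default 0.95 remains the right gate for real, finned fish.

## Numerical choices and degenerate inputs

* A constant frame has no percentile spread; the stretch maps it to all
  zeros, and Otsu on any constant region raises a classed
  degenerate-histogram condition that the pipeline converts into an
  invalid frame.
* Thinning retreats from the rounded head by roughly one half-width (the
  medial axis of a cap ends near its center). The pipeline compensates by
  extending the oriented path along its end tangents until the blob
  boundary (`extend_midline = TRUE`); with the extension the estimated
  body length lands within a few percent of truth. The accuracy tests on
  extracted midlines use the directed Hausdorff distance from the
  extracted path to the true midline, which is the meaningful direction:
  it catches spurious branches without penalizing the residual end bias.
* Head/tail assignment uses the blob's distance transform (the head end
  is thicker); an exact tie falls back to a configured tunnel heading
  (`head_x_sign`), since fish in a flow tunnel face upstream.
* Spurious skeleton branches are pruned by taking the weighted diameter
  of the skeleton graph: the maximum over endpoint pairs of the shortest
  (geodesic) path between them, with steps weighted 1 and $\sqrt 2$. A
  skeleton with no degree-1 pixel (a cycle) invalidates the frame; a
  disconnected skeleton is reduced to its largest component with a
  warning.
* Zero-crossing detection assigns exact zeros the sign of the preceding
  nonzero sample, so a tangential touch does not double-count. Crossings
  within the filter's edge transient (a few tens of samples at the very
  start or end of a fragment) can be missed; with one-second fragments
  and ~20 crossings this costs at most one half cycle.
* Blob selection ties are resolved by area, then elongation, then
  bounding-box x — a total order, making the pipeline deterministic
  byte-for-byte.

## Worked example

```{r example, eval = FALSE}
cfg <- fish_model_config(wave_frequency_hz = 10, amp_tail_px = 15,
                         fps = 1000, duration_s = 1)
video <- generate_video(cfg)

res <- analyze_video(video,
                     gait_config(fps = 1000, gaussian_sigma = 0,
                                 criteria = selection_criteria(max_solidity = 1)))
res
summary(res)
plot(res)
```

On this noiseless video the analysis accepts all 1000 frames and recovers
the 10 Hz tail-beat frequency within a few hundredths of a Hz on all
three angle signals, with per-frame angle errors of about two degrees
RMS — numbers recomputed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` at every run.

## Known limitations

* Single fish only; no tracking, no occlusion handling.
* The midline is a pixel path, not a subpixel spline; angle traces carry
  ~1–2° of quantization jitter, which the 25 Hz filter removes before
  cycle detection but which remains in the per-frame angles.
* The head-end bias of thinning is compensated, not eliminated; point A
  is the least accurate of the four.
* Frequency estimation assumes an oscillatory signal with at least two
  full cycles in the (possibly gap-split) fragment; shorter fragments
  yield flagged, undefined summaries rather than guesses.
* Left/right asymmetry, swimming speed, Strouhal number and group-level
  statistics are out of scope.
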