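# gaitkin

Swimming-gait kinematics of a single fish from high-speed silhouette
video.

Fish forced to swim steadily in a water tunnel bend their bodies in a
periodic traveling wave, and the geometry of that wave is a sensitive
readout of motor function: neurotoxic insults that produce ataxic gait in
mammals show up in fish as reduced bending angles and tail-beat amplitude
at an unchanged beat frequency. `gaitkin` extracts those endpoints from
high-speed video (e.g. 1000 fps) of a dark fish on a lighter background,
for researchers doing behavioral phenotyping of locomotion in zebrafish
and similar species.

## Method

Per frame, the pipeline runs

> percentile contrast stretch + Gaussian smoothing → motion-based
> clipping of the region of interest → Otsu binarization → 8-connected
> blob detection and size/shape-based fish selection → Zhang–Suen
> thinning → longest skeleton path, oriented head-first → four points
> A, B, C, D at arc-length fractions 0, 1/3, 2/3, 1.

The three body segments AB, BC, CD give the signed inter-segment angles —
head–trunk *β*, trunk–tail *γ*, head–tail *α* (each the turning angle
atan2(u × v, u·v) between the segment direction vectors) — and the
tail-beat amplitude *a*, the distance from D to the line through the head
segment AB. Per video, half cycles of bending are the intervals between
zero crossings of each mean-subtracted, low-pass-filtered angle signal;
from them come the mean tail-beat frequency (full cycles over spanned
time, using all cycles of the fragment), the average half-cycle curvature
(time average of |angle|, which for a sinusoid of peak *P* equals
(2/π)·*P*), and the mean per-beat peak amplitude in px and body lengths.

Validity checks at every stage (single qualifying blob, skeleton
contained in the blob, non-degenerate histogram, non-cyclic skeleton)
mark frames invalid; a video is accepted for evaluation only when
strictly less than 10% of its frames are invalid.

A ground-truthed synthetic generator (`generate_video()`) renders an
undulating fish silhouette whose midline follows a traveling bending wave
y(s,t) = A(s)·sin(2πft − 2πs/λ) with known frequency, envelope and
wavelength, so every stage is validated by parameter recovery — no real
videos are required to test the tool.

## Worked example

```r
library(gaitkin)

cfg <- fish_model_config(wave_frequency_hz = 10, amp_tail_px = 15,
                         fps = 1000, duration_s = 1)
video <- generate_video(cfg)

res <- analyze_video(video,
                     gait_config(fps = 1000, gaussian_sigma = 0,
                                 criteria = selection_criteria(max_solidity = 1)))
res
#> <gait_analysis: 1000 frames at 1000 fps, ACCEPTED (0.0% invalid)>
#> Gait summary
#>   frames: 1000 (0.0% invalid)
#>   alpha freq   9.99 Hz  half-cycle curvature  13.81 deg  (9 cycles)
#>   beta  freq  10.00 Hz  half-cycle curvature  11.65 deg  (9 cycles)
#>   gamma freq  10.01 Hz  half-cycle curvature  19.07 deg  (9 cycles)
#>   tail-beat amplitude: 32.26 px = 0.1505 BL
```

The 10 Hz tail-beat frequency of the simulated fish is recovered within
0.01 Hz on all three angle signals; the curvature values are the time
averages of |α|, |β|, |γ| over half cycles of bending, and the amplitude
endpoint is the mean per-beat peak distance from the caudal-peduncle
point D to the head-segment line, in pixels and body lengths (the
per-beat peak exceeds the 15 px lateral tail amplitude because the head
line tilts against the tail's excursion). `plot(res)` draws the angle and
amplitude traces; `write_gait_csv()` / `write_gait_json()` export
per-frame values and the summary.

A thin command-line wrapper is installed with the package
(`exec/gaitkin`): `gaitkin analyze video.avi --config cfg --out outdir`,
`gaitkin synth --out outdir` (uncompressed AVI + PNG frames + ground
truth CSV), `gaitkin summarize trace.csv`. Exit status 3 means the video
was rejected by the invalid-frame rule.

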