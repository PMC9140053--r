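---
title: "Super-resolution ultrasound velocimetry of the renal microvasculature: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolution ultrasound velocimetry of the renal microvasculature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalsrus)
```

## The problem

Ultrasound localization microscopy (ULM, also called super-resolution
ultrasound, SRUS) maps micro-vessels far below the diffraction limit by
localizing individual intravascular microbubbles (~2.5 µm contrast agent)
in thousands of contrast-mode frames and linking the localizations into
tracks. Microbubble speed is a surrogate for blood velocity. `renalsrus`
implements a complete analysis chain for coronal scans of the rat kidney:

1. **Localization** — per-frame detection and sub-pixel weighted-centroid
   localization of bubbles.
2. **Motion compensation** — patch-based non-rigid motion estimation from
   interleaved B-mode frames, applied to the localizations.
3. **Tracking** — hierarchical Kalman multi-target tracking with
   Rauch–Tung–Striebel smoothing; per-position velocity vectors.
4. **Mapping** — super-resolved density images and RGB direction/velocity
   maps.
5. **Flow separation** — assignment of tracks to six vascular beds
   (cortical arteries/arterioles and veins/venules; outer- and
   inner-medulla descending and ascending vasa recta) using region masks
   and angular flow sectors around the mean arterial direction.
6. **Velocity statistics** — 30-s moving averages, alignment of scan 2 to
   the prazosin injection, per-scan and sub-period means, paired t-tests,
   repeated-measures ANOVA with Greenhouse–Geisser correction, Tukey
   post-hoc comparisons, and Pearson correlations with mean arterial
   pressure (MAP).

Because raw scanner data of this kind are not publicly deposited, the
package ships a first-class synthetic module — a renal vascular phantom,
ground-truth bubble trajectories under a prazosin hemodynamic model, and a
frame renderer — so every downstream stage is tested against known truth.

## The synthetic phantom

`build_renal_phantom()` constructs a 2-D coronal cross-section with three
nested regions (cortex outermost, then outer medulla, then inner medulla)
on a 128 × 128 grid at 0.05 mm pitch (6.4 × 6.4 mm field; configurable).
Vessels are straight segments fanning from the kidney center:

* **Cortex** — 6 arterial and 6 venous vessels over a 110° wedge; arterial
  flow points outward (toward the renal surface), venous inward. Venous
  vessels interleave the arterial comb half a step off, alternating sides
  so the venous mean direction opposes the arterial mean by exactly 180°.
* **Outer medulla** — 3 descending (inward) and 3 ascending (outward)
  vasa recta on the same fan geometry.
* **Inner medulla** — vasa recta bundles are modeled as near-parallel
  chords along the wedge axis at 0.35 mm lateral spacing, descending flow
  toward the papilla, matching the loss of angular fanning deep in the
  medulla.

All inter-vessel spacings exceed ~0.35 mm. This is deliberate: two bubbles
closer than the sum of their supra-threshold image radii (~0.3–0.35 mm at
the default point-spread sigma of 0.075 mm and detection threshold) merge
into a single image component, and the pipeline does not attempt
multi-emitter splitting (see *Limitations*). The phantom therefore
emulates the dilution/resolvability regime ULM acquisition is designed
for.

Default bed speeds are the baseline (scan 1) means: 1.59 mm/s in cortical
arteries/arterioles, 0.70 mm/s in outer-medulla descending vasa recta,
with slower venous/ascending beds (0.85, 0.55, 0.60, 0.50 mm/s for
cortical veins, OM-AVR, IM-DVR, IM-AVR). The first two are the observed
calibration targets of the simulated prazosin experiment; the remaining four are plausible values consistent with the
ordering arterial > venous and cortex > medulla, chosen once.

## Hemodynamic model

`hemo_params()` defines a piecewise-exponential MAP trace: a baseline
plateau (84 mmHg) until 10 s after injection, an exponential descent
reaching exactly the minimum (54 mmHg) 67 s after injection (the center of
the observed 52–82 s range), then an exponential relaxation (time constant
90 s) toward the recovery plateau (65 mmHg). Gaussian noise (sd 4 mmHg)
rides on top. Only the landmark values are constrained by observation; the
exponential shape is the package's own choice of a smooth curve through
them, with the drop time constant set to a quarter of the onset-to-peak
interval so the minimum is met cleanly.

Commanded bubble speeds couple to MAP through a normalized excursion
`x(t) = (MAP_baseline − MAP(t)) / (MAP_baseline − MAP_min)` in [0, 1]:
during scan 2 each responsive bed's multiplier is `1 − α·x(t)`, with α
scaled so the *mean* multiplier over the post-injection analysis window
equals the configured scan-2 target (1.14/1.59 for cortical arteries,
0.66/0.70 for OM-DVR; the other beds showed no significant response and
keep multiplier 1). This normalization makes the commanded window mean
equal to the target at any window length, which is what the
parameter-recovery checks compare against. Scans 1 and 3 use constant
multipliers.

Bubbles arrive per vessel as a Poisson process (default 0.3 bubbles per
vessel per second — a free parameter, since the infusion-rate to in-plane
arrival-rate conversion is not derivable from first principles) and are
advected along the centerline by exactly `speed/frame_rate` per frame, so
the recorded per-step speed is the instantaneous commanded speed.
Optional disruption (default 0.02/s hazard) truncates trajectories, as
many bubbles are destroyed before reaching the ascending vasa recta.

## Rendering and tissue motion

Each in-frame bubble is an isotropic Gaussian blob (σ = 0.075 mm) with
log-normal per-bubble amplitude (mean 10 a.u., CV 0.2) on additive
Gaussian background noise (sd 0.5 a.u.). The B-mode channel is a static
speckle-like texture (Gaussian-smoothed white noise) warped backward by
the tissue motion field; it can be rendered at a reduced cadence
(`bmode_every`) to represent interleaved acquisition.

Residual respiratory motion is a smooth, periodic, spatially varying
displacement field: sinusoidal in time at the ventilation rate
(69 breaths/min), with a Gaussian depth envelope whose peak row gives a
maximum displacement exactly equal to the configured amplitude (default
0.1 mm — residual motion after mechanical stabilization, about two
pixels). This is *not* a model of free breathing; it is the small
quasi-periodic residual the motion-estimation stage must remove.

## Localization

Frames are Gaussian-smoothed (σ = 1 px), thresholded (absolute threshold
2 a.u. by default, percentile mode available), and 4-connected components
with at least 3 pixels become candidates. The localization is the
intensity-weighted centroid of the component on the smoothed frame, with
pixel `(r, c)` centered at `((c+0.5)·pitch, (r+0.5)·pitch)` (x lateral, y
axial depth, origin top-left). On noiseless symmetric blobs the centroid
is exact; at the default noise it is accurate to a few hundredths of a
pixel.

Components whose intensity-weighted second-moment ellipse is elongated
beyond an axis ratio of 2 are rejected. Single bubbles image as
near-isotropic blobs; an elongated component is almost always two bubbles
merging, and its centroid tracks neither bubble — following such
centroids produced spurious slow tracks between opposed vessels in early
versions of the phantom experiments.

## Motion estimation and compensation

Non-rigid motion is estimated per B-mode frame against the first frame of
the scan in 3 × 3 mm patches with 80% overlap (0.6 mm stride). Each patch
takes the integer displacement maximizing normalized cross-correlation
within a search window, refined per axis by a parabolic fit through the
NCC peak and its neighbors; summed-area tables make the search linear in
frame size. Patches keep a margin from the frame border equal to the full
search radius so every patch can reach every shift; flat patches get zero
displacement and a low-confidence flag. Successive frames reuse the
previous frame's median shift as a warm start with a ±2 px search
(respiratory tissue motion moves well under a pixel per frame), falling
back to a full search whenever a peak lands on the search-window edge.

The patch vectors are bilinearly interpolated to localization positions
(clamped at the borders) and *subtracted*; each localization uses the
nearest-in-time field. On the synthetic round trip (known sinusoidal
field, default speckle), static-bubble scatter shrinks by more than 5×
and positions are recovered well within half a pixel RMS.

## Tracking

A constant-velocity Kalman filter per track (state `x, y, vx, vy`;
white-acceleration process noise, default sd 2 mm/s²; measurement noise
default 0.025 mm = half a pixel) with tiered, gated, globally optimal
association:

* **Tiers** — confirmed tracks associate before tentative ones; within a
  status tier, slow tracks (≤ 5 mm/s) before fast ones.
* **Gate** — candidate pairs must lie within
  `max_speed·dt + 3·meas_sd` (with the 15 mm/s span and 54 Hz: 0.35 mm).
  Confirmed tracks additionally tighten their gate to
  `speed·dt + 4·innovation sd`: once the velocity is known, a candidate
  far beyond the expected displacement is implausible, and accepting it
  stitched neighboring opposed vessels together in development runs.
* **Assignment** — within the gate, a shortest-augmenting-path solver
  finds the one-to-one assignment minimizing total squared innovation
  distance (each localization used at most once); it is oracle-tested
  against brute-force enumeration.
* **Lifecycle** — unmatched localizations spawn tentative tracks; 3 hits
  confirm; 2 consecutive misses (or any miss while tentative) terminate;
  tracks with fewer than 5 observed positions are dropped.

Finished tracks are Rauch–Tung–Striebel smoothed, and the per-position
velocity vectors and speeds used by all downstream statistics come from
the smoothed states (time-stamped per position, which the moving-average
graphs require). Steps whose speed exceeds the 0–15 mm/s tracking span
break the track. On noise-free straight-line input with zero-noise filter
settings the smoothed speeds are exact to better than 10⁻⁶ mm/s; a
simulated 20 mm/s bubble yields no confirmed track because consecutive
localizations fall outside the gate.

## Flow separation

Tracks are assigned to the region (cortex / outer medulla / inner
medulla) containing the majority of their positions. Within each region a
flow sector around the mean arterial angle classifies the track by the
length-weighted circular mean of its in-region step directions: arterial
if within half the sector span of the mean angle, venous if within half
the span of the opposed direction, excluded otherwise. The spans are 125°
(cortex, wider because afferent arterioles radiate at varied angles from
the cortical radial arteries) and 90° (medulla), read as *total* sector
widths — the half-width reading would make arterial and venous sectors
overlap, which the opposed-direction definition of veins rules out; a
half-width interpretation remains available by doubling the configured
span. `mean_arterial_angle()` estimates the mean angle from an ROI of
tracks for real data; synthetic runs use the phantom's ground-truth
sectors.

## Periods, alignment and statistics

Speed samples are per track position (one sample per smoothed position,
at that frame's timestamp). Moving averages use centered 30-s windows at
1-s steps, with empty windows left missing; across-subject aggregation
averages per time step without interpolation. Scan 2 is aligned to the
injection: display span from 50 s before to 410 s after injection (460 s
total), scan-2 mean over the 410 s after injection, scans 1 and 3 over
their first 410 s. Sub-periods of scan 2 are its first 30 s (baseline),
the contiguous 30-s window with the lowest mean MAP (earliest on ties),
and its last 30 s (recovery). Scan and sub-period means weight each
position equally (a per-track option exists); a position-weighted mean
under-weights fast episodes slightly (fast bubbles spend fewer frames in
the field), a ~2% effect at the default modulation depth.

Statistical comparisons operate on variance-stabilized speeds: natural
log in the cortex, square root in the medulla. `rm_anova_gg()` is a
within-subject one-way ANOVA whose degrees of freedom are scaled by the
Greenhouse–Geisser epsilon, computed from the condition covariance matrix
through orthonormal contrasts (`ε = tr(M)²/((k−1)·ΣM²)`, clamped to
`[1/(k−1), 1]`); it is verified against the covariance-entry-sum formula.
Tukey comparisons use the studentized range on the within-subject error
mean square with `(n−1)(k−1)` degrees of freedom. `paired_t()` and
`pearson_log()` wrap the base R tests with explicit degenerate-case
flags.

For power properties, `simulate_subject_means()` draws per-subject scan
means around the commanded values with a multiplicative subject effect
and residual noise on the transformed scale (both sd 0.15 by default —
together matching the ~24% between-animal coefficient of variation of the
baseline cortical speeds). Running the full frame-level pipeline for
every subject of every replicate batch would be computationally
meaningless here (hundreds of full simulations to re-measure what the
recovery tests already quantify), so the detection-power property is
assessed at the subject-mean level: with 7 subjects and the default
effect, the GG-corrected repeated-measures ANOVA on log cortical speeds
rejects at α = 0.05 in ~90% of replicate batches.

## Problem sizes and numerical choices

The reference recovery session runs two scans of 120 s at 54 Hz on the
128 × 128 grid (6480 frames per channel per scan), a field and duration
chosen so a complete two-scan run finishes in a few minutes on a single
core while leaving 4500–8000 track positions per bed — recovered scan
means then sit within ~3% of the commanded values, comfortably inside
the 10% acceptance band. Unit and property tests use a 64 × 64 phantom
and 4–20 s scenes. Other numerics: NCC denominators below 10⁻⁹ mark a
patch flat; the innovation covariance carries a 10⁻¹² jitter so zero-noise
filtering stays well-posed; the RTS backward gain falls back to zero
(keeping filtered states) if a predicted covariance is numerically
singular; assignment forbids pairs via a large finite cost so maximum
cardinality precedes cost; circular means snap results within 10⁻⁹ of
360° to 0.

## What passing tests do and do not show

The simulator is an idealization: Gaussian blobs instead of a measured
point-spread function (no side lobes, no depth dependence), additive
Gaussian noise instead of speckle statistics on the contrast channel, a
smooth single-mode respiratory field, straight vessels, and no
out-of-plane motion. Passing the recovery tests shows the chain is
unbiased and self-consistent under these conditions; it does not certify
accuracy on scanner data, where point-spread anisotropy, clutter,
attenuation and out-of-plane flow add biases the phantom does not model.
Known limitations, by design: merged bubble images are rejected rather
than split (dense convoys are invisible to the tracker); arterial/venous
separation is purely directional, so vessels flowing against their bed's
main direction are misclassified (pulsatility-based separation is out of
scope); and volume flow is not estimated — speeds are bubble speeds, not
flow rates.
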