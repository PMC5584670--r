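---
title: "Closed-loop visually guided patch clamp on a virtual rig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop visually guided patch clamp on a virtual rig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchrig)
```

## The problem

Two-photon targeted whole-cell patch clamp lets an electrophysiologist
record from a genetically or morphologically identified neuron in vivo
rather than from whichever cell a blind pipette happens to meet. Automating
it is hard for one central reason: pushing a glass pipette through cortical
tissue deforms the tissue viscoelastically, so the target cell migrates
away from the coordinates where it was selected, while the shallow depth of
field of two-photon excitation makes the cell vanish from view after a few
micrometres of axial drift. A robotic system therefore has to *servo*: see
the cell, step the pipette, re-find the cell, correct the trajectory, and
repeat — while simultaneously managing pipette internal pressure and
interpreting the electrode impedance to know when it has touched, sealed
onto, and broken into the cell.

`patchrig` implements that control stack end to end and couples it to a
built-in virtual rig — synthetic imaging, tissue mechanics, pneumatics, and
a pipette/membrane impedance simulator — so that every layer is exercised
and tested without a microscope or an animal.

## The virtual preparation

`make_scene()` builds a volume (coordinates in micrometres, z negative
below the pial surface) containing fluorescent somata and a dye-filled
pipette cone. The default study scene holds one 10 um target soma at
(0, 0, −120) plus three seeded distractors.

Rendering (`render_frame()`) uses a deliberately minimal optical model:

* a soma is a Gaussian blob of lateral width
  `sqrt((diameter/4)^2 + (z_sigma0 + z_defocus_rate * |dz|)^2)` — the soma
  extent convolved with a defocus-dependent blur;
* its amplitude is scaled by `exp(-dz^2 / (2 * axial_visibility_sigma^2))`
  with a sigma of 3 um, emulating two-photon optical sectioning: a cell a
  few micrometres off the focal plane fades into the background;
* a uniform ambient floor (`background_level`, default 1500 of 65535)
  stands in for autofluorescence and dye accumulation. The floor matters:
  contrast scores are ratios, so without an absolute reference a defocused
  Gaussian blob would keep the same relative contrast at any blur. Against
  a floor, defocus costs real contrast, which is what makes contrast-based
  focusing work here (and in tissue);
* noise is Poisson-like shot noise (exact Poisson below 30 expected
  photons, Gaussian above) plus Gaussian read noise, generated as a
  deterministic function of (scene seed, time, focal plane) so that
  identical configurations replay bitwise-identically.

Tissue mechanics: each insertion step displaces every cell by
`push_gain * exp(-r / decay_length)` times the step vector (`r` = distance
from the pre-step tip position), after which a fraction
(`relaxation_fraction`, default 0.3) of the displacement relaxes back with
a 5 s time constant. The paper-level design constraint is that a single
3–4 um step near the target must not move it by more than half of the
smallest targeted soma diameter (~5–8 um); the defaults
(`push_gain = 0.75`, `decay_length = 25`) put a 3 um step at the target at
~2.3 um of migration, just inside that bound for the configured 6 um
smallest soma. The true rheology of cortex varies widely; this
two-parameter exponential push is a deliberate stand-in that produces the
phenomenon the tracker must survive, not a mechanical model of brain.

Breathing (1 Hz, 0.6 um) and heartbeat (8.3 Hz, 0.25 um) move all cells
rigidly along a mostly axial axis. Both are zero-mean, so targets that
blink out of focus reappear at the same place — the property the tracker's
occlusion budget exploits.

What the generator does *not* emulate: depth-dependent scattering and
signal loss, dye ejection building up near the tip, anisotropic or
plastic tissue flow, electrode flex. Passing tests therefore demonstrate
the correctness and closed-loop robustness of the algorithms under
plausible optics and mechanics — not performance statistics transferable
to tissue.

## Image quantification

`segment_frame()` runs the on-line chain: channel separation,
local-median background correction (31 px window), Otsu thresholding,
hole filling, particle analysis. Two practical details:

* **Noise-floor guard.** Otsu always finds *a* threshold, including inside
  the unimodal histogram of a signal-free frame. The working threshold is
  therefore never allowed below `noise_floor_k` (5) times the MAD of the
  raw plane, so empty frames yield zero particles instead of hundreds of
  noise specks.
* **Mask geometry.** Components are labeled 8-connected on the filled,
  pre-erosion mask. For each particle the *internal* mask is the component
  eroded by a 2 px disk and the *external ring* is the band between the
  original and eroded boundaries. The contrast-focus score is
  `(mean(internal) - mean(ring)) / mean(internal)`, probed on the
  *original* (uncorrected) plane. It is scale-invariant, may be negative,
  and is `NA` when the interior mean vanishes.

Design choices that were genuinely open and are fixed here: binary (not
intensity-weighted) centroids, since segments are binary after
thresholding; lowest-threshold tie-breaking in Otsu; 8-connectivity for
foreground with 4-connected hole filling; background correction by local
median, which removes smooth shading exactly while leaving compact blobs
intact.

## Autofocus

`sweep_focus()` steps the virtual objective through a centered z-grid
(default ±10 um in 2 um planes), segments a ±8 um window around the target
at each plane, and records the target's score (0 when undetected).
`fit_focus_gaussian()` fits `a * exp(-(z - mu)^2 / 2w^2) + c` by
Levenberg–Marquardt, initialized at (range, argmax, 2·step, min). The peak
is the new focal estimate; the fit is rejected in favor of the argmax
sample when it leaves the sweep range, collapses below one plane spacing,
or leaves more than half the score range as residual. On noise-free
synthetic sweeps the fitted peak lands within 0.2 um of the true soma
depth; with 5% score noise it stays within one half plane spacing in well
over 95% of sweeps. Sweeps are centered and bidirectional — the method
needs only the samples, not their acquisition order.

## Tracking and the step-and-reacquire contract

The correspondence problem is solved locally: the detection nearest the
track's last position within a gate of half the smallest soma diameter
(3 um), ties broken by higher contrast then lower label. There is no
motion model — step-synchronized acquisition keeps displacements inside
the gate by design, which is simpler and easier to reason about than a
filter, and the occlusion budget (5 frames, roughly one breathing cycle at
4 Hz) absorbs periodic disappearances.

`reacquire_after_step()` enforces the core safety contract: after every
insertion step the target must be re-found — laterally, or axially via an
autofocus sweep — before the servo may step again. A subtlety discovered
on the virtual rig: a bright soma stays laterally matchable even 3–4 um
off focus, because its score declines only gently while the amplitude is
far above the ambient floor. Contrast decay alone is therefore not a
sufficient refocus trigger. The approach loop additionally forces a sweep
every 8 steps far from the target, every 4 within 60 um, and every 2
within 25 um, where per-step migration is largest; this bounds the axial
staleness of the track and keeps the total 3D tracking error inside the
gate throughout the approach.

## The approach servo

`plan_entry()` translates the pipette laterally so the (fixed) manipulator
axis passes through the target and places a standoff point 250 um up-axis.
From there `run_approach()` interleaves: re-aim at the tracked position
(lateral correction capped at 1.5 um per step), advance
`min(step_length, distance - contact_distance)`, deform the scene,
re-acquire. Internal pressure is staged: 25 kPa during navigation, dropped
to 7.5 kPa once within 20 um of the target (boundary inclusive, latched so
centroid jitter cannot bounce the setpoint). The loop ends at a contact
distance of one cell radius (3 um); if the step budget (3x the ideal step
count) runs out within 8 um of the target, a single flagged correction
move closes the gap — the automated analogue of the small manual nudge an
operator is allowed.

## Pneumatics

A discrete PID (1 kHz, derivative-on-measurement, clamped integral and
output) drives a signed first-order plant (tau = 0.1 s) that collapses the
physical valve network — positive branch, Venturi vacuum branch, selector
valve — into one saturating system bounded by [−80, 50] kPa. The
commanded pressure is scaled by actual/nominal supply, so supply drift is
a genuine disturbance: open loop it would displace the equilibrium
proportionally; the integral term absorbs it, which is the practical
argument for closed- over open-loop pressure control. Default gains
(kp = 3, ki = 30) settle a setpoint change within ~0.5 s; the paper gives
no gains, so these are tuned against the simulated plant's stated time
constant.

## Electrophysiology and the seal state machine

The seal test is a 10 mV, 10 Hz square wave sampled at 20 kHz; the evoked
current is filtered with an order-4 digital Bessel filter designed from
the analog prototype (reverse Bessel polynomial, −3 dB normalization,
prewarped bilinear transform; DC gain exactly 1). The per-cycle resistance
is amplitude over peak-to-peak current, with the peak-to-peak measured
between plateau medians so the filter's edge transient does not bias it;
the reported value is the median across cycles (chosen over the mean for
robustness). A digital filter cannot have its cutoff at the Nyquist
frequency, so the default cutoff sits at 9 kHz (0.45 of the sample rate)
and the configuration rejects cutoffs at or above Nyquist.

The membrane simulator is staged: constant bath resistance (6 MOhm);
contact raises it 1.3x (engagement is declared on a 20% sustained rise);
during sealing the resistance grows logistically toward 1.5 GOhm at a rate
multiplied by `(1 + 0.5 |P_suction|) (1 + |V_hold|/70)` — gentle suction
and hyperpolarization both speed seal formation, and the package asserts
that property rather than assuming it. The growth law is invented: the
literature describes the manoeuvre, not gigaseal biophysics. Per-run
lognormal variability (sd 0.25 on the rate; rupture threshold lognormal
around 30 kPa of cumulative pulse amplitude) represents cell-to-cell
variation; these values are fixed study conditions, not tuning knobs.

Sealing proceeds as an operator would: pressure released, holding stepped
to −70 mV, and the adaptive rule evaluated continuously — *iff* the
resistance is below 15% of the seal target *and* has grown less than
5 MOhm over the trailing 2 s window, suction deepens by 1 kPa (bounded at
−10 kPa, at most once per window). A seal is declared at 1 GOhm; break-in
applies escalating suction pulses (−15 kPa, −5 kPa steps, 10-pulse budget)
until the resistance collapses by at least 10x, which lands at the 16 MOhm
access-resistance scale typical of whole-cell recordings.

## Orchestration, determinism, and problem sizes

`run_experiment()` wires the stages in the canonical order — positioning,
approach, engagement, seal, break-in, whole-cell — with an append-only
event log (single terminal event: `wholecell` or a machine-readable
failure), a resistance/pressure/depth trace, and the approach trajectory
against ground truth. All timing is simulated seconds at fixed ticks
(frames at 4 Hz, seal ticks of 0.1 s, controller at 1 kHz); nothing reads
the wall clock, so a configuration plus seed reproduces a run exactly.
Simulated times-to-seal (~40–60 s) are not calibrated against in vivo
durations, which include much slower biological dynamics.

The shipped test suite runs each module against analytic oracles
(exhaustive Otsu maximization, closed-form deformation and first-order
responses, generated Gaussian sweeps) and closes with a 50-seed end-to-end
batch at the default conditions — chosen to keep the whole suite within a
few minutes on one core while leaving every stage of every run fully
logged. On that batch the whole-cell rate exceeds 90%, every insertion
step obeys the half-diameter bound, and no step is ever taken while the
target is not visible.

## Known limitations

* The optical, mechanical, and membrane models are the simplest members of
  their families that exhibit the phenomena the controller must handle;
  none is predictive of tissue.
* Only the selected target is tracked; multi-pipette and multi-target
  operation are out of scope.
* Blind-mode descent is exposed only as a minimal configuration flag; its
  performance is not part of the tested surface.
* The pipette tip position is taken from the (exact) virtual manipulator;
  visual tip re-detection is not modeled.
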