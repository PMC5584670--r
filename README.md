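# patchrig

Control algorithms for robotic two-photon *targeted* whole-cell patch-clamp
recording, developed and tested entirely against a built-in virtual rig.

Targeted patching records from a specific fluorescently labeled neuron
rather than from whichever cell a blind pipette happens to contact. The
obstacle to automating it is mechanical: advancing a pipette through soft
tissue deforms it viscoelastically, so the target migrates away from its
selected coordinates while the shallow two-photon depth of field hides it
after a few micrometres of axial drift. `patchrig` implements the
closed-loop answer — visual servoing — together with the surrounding
instrumentation logic, and couples all of it to simulated optics, tissue
mechanics, pneumatics, and electrode impedance so every layer is testable
on a desk.

## What is inside

* **Scene simulator** (`make_scene`, `render_frame`,
  `apply_insertion_step`) — fluorescent somata and a dye-filled pipette
  cone in a 3D volume; Gaussian-blob optics with an axial visibility
  envelope (sigma ~3 µm) emulating two-photon sectioning; exponential
  push-field deformation with viscoelastic recoil; breathing/heartbeat
  motion; seeded shot and read noise. 16-bit multi-page TIFF I/O
  (`write_stack`/`read_stack`).
* **Vision** (`segment_frame` and its parts) — background-corrected Otsu
  segmentation, hole filling, 8-connected particle analysis, and the
  contrast-focus score of object *i*,

  CFS_i = (⟨I⟩internal,i − ⟨I⟩external,i) / ⟨I⟩internal,i,

  where the internal region is the particle eroded by a 2 px disk and the
  external ring is the band between the original and eroded boundaries.
* **Autofocus** (`sweep_focus`, `fit_focus_gaussian`) — CFS-versus-z sweep
  over the target's region of interest; the focal estimate is the peak of
  a fitted Gaussian, with an argmax fallback under documented rejection
  rules.
* **Tracking** (`associate`, `update_track`, `reacquire_after_step`) —
  local nearest-neighbour correspondence inside a gate of half the
  smallest soma diameter, an occlusion budget for periodic physiological
  disappearance, and the step-and-reacquire safety contract: the servo
  never steps while the target is not visible.
* **Servo** (`plan_entry`, `approach_step`, `run_approach`,
  `pressure_for_distance`) — axis alignment, rapid advance to a 250 µm
  standoff, then 3 µm insertion steps interleaved with reacquisition and
  per-step re-aiming; internal pressure staged 25 kPa → 7.5 kPa inside
  20 µm of the target.
* **Pneumatics** (`pid_step`, `plant_step`, `settle`) — discrete PID with
  anti-windup driving a saturating first-order plant standing in for the
  positive/Venturi valve network; supply-pressure drift enters as a real
  disturbance the loop must reject.
* **Ephys** (`seal_test_waveform`, `bessel_lowpass`,
  `estimate_resistance`, `impedance_response`, `adaptive_suction_step`,
  `detect_seal`, `detect_breakin`, ...) — 10 mV / 10 Hz seal test sampled
  at 20 kHz, order-4 digital Bessel filtering, per-cycle R = V / I_pp,
  a staged pipette/membrane impedance simulator, and the adaptive-suction
  rule: deepen suction iff R < 15% of the seal target *and* R grew less
  than S_th over the trailing T_seal window.
* **Rig** (`run_experiment`, `run_batch`, `select_target`) — the full
  state machine (positioning → approach → engagement → seal → break-in →
  whole-cell) with an append-only event log, trace and trajectory tables,
  and exact seeded reproducibility. A thin CLI lives in `exec/patchrig`
  (`simulate`, `patch`, `track`, `report`).

## Worked example

```r
library(patchrig)

res <- run_experiment(experiment_config(seed = 42))

res$status
#> [1] "wholecell"
stages_visited(res)
#> [1] "positioning" "approach" "engagement" "seal" "breakin" "wholecell"
res$steps
#> [1] 89
```

Seed 42 walks the pipette from a 250 µm standoff to membrane contact in
89 bounded insertion steps, seals at simulated t = 77.8 s with the
resistance crossing 1.00 GΩ, and breaks in after 2 suction pulses,
landing at a 16.0 MΩ access resistance:

```r
event_values(res, "sealed", "resistance") / 1000   # GOhm at seal
#> [1] 1.004794
res$final_resistance                               # MOhm after break-in
#> [1] 16.00516
tr <- res$trajectory
max(sqrt((tr$tracked_x - tr$true_x)^2 + (tr$tracked_y - tr$true_y)^2 +
         (tr$tracked_z - tr$true_z)^2))            # worst 3D tracking error
#> [1] 1.951348
```

The trajectory table compares the tracked target against the simulator's
ground truth: despite ~18 µm of cumulative insertion-induced migration,
the tracker stays within 2 µm — inside its 3 µm association gate — which
is what lets the approach terminate at the 3 µm contact distance.
`res$trace` carries the resistance / current / holding / pressure / depth
time course of the whole procedure, and `res$events` the machine-readable
log (JSON-lines on disk when `outdir` is set).

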