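# ribxromm

Rib kinematics during breathing, from marker-based biplanar
videoradiography (XROMM) data.

## The problem

In crocodylians and many other amniotes, lung ventilation is driven by
rotation of the ribs about their joints with the vertebral column. The
double-headed (bicapitate) vertebral rib articulates with two vertebral
facets — the parapophysis (P) and diapophysis (D) — and the classic hinge
hypothesis says the rib rotates about the line through them, so joint
*anatomy* should predict joint *motion*. Testing that requires measuring
the actual 3D rotation axis of each rib in a living, breathing animal, at
sub-degree resolution, and comparing it with the axis predicted from bone
morphology.

`ribxromm` implements that measurement chain for marker-based XROMM data
(reconstructed 3D marker trajectories at 60–100 frames s⁻¹, with tracking
precision around 0.12 mm), for anyone analysing ribcage or other
multi-body skeletal kinematics:

1. **Rigid-body poses** — per-frame least-squares (SVD/Kabsch) fits of
   each bone's rotation and translation from ≥ 3 markers, with per-frame
   residuals; transforms are low-pass filtered (zero-phase Butterworth,
   1–2 Hz for ~0.1 Hz breathing).
2. **Rigidity screen** — intermarker distances decide what counts as one
   rigid body: constant distance (within *k*× tracking precision, default
   *k* = 2) ⇒ same body; fluctuating across a joint ⇒ mobile joint;
   fluctuating within a bone ⇒ suspected bending.
3. **Joint coordinate systems** — four joint archetypes (costovertebral,
   sternocostal, dorsal/ventral intracostal) with anatomically oriented
   axes, attached to both bones at the zero pose (maximum inhalation).
   Joint rotation is decomposed as intrinsic ZYX Euler angles
   (R = R_z·R_y·R_x): at a costovertebral joint, Z-rotation is bucket
   handle, Y calliper, and X pump handle motion.
4. **Breath normalization** — cycles segmented at inhalation peaks,
   resampled to 100 phase points, mean-zeroed and averaged across breaths.
5. **Axis-angle comparison** — the anatomical prediction is
   **A = (D − P)/|D − P|**; the in vivo axis comes from converting the
   peak-inhalation → peak-exhalation rotation (computed on reconstructed
   rotation matrices, never by subtracting Euler angles) to axis-angle
   form (θ, unit axis). Both axes are summarized as ternary
   |x| : |y| : |z| compositions (pump : calliper : bucket) and as angles
   to the sagittal/coronal/transverse body planes, then compared by OLS
   regression against the identity line.
6. **Synthetic ribcage** — a ground-truthed generator (tripartite ribs on
   prescribed hinge or Euler motions, jittered ~10 s breaths, isotropic
   Gaussian marker noise) that serves as the test harness for the whole
   pipeline.

## Worked example

Simulate a breathing ribcage whose mid-thoracic costovertebral joint
(rib 4) hinges about its own anatomical axis, then recover that axis from
the noisy markers:

```r
library(ribxromm)

model  <- build_ribcage()
script <- default_motion_script(model, seed = 1, n_breaths = 5,
                                frame_rate = 100)   # noise sd 0.12 mm
sim    <- simulate_breathing(model, script)

joint <- lapply(model$joints["cv4"], function(j) { j$zero_pose_frame <- NA; j })
res <- run_pipeline(sim$trajectories,
                    model$bodies[c("vcol2", "rib4_vertebral")],
                    joint, predicted_axes = model$predicted_axes)
res$invivo_axes[, c("joint_id", "theta_deg",
                    "ternary_x", "ternary_y", "ternary_z")]
```

```
 joint_id theta_deg ternary_x ternary_y ternary_z
      cv4        20      44.7      30.2        25
```

The recovered total rotation is 20.0° (the scripted amplitude), and the
in vivo ternary composition 44.7 : 30.2 : 25.0 (pump : calliper : bucket)
matches the anatomical prediction for that joint, 44.4 : 30.1 : 25.6.
The pipeline's precision estimate, 0.170 mm, is the expected distance SD
for 0.12 mm isotropic marker noise (0.12·√2).

The `analysis/` scripts run the full study workflow on the default
synthetic dataset and write their tables under `results/`:
`01_simulate_ribcage.R` (dataset + ground truth), `02_rigid_bodies.R`
(precision and rigidity screen), `03_joint_kinematics.R` (JCS angles and
averaged cycles), `04_axis_comparison.R` (predicted vs in vivo axes and
regression).

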