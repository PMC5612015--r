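---
title: "Measuring rib rotation axes from marker-based XROMM data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rib rotation axes from marker-based XROMM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribxromm)
```

## The scientific question and the measurement model

Costal breathing converts intercostal muscle shortening into thoracic
volume change through rotation of the ribs about their vertebral
articulations. For a bicapitate rib, the two articular facets on the
vertebra — parapophysis `P` and diapophysis `D` — define a putative hinge
axis. In the coordinate frame used throughout this package (x
left-lateral, y caudal along the vertebral column, z dorsal) the
prediction is purely geometric:

$$ A = \frac{D - P}{\lVert D - P \rVert} $$

and the axis's composition maps onto named motions: the |x| share of the
axis predicts pump handle motion, |y| calliper motion, |z| bucket handle
motion. In crocodylian-grade anatomy the parapophysis sits on the
vertebral centrum for the first two thoracic vertebrae and then shifts
onto the transverse process, migrating laterally caudalwards, so the
prediction is a craniocaudal gradient: bucket handle motion giving way to
calliper motion from the third joint back.

Testing the hinge hypothesis requires the *measured* axis. The package's
chain is:

marker trajectories → per-frame rigid-body poses → joint coordinate
system (JCS) Euler angles → filtered, breath-normalized, averaged cycles
→ peak-to-peak rotation → axis-angle → body-plane angles → regression
against the anatomical prediction.

Every stage is an exported function; `run_pipeline()` wires them
together.

## Rotation conventions

All rotations act on column vectors. Joint rotation is decomposed as
*intrinsic ZYX* Euler angles, `R = Rz(z) %*% Ry(y) %*% Rx(x)`: first
about the joint's Z axis, then the rotated Y, then the twice-rotated X.
Angles are degrees everywhere outside function bodies; the canonical
triple has `y` in [−90°, 90°] and `z`, `x` in (−180°, 180°]. At gimbal
lock (|y| = 90°) the x-angle is set to zero, the degeneracy is absorbed
into z, and the result is flagged — a deterministic convention chosen so
tests can assert exact values.

Axis-angle conversion uses quaternion (Shepperd) extraction, which keeps
full floating-point precision at all angles including near 0° and 180°.
A subtlety worth stating: an axis-angle pair with θ in [0°, 180°] is
unique up to sign only at the endpoints, so `matrix_to_axis_angle()`
returns the *faithful* pair (Rodrigues reconstruction reproduces the
input exactly) and applies sign canonicalization only where both signs
describe one rotation, or when the caller supplies a reference axis — in
which case the axis is treated as an unsigned line and flipped to a
non-negative dot product, the form used for anatomical comparison.

The angle between a unit vector and the sagittal (YZ), coronal (XZ) and
transverse (XY) planes is `asin(|component along the plane normal|)`;
the squared sines of the three plane angles always sum to 1.

## Pose estimation and the rigidity screen

Each body's pose per frame is the closed-form orthogonal-Procrustes
optimum (SVD of the cross-covariance, determinant guard against
reflections), with uniform marker weights and per-frame RMS residuals.
Frames with fewer than three visible, non-collinear markers are missing.
A body must have at least three non-collinear reference markers
(collinearity test: second singular value of the centered positions
above 1e-6 mm).

Whether two markers belong to one rigid body is decided from their
distance series: after zero-phase low-pass filtering, a fluctuation
amplitude (5th–95th percentile range — robust to single-frame outliers)
within *k* times the tracking precision is "same rigid body"; beyond it,
"mobile joint" for a cross-bone pair and "suspected bending" for a
co-osseous pair. Tracking precision itself is the SD of unfiltered
co-osseous distances, averaged across pairs; for isotropic noise of SD σ
per marker the expected value is σ√2. The default *k* = 2 operationalizes
"fluctuation mostly within the precision band" as a ±2σ criterion. For
the screen the pipeline pairs, across each joint, the marker on either
bone farthest from the joint anchor: sensitivity to relative rotation
grows with the lever arm, so the far pair has the most detection power.

Rigid-body transforms are themselves low-pass filtered (rotation entries
filtered and re-projected onto SO(3); translations filtered
componentwise) before any joint decomposition. This matters most for the
zero pose: a JCS is anchored at an instant, and anchoring on an
unfiltered frame would freeze that frame's full tracking noise (1–2° of
orientation for sparsely marked rib segments) into every extracted angle
as a constant bias.

## Joint coordinate systems and the zero pose

Four archetypes cover the ribcage. Costovertebral and sternocostal JCSs
take the body-plane axes at the zero pose: Z dorso-ventral (dorsal
positive, bucket handle), Y cranio-caudal (caudal positive, calliper), X
medio-lateral (left positive, pump handle). Intracostal JCSs align X
with the distal rib segment's long axis, put Z in the proximal segment's
plane orthogonal to X (X then measures long-axis rotation, Z
abduction–adduction, Y = Z × X depression–elevation). All frames are
right-handed; axes are constructed in world coordinates at the zero pose
and then rigidly attached to both bodies, so the decomposition is
well-defined at every other frame and invariant under rigid motion of
the whole world.

The zero pose is maximum inhalation. When a joint is declared with
`zero_pose_frame = NA`, the pipeline resolves it to the detected
inhalation peaks and anchors on the *average* pose across all interior
peaks (chordal mean of the rotations). Maximum inhalation is a recurring
posture, and averaging suppresses the single-frame tracking noise that a
one-instant anchor would keep; recording edges are avoided because
zero-phase filtering cannot average noise symmetrically there. The joint
anchor point (JCS origin) is user-supplied; for costovertebral joints
the documented default is the P–D midpoint. Translations of the distal
anchor in the proximal JCS are reported but no analysis depends on them.

## Breath analysis

*Filtering.* Zero-phase (forward–backward) Butterworth, 4th order per
pass, default cutoff 1.5 Hz — the midpoint of the 1–2 Hz range
appropriate for ~0.1 Hz breathing, 10–20× above the motion frequency.
The series is extended by odd reflection before filtering and the
numerator is renormalized to unit DC gain, so a constant series passes
through bit-exactly and edge transients fall outside the retained
samples.

*Segmentation.* Inhalation peaks of an expansion signal delimit cycles.
The default expansion signal is the first principal-component score of
the joint's three Euler traces, oriented by correlation against a direct
ribcage-expansion proxy (mean marker distance from the per-frame
centroid, maximal when the ribs are unfolded). Peaks are local maxima —
endpoints included, so a trial starting exactly at an inhalation peak
contributes its boundary cycle — screened by height (default: above the
signal's mid-range, rejecting noise ripples on the near-flat inhalation
plateau) and thinned greedily to a minimum separation (default 3 s).
Both thresholds are parameters; shallow-breathing data may need a lower
height fraction.

*Normalization.* Each inhalation-to-inhalation cycle is linearly
interpolated onto 100 phase points (point k at phase (k−1)/99) and
mean-zeroed per component; averaging across breaths is pointwise mean
and sample SD. The removed per-component baseline travels with the cycle
as an attribute and is restored before any rotation reconstruction:
Euler angles shifted by per-component constants describe a *different*
rotation, and reconstructing from mean-zeroed triples was measured to
tilt recovered axes by several degrees. An optional cubic-spline
smoothing pass over the averaged trace is available (off by default: the
pointwise mean is the simplest reproducible reading of a
"splined average", and smoothing does not reduce the dominant,
bias-like error).

*Total rotation.* Peak inhalation and exhalation are the extrema of the
expansion signal on the averaged cycle. The two Euler triples (baseline
restored) are reconstructed to rotation matrices; their difference
rotation — never a componentwise Euler subtraction — is converted to
axis-angle. Rotations below 0.5° are flagged: the axis direction of a
near-identity rotation is meaningless.

*Comparison.* Measured and predicted axes are compared per body plane by
OLS of measured on predicted angle, with t-tests of intercept ≠ 0 and
slope ≠ 1 (identity-line departures).

## The synthetic ribcage

The generator emulates the study system: 8 thoracic vertebrae 20 mm
apart (a plausible sub-adult alligator trunk), tripartite ribs whose
segments are straight cylinders (45 / 30 / 40 mm), a sternum, and the
parapophysis migration pattern (centrum on V1–V2; transverse process
from V3, moving laterally 5 → 10.5 mm and dorsally 0 → 3 mm). With these
defaults the predicted ternary composition reproduces the expected
craniocaudal gradient (%Z falling, %Y rising from joint 3), and joint 1
has a larger bucket share than joint 7.

Marker placement mirrors sparse experimental marking: 3 beads per rib
segment at a 4 mm radial offset from the segment axis (beads mounted on
2–3 mm posts stand well off the bone; this lever is what makes long-axis
rotation observable at all), 4 markers per vertebral section (sections
of up to 3 vertebrae animated as one rigid body, with scute beads in
paravertebral rows ±6 mm off midline), and 3 sternal markers (a pose
needs three; the sparse-marking default of two would leave the sternum
unfittable). All counts and offsets are configurable; tests that probe
small-amplitude recovery use a denser "precision study" configuration
(5 markers per segment, 6 mm offset).

Motion is scripted per joint as a hinge (fixed axis — recoverable ground
truth) or independent ZYX amplitudes. The angle waveform is
`amplitude · (1 − cos 2πφ)/2` with φ the breath phase: zero at every
inhalation peak (the rest pose is the zero pose) and positive rotation
folding the ribs caudo-medially into exhalation. Breath periods are
drawn once at script construction (default 10 ± 1 s uniform, seeded) and
become part of the script, so ground-truth kinematics are identical
across noise seeds. Default costovertebral amplitudes (10–20°, peaking
at rib 4) follow the observed pattern of range of motion peaking
mid-ribcage; intracostal mobility grows caudally. Marker noise is
isotropic Gaussian, default σ = 0.12 mm — the tracking precision
reported for the emulated recordings.

What the generator does *not* emulate: temporally correlated tracking
error, marker occlusion gaps, soft-tissue coupling between adjacent
ribs, cartilage bending, vertebral flexion (available but zero by
default), and asymmetric inhale/exhale timing (available as an option).
Passing tests therefore demonstrate correctness of the measurement
chain under the stated noise model, not robustness to every artefact of
real videoradiography.

## Numerical choices and limitations

* Validation problem sizes: rotation-algebra properties use 1000 random
  rotations; pose-fit Monte Carlo uses 500 replicates of 4 markers
  spanning 15 mm at σ = 0.12 mm; end-to-end runs use 3–5 breaths at
  60–100 Hz with 8 costovertebral joints (~2000–5000 frames, ~11
  bodies). These sizes make the full suite run in about two minutes
  while keeping Monte-Carlo margins wide.
* Noiseless contracts are exact: pose fits recover synthetic transforms
  to < 1e-9, the full pipeline recovers prescribed hinge axes to
  numerical precision, and the predicted-vs-measured regression sits on
  the identity line with R² = 1.
* With noise, axis *direction* uncertainty scales as the endpoint angle
  noise divided by the total rotation. At 0.12 mm precision and default
  sparse marking the endpoint noise is ~0.2°, so a 20° hinge is
  recovered to well under 1°, while 8–10° cranial joints can err by a
  few degrees and 5° rotations sit at the noise floor. This is an
  observability limit of the marking density, not of the algorithms;
  denser marking or longer marker posts tighten it, and the same scaling
  cautions against over-interpreting measured axes of small rotations in
  real data.
* Left/right: right-side landmarks are mirrored to the left-handed
  convention before axis computation, so one sign convention holds
  across animals; whether to average sides is left to the caller.
* Intermediate results are plain data frames and CSVs (angles in
  degrees, coordinates in mm, frames 0-based in files and 1-based inside
  R, phase points 0–99);
  trajectory CSVs follow the XMALab export dialect (`<marker>_X/_Y/_Z`
  columns, blank cells for missing observations) and are written at full
  precision so write/read round trips are exact.
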