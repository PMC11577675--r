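---
title: "Virtual biplanar open-wedge HTO and squat kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual biplanar open-wedge HTO and squat kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htosim)
```

## The problem

Medial open-wedge high tibial osteotomy (owHTO) valgizes a varus knee by
cutting the proximal tibia from the medial side and opening a wedge about a
lateral hinge. Surgeons stabilise the cut with a second, roughly coronal
"biplanar" plane passed behind the tibial tuberosity. That second cut can
be extended *ascending* (the tuberosity stays attached to the distal,
moving fragment — so it translates laterally and distally as the wedge
opens) or *descending* (the tuberosity stays with the fixed plateau
fragment). The choice changes patellofemoral geometry: the ascending
variant increases the tibial tuberosity–trochlear groove distance (TT–TG)
and lowers the patella, both suspected contributors to anterior knee pain
and patellofemoral osteoarthritis after owHTO.

`htosim` implements this comparison end to end as an in-silico experiment:
synthetic lower-limb models, virtual biplanar osteotomies at wedge heights
of 6–12 mm, tendon-preserving patellar repositioning, a quasi-static squat
simulation over 5°–100° of knee flexion, and the downstream statistics
(per-curve RMSE against the preoperative model, paired change tests at
deep flexion, and linear mixed models of kinematics on wedge height and
cut variant).

## Coordinates and units

One convention everywhere: right-handed, +X lateral (right limb), +Y
anterior, +Z proximal; millimetres and degrees. Left limbs are mirrored
into this convention at creation and flagged. The knee-model builder
additionally assumes its input is in this convention (the trochlear
channel's mediolateral direction is the global X axis); the generator
guarantees it.

## Synthetic anatomy

There is no public imaging cohort behind this experiment, so the package
generates one. A `cohort_spec()` holds normal distributions `(mean, sd)`
for nine per-limb indices. The first three defaults are the preoperative
cohort statistics this artifact is calibrated against — hip–knee–ankle
angle (HKA) 178.1° ± 2.7°, axial TT–TG 13.6 ± 2.4 mm, Insall–Salvati index
0.8 ± 0.1 — and the remaining six (plateau width 75 ± 5 mm, tibia length
380 ± 25 mm, femur length 430 ± 25 mm, femoral head diameter 46 ± 4 mm,
medial tibial slope 7° ± 2.5°, patellar length 40 ± 3 mm) are population
defaults chosen once from adult anthropometry; all are configurable, none
is derivable from the source experiment, which did not report them.

The construction is *inverse*: each limb is built so that the measurement
operators recover the drawn values exactly. Varus is introduced by tilting
the tibial shaft axis in the coronal plane below the plateau (which is
where the osteotomy later corrects it); the tuberosity apex is placed at
the drawn TT–TG lateral of the trochlear groove point; the patellar poles
and tendon insertion are placed so that tendon length / patellar length
equals the drawn Insall–Salvati. The generator and the metrics module
share frame conventions by design, so the round trip
`|measured − drawn| < 1e-6` is an invariant, and cohort-level calibration
(sample means within 3 SE of the targets at n = 1000) follows.

Draws that are geometrically infeasible (e.g. a tendon too short to reach
its insertion) are rejection-resampled with a hard cap of 100, then an
error: the distributions stay clean without silent truncation. Generation
is deterministic in `(seed, index)` via a per-limb derived seed, so limbs
can be generated in any order.

Bone solids are simplified parametric extrusions (elliptic contours along
the shaft axis with a radial tuberosity bump that passes exactly through
the apex landmark), watertight by construction. They carry the plane cuts
and the fragment bookkeeping; they are *not* statistical shape models, and
nothing downstream depends on surface detail beyond the landmarks.

## Osteotomy engine

`plan_osteotomy()` encodes the surgical construction: a strictly medial
main cut parallel to the medial tibial slope, entering at a depth of half
the plateau width below the plateau on the medial cortex, hinging on a
sagittal axis 15 mm below the plateau at the lateral cortex; a coronal
biplanar plane 10 mm posterior to the tuberosity apex. The clinically
reported inclination between the two planes (~110°) is not modelled; the
biplanar plane is exactly coronal, and this is exposed through the plan's
AP-axis construction.

Opening a wedge of height *h* is a pure rotation of the distal fragment
about the hinge axis by

θ(h) = 2·asin(h / (2·W⊥)),

the angle that separates the two images of the medial entry point by a
chord of length *h*, where W⊥ is the perpendicular distance from the
entry point to the hinge axis. Whether "wedge height" is a chord, an arc,
or a plate-gauge distance is genuinely ambiguous in the surgical
literature; the chord reading is the default and an `arctan` plate-gauge
mode (θ = atan(h/W)) is available on the plan. Note a subtlety: the
entry–hinge segment is not exactly perpendicular to the slope-tilted hinge
axis, so using the raw entry–hinge distance in the chord formula would
miss the gap by ~5 µm; the perpendicular lever is used so the medial gap
equals *h* to 1e-6 mm exactly, and the raw distance is recorded separately
as `W`.

The proximal (plateau) fragment is the fixed body; the femur never moves;
all postoperative measurements live in the fixed frame. Landmarks are
assigned to fragments by the sign of their distance to the main cut plane,
except the tuberosity block (apex + tendon insertion), which follows the
variant. Two consequences are exact, not approximate: the descending cut
leaves TT–TG and Insall–Salvati bitwise unchanged, and the HKA correction
is identical between variants for the same limb and height (the ankle
experiences the same transform).

One deliberate deviation from the source experiment's tables: it reports a
small Insall–Salvati *change* (≈0.1 at ≥8 mm) for the ascending cut, even
though its own repositioning method preserves 3-D tendon length — under
which the 3-D Insall–Salvati ratio is exactly invariant. This package
computes the 3-D definition and therefore reports an ascending IS delta of
0; the nonzero published change is presumably a projected (lateral
radiograph) measurement. The ambiguity is documented here rather than
imitated.

## Patellar repositioning (ascending models)

After the wedge opens, the tendon insertion has moved laterally and
distally. The patella is repositioned as a rigid body by a pure
proximodistal translation: the distal pole keeps its AP and ML coordinates
in the femoral frame, and its proximodistal coordinate solves
`|distal_pole(z) − insertion| = L0` with the preoperative tendon length
L0, taking the proximal of the two sphere–line roots (the distal root
would put the patella below the joint line). Induced tilt or rotation is
deliberately *not* part of this anatomy update — it emerges later from the
simulator. Descending models are returned untouched, bitwise.

## The squat simulator

The source experiment used a commercial multibody engine whose internal
equations and patient-specific parameters are not published. The simulator
here is therefore a documented, self-contained *stand-in* with the same
input/output structure — kinematic curves versus flexion angle — and its
entire formulation is explicit configuration (`default_knee_params()`):

* **Bodies and DOFs.** Femur fixed. Tibia: prescribed flexion about the
  epicondylar axis plus one free DOF, internal–external rotation ψ about
  its long axis. Patella: free mediolateral shift *s*, tilt τ (about its
  long axis) and mediolateral rotation ρ (about its AP axis); its AP
  position is bound to a parametric trochlear channel and its
  proximodistal position to an inextensible patellar tendon link of
  length L0.
* **Channel.** A circular trochlear/condylar track of radius 26 mm about
  a point near the femoral knee centre, with a parabolic cross-section:
  the patellar centre rides at radial depth `R + 0.06·s²`. Under the
  compressive muscle loads this converts mediolateral force into a
  restoring force, the energetic surrogate of the groove walls.
* **Loads.** Quadriceps force `(0.3 + 1.7·sin(flexion/2))·BW·g` — a
  squat-like ramp from ~0.37 BW near extension to ~1.6 BW at 100° — along
  the line from the patellar attachment to the quadriceps origin; two
  constant hamstring forces of 0.08 BW each (biceps femoris to the
  fibular head, semimembranosus to the posteromedial plateau). Body
  weight comes from the femoral head diameter via a configurable linear
  regression (default 2.741 kg/mm − 54.9 kg, an adult-male regression of
  the Ruff family; the source names the author but not the coefficients).
* **Ligaments.** ACL/PCL/MCL/LCL as tension-only springs (120/150/80/60
  N/mm) whose slack lengths are set at the preoperative 5°-flexion
  reference pose — zero pre-tension, so the preoperative model starts
  with zero ligament energy by construction. Osteotomized models inherit
  slack lengths, stiffnesses, tendon length and body weight from their
  preoperative model, so *only geometry* differs. The MCL insertion sits
  distal to the cut and travels with the moving fragment: that is the
  geometric pathway by which the wedge perturbs tibiofemoral rotation.
* **Regularisers.** Weak quadratic restraints on ψ (1000 N·mm/rad) and on
  τ, ρ (20 000 N·mm/rad ≈ 350 N·mm/deg, a surrogate for retinacular and
  facet-contact stiffness) keep the free DOFs well-posed where all
  ligaments are slack. Menisci and articular contact pressure are omitted
  — the same structural omission the source experiment reports for its
  own model.

Equilibrium at each integer flexion angle minimises total potential energy
(spring energies plus force × length potentials for the constant-force
lines). The tendon-track constraint is eliminated analytically: the track
coordinate *u* is the root of `|A_t(u) − insertion| = L0` nearest a
per-solve *branch anchor* (the constraint generically has two roots; the
anchor — advanced only by accepted solutions — keeps the energy a pure,
history-free function of the DOFs). Gradients are analytic, including the
implicit du/dx terms, which is what lets the solver polish to relative
gradient norms below 1e-8 (BFGS followed by damped Newton with a
finite-difference Jacobian of the analytic gradient) and keeps the
default experiment's ≈18,700 solves tractable in pure R. Solves are
warm-started degree to degree; everything is deterministic — the global
seed touches only the anatomy generator.

Sign conventions (all for the right-limb coordinate convention): lateral
patellar shift +, tibial external rotation +, patellar tilt and rotation
follow the solver's axis conventions and flip sign under mirroring. A
mirrored model yields sign-flipped, equal-magnitude kinematics to 1e-6 —
this is a structural test of the formulation, checked in the suite.

### What the synthetic world does and does not establish

The generator reproduces the *index distributions* of a preoperative
cohort and the simulator reproduces the *structure* of the experiment
(which quantities respond to which cut, in which direction, growing with
wedge height). It does not reproduce: individual cadaver bone shape,
cartilage/menisci mechanics, muscle recruitment, or the numerical
magnitudes of the source experiment's RMSE tables and p-values — those
depend on 13 private anatomies and a proprietary engine. Green tests
therefore certify geometric identities, oracle equivalence, calibration,
and bookkeeping; the comparison of effect *magnitudes* against the source
is reported as qualitative concordance (logged, not asserted). On the
default 13-limb cohort the concordance report passes throughout:
ascending > descending for patellar shift, tilt and rotation RMSE medians
at every height, and descending ≥ ascending for tibiofemoral rotation at
12 mm. The tilt margin is narrow (tilt in this stand-in responds
substantially to tibial rotation, which the descending cut perturbs
more), and on very small sub-cohorts that comparison can flip; the report
records whatever is measured.

## Statistics

RMSE is computed per (limb, variant, height, parameter) over the 96-point
flexion grid against the same limb's preoperative curve, and summarised as
median/min/max per cell — the boxplot statistics of the usual reporting
style. The change test at a chosen flexion angle (default 100°, wedge
height 12 mm) is a *paired* one-sample t-test of the per-limb post−pre
differences, written out explicitly (`t = mean/ (sd/√n)`); zero-variance
cells are flagged degenerate rather than given a fabricated p-value. No
multiple-testing correction is applied by default (matching the source's
reporting); a Holm flag exists.

The mixed model is `value ~ wedge_height (centred, mm) + variant
(0 = descending, 1 = ascending) + (1 | limb)`, REML via lme4, at the
reporting angles 20/40/60/100°. The source does not state random slopes
or interactions, so the minimal random-intercept model is implemented.
lme4 provides no denominator degrees of freedom and `lmerTest` is not
available in the target environment, so Wald z inference is reported —
with 13 limbs × 14 within-limb conditions the normal approximation is
accurate, and the seeded null study in the acceptance suite measures the
type-I rate inside 5% ± 2%. Standardised coefficients (unit-SD scaling of
response and predictors) are reported alongside raw ones so the relative
importance of variant versus height is directly comparable. Normality is
supported by a quantile–quantile *export* (data only, no automated
decision), mirroring visual assessment.

## Configuration, determinism, artifacts

`default_config()` documents every key: cohort spec, heights (6–12 mm),
variants, flexion grid (5–100°, 1°), simulator parameters, statistics
options, output directory, global seed. Configs serialise to JSON
(lossless round trip; YAML was not available in the supported dependency
set, the documented-keys contract is unchanged). `cli_run()` writes a
deterministic artifact tree — landmarks (JSON), meshes (STL), curves and
tables (CSV with a config-hash header), a JSON report bundle, and a run
log — and re-running a config reproduces the tables bit for bit.
`cli_validate()` re-checks grid completeness, descending identities,
tendon conservation and fragment rigidity on a finished tree, and
enumerates missing artifacts otherwise. `hto_cli()` exposes
generate/osteotomize/run/validate subcommands with `--config`, `--seed`,
`--out`, `--heights`, `--variants`, `--limbs`, `--dry-run`.

## Numerical choices and degenerate inputs

* Cutting planes are nudged by ≤ a few 10⁻⁷ mm when they pass exactly
  through mesh vertices; exact coincidence is combinatorially fragile and
  the shift is orders of magnitude below every stated tolerance.
* `h = 0` wedges return their input bitwise (no identity-rotation
  round-off), which makes the zero-wedge identity of the simulator exact.
* Cap triangulation after a cut fans around the loop centroid; cut
  cross-sections of the parametric bones are star-shaped, so this is
  valid. Arbitrary user meshes with non-star-shaped sections are outside
  the supported envelope.
* Degenerate statistics (zero-variance differences, singular mixed-model
  fits) are flagged, never silently dropped.
* Infeasible geometry is an error with the offending limb/height named:
  repositioning with `L0² <` squared in-plane offset, wedges with
  `h ≥ 2W`, tuberosity not anterior to the plateau centre, anatomy draws
  beyond the rejection cap.

## Known limitations

The simulator is a quasi-static energy model with a single-channel
patellofemoral surrogate: no contact patches, no wrapping, no
muscle-recruitment optimisation, no dynamics; behaviour below 5° and
above 100° flexion is out of scope (as it was for the source experiment,
whose engine was also unstable there). Bone surfaces are parametric
solids, adequate for cutting and landmark kinematics, not for
shape-dependent analyses. The Insall–Salvati index is a 3-D measurement;
projected-radiograph definitions will differ for ascending models.
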