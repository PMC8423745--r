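---
title: "Displacement-driven occlusal stress analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement-driven occlusal stress analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlustress)
```

## The problem and the modelling idea

Occlusal stress — how hard and where the teeth of the two arches press on
each other — changes continuously during closing, protrusion and lateral
excursion. Classical finite-element treatments drive the mandible with
modelled muscle forces, which entangles the contact question with a much
harder neuromuscular one. `occlustress` instead treats the *recorded
kinematics as the boundary condition*: the mandibular dentition is a rigid
body whose pose at every instant is known from two recordings, and all
that remains is a contact problem between two known surfaces.

Two recording modalities are fused:

* a **displacement trace**: the 3-D position of a point on the mandibular
  central incisors (an electrognathograph magnet site), nominally at
  1000 Hz, expressed relative to the centric-occlusion reference pose;
* three **marker-pair rotation traces** at video rate: in each viewing
  plane (sagittal, frontal, horizontal) a fixed skeletal landmark and a
  movable one define a vector whose signed rotation versus its baseline
  orientation is the plane angle. The admissible pairs are RZP/gonion
  (sagittal), nasion/pogonion (frontal) and hyoid/pogonion (horizontal).

The coordinate frame is x = subject's right, y = superior, z = anterior,
origin at the mandibular incisal midpoint in centric occlusion — chosen so
a statement like "6.9 mm rightward and 6.6 mm downward" is the vector
(+6.9, −6.6, ·). All geometry is in millimetres (the dental-scan
convention); angles are radians unless a trace is read with
`angle_unit = "deg"`.

## Trajectory fusion

The two streams are not synchronously sampled, so both are aligned on the
task interval and the interval is cut into `n_segments` equal bins (the
merged-segment counts default to 18 for centric closing, 61 for
protrusion, 29 for left and 35 for right lateral excursion; they are
configuration, not computation — no rule reproduces them from the data).
At each bin end, linear interpolation of the displacement and of each
angle series yields one absolute rigid pose

$$R = R_{hor}(\theta_{hor})\,R_{fro}(\theta_{fro})\,R_{sag}(\theta_{sag}),
\qquad p \mapsto R\,(p-c)+c+d .$$

Linear interpolation is deliberate: at 1000 Hz the displacement
interpolation error is far below the video-limited angular accuracy, so
higher-order schemes buy nothing. The composition order
horizontal∘frontal∘sagittal is fixed and documented; at the recorded
centric-closing magnitudes the order is immaterial (all six orders agree
within 0.05 mm on a 50 mm point set), while with the large horizontal
excursion angles the spread reaches ~2 mm — one reason the rotation
handling below is conservative.

The **rotation center** defaults to the incisal reference point, the only
point whose translation the displacement recording actually constrains; it
is configurable because stress fields depend on it. The synthetic
recording generator renders a minimum-jerk profile
$\sigma(u)=10u^3-15u^4+6u^5$ from centric pose to the task endpoint, then
projects virtual landmark pairs through it, optionally with Gaussian pixel
jitter. Default task duration is 3.5 s — a realistic deliberate excursion
— which also places the 35 bin ends of the recovery experiments exactly on
both the 1 kHz and the 30 Hz sampling grids, so the noiseless
generate→extract→merge loop is exact to floating point and any recovery
error observed with jitter is attributable to the jitter alone. Virtual
marker baselines are ~1100 px, so 0.5 px jitter maps to ≈1 mrad of angle
noise per frame.

**Rotations in the stress experiments.** `preset_trajectory()` applies the
translational trace with the plane angles held at zero unless
`include_rotation = TRUE`. The recorded horizontal excursion angles (up to
0.471 rad if read as radians) are measured on facial landmark pairs; as
*rigid-body* rotations about the incisal point they would sweep posterior
teeth through ~2 cm, which no occlusal geometry admits — the physically
correct center (the condyle) is simply not observable from these
recordings, and if the angles are degrees they are negligible. The
kinematics layer treats rotations fully (composition, mirroring,
recovery); the stress experiments make translation-driven ordering
statements.

`mirror_trace()` reflects a trajectory about the mid-sagittal plane:
lateral translation, frontal and horizontal angles change sign, vertical
and anterior translation and the sagittal angle are preserved, and
excursion labels swap sides. It is an exact involution.

## The contact solver

Each merged segment is one quasi-static solve; the elastic response is an
elastic-foundation (Winkler) layer rather than a deformable-shell FE
model. The solver:

1. transforms the lower-arch face centroids (one material point per face)
   by the segment pose;
2. finds each point's nearest triangle on the upper arch via an AABB
   bounding-volume hierarchy (compiled; verified exactly against an
   independent exhaustive search in plain R), signs the distance by the
   triangle's outward normal, and re-pairs from scratch every frame
   (finite sliding — no persistent anchors, so arbitrarily large
   tangential motion is fine);
3. converts penetration to pressure $p = k\,\max(-g,0)$ with
   $k = E^*/h$, $E^*=E/(1-\nu^2)$ (defaults E = 84 GPa, ν = 0.3, h = 2 mm
   ⇒ k ≈ 46 154 N·mm⁻³);
4. computes Coulomb shear $\tau=\mu p$ opposing the backward-difference
   slip direction ("no elastic slip": rigid sliding, zero traction at zero
   slip speed — a kinematically driven model cannot recover stick forces);
5. reports the maximum principal contact stress
   $\sigma_1 = p/2+\sqrt{(p/2)^2+\tau^2}$ per face as a positive
   magnitude, plus per-frame contact area $\sum A_{p>0}$ and total normal
   force $\sum pA$.

Numerical conventions: separated points beyond a 5 mm cutoff are the
far sentinel (excluded from contact; the cutoff never truncates
penetrations); equidistant nearest triangles tie-break to the lowest face
index; the first frame has zero slip by definition; quads are split along
their shortest diagonal before indexing. Everything is deterministic — no
iteration, no RNG — so identical configurations reproduce byte-identical
reports.

Two closed forms anchor the solver's correctness: a rigid sphere pressed
δ into a flat foundation carries $F=k\pi R\delta^2$ (checked within 3%,
with the log–log force–penetration slope 2.00), and at fixed total force a
flat contact of doubled area halves the maximum stress (the area–stress
reciprocity the displacement-driven approach rests on).

## The synthetic dentition and its closed-form design

No subject dentition is available, so the generator builds a stylised but
mechanistically faithful occlusion: sphere-capped conical cusps (tip
radius 1.6 mm, one per tooth by default, FDI-labelled) on an elliptic arch
(50 × 45 mm, last molar placed where the arch runs fully
antero-posteriorly), opposing a swept occlusal gutter: a flat fossa floor
of half-width w = 3.96 mm sitting `centric_gap` (default 0.5 mm) above the
cusp tips, flanked by guidance walls of slope 2 (≈63°, the inner inclines
of the opposing cusps) descending 10 mm. An **interference bump** raises
one cusp by `height`, closing its centric gap by the same amount — a
balancing-side interference in miniature.

The wall geometry was designed in closed form (sphere against an inclined
plane) so that, under the recorded excursion amplitudes, the model
exhibits the clinically expected arc:

* during the native left excursion (4.1 mm lateral / 1.9 mm vertical) only
  the 0.5 mm interference on FDI 47 engages its wall (~0.16 mm normal
  penetration); sound teeth keep a ~0.06 mm clearance;
* replaying the mirrored, longer right excursion (6.9 / 6.6 mm) on the
  left side drives the same contact ~3.5× harder;
* carving the bump (depth = its height, cosine taper centred on the
  lingual flank where the wall contact occurs, so roughly half the depth
  is removed at the apex) and **re-seating** leaves ~0.03–0.05 mm
  penetrations shared between FDI 47 and the contralateral working-side
  teeth.

Re-seating deserves a note: in a purely prescribed-displacement model,
removing material from one tooth cannot change contact anywhere else. What
happens clinically is that after an interference is ground away the
mandible closes further into a new intercuspal position.
`run_modification_experiment()` therefore translates the carved model
superiorly until tangential contact before re-running the tasks; that
re-seat is exactly what creates the new working-side contacts.

With symmetric parameters the generator is exactly mirror-symmetric (left
teeth are floating-point mirrors of right teeth), which turns mid-sagittal
symmetry of the whole pipeline into a testable identity (mirrored
trajectory ⇒ mirrored stress field to ~1e−13 relative). Optional per-tooth
jitter (`jitter_sd`) breaks the symmetry reproducibly under a seed.

What the generator does **not** emulate: real crown anatomy (multiple
cusps, ridges, wear facets), periodontal compliance, arch asymmetry, and
soft-tissue-limited motion. Passing the ordering tests therefore shows the
*mechanism* — penalty contact driven by recorded kinematics reproduces
interference loading, mirror aggravation and carve relief — not that any
particular patient's stresses are predicted.

## Limitations

* The arches are rigid and the elastic response is a local foundation
  layer: absolute stress values scale with the penalty stiffness and must
  be read as orderings and locations, not tissue stresses (reported
  magnitudes land in the GPa range, as displacement-driven contact models
  of enamel tend to).
* No stick-slip hysteresis, no dynamics, no periodontal support, no
  maxillary-side report by default (the moving mandibular side is
  reported; the upper side can be obtained by swapping the arches).
* Tooth labels drive reporting only; contact is resolved on the full
  surface.

## Problem sizes

The shipped experiments use a 7-teeth-per-quadrant dentition (~31 000
moving faces against a ~1 500-face indexed gutter, ~60–130 segments per
experiment), a 3 600-element contact patch for the sphere oracle, and 20
jittered replicates for the noisy-recovery bound; a full validation pass
(test suite plus acceptance script) completes in a few minutes on one CPU.
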