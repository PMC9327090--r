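---
title: "Chest-wall surface reconstruction and breathing kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chest-wall surface reconstruction and breathing kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoraco)
```

## The problem

Opto-electronic plethysmography (OEP) tracks reflective markers on the
thoraco-abdominal surface and estimates chest-wall volumes by triangulating
and integrating the marker cloud. Classical OEP analysis stops at global or
compartmental volumes (pulmonary ribcage RCp, abdominal ribcage RCa,
abdomen AB). `thoraco` extends this to *local* analysis: it reconstructs a
closed, smoothed trunk surface, measures its geometry at the four static
respiratory volumes, derives per-vertex breathing displacement fields with
an inward-negative sign convention, and compares groups triangle by
triangle with the exact Wilcoxon-Mann-Whitney test. Local maps matter
clinically because individual compartments can move paradoxically (inward
during inspiration): the Hoover sign of the abdominal ribcage in airway
obstruction, abdominal paradox under diaphragmatic paralysis, or asymmetric
motion after thoracic surgery.

## Marker layout and mesh construction

The canonical seated protocol places 89 markers in 7 circumferential rows:
5 columns on the front sheet, 5 on the back, lateral markers on both sides,
and a denser pelvic ring at the lowest row. The protocol literature does
not enumerate the 89 positions, so the layout here is a declared,
fully configuration-driven convention (`marker_layout()`, or a flat
key-value file via `load_layout()`): front columns at 30-150 degrees,
back columns at 210-330 degrees, laterals at 0/180 degrees, five extra
row-7 markers at fixed stations, reference rows louis_angle = 2,
xiphoid = 4, umbilicus = 6, and compartments RCp = rows 1-4, RCa = 4-5,
AB = 5-7 (adjacent compartments share their boundary row). All of these
are configurable; a supine-style 52-marker variant is exercised in the
test suite.

Because the head and limbs prevent markers at the trunk boundaries, the
cloud is closed with four *virtual* markers, each an arithmetic mean of a
defining subset (top/bottom: the sheet markers of the extreme rows;
right/left: the most-lateral sheet columns). Being means, they are
recomputable fixed points of the frame. The triangulation is derived from
the layout only, so the topology is identical in every frame: ring-to-ring
bands split with a fixed diagonal rule, the top/bottom virtuals fanning the
extreme rings, and each side virtual inserted by splitting the seam
triangle of the middle row pair nearest its side. The result is watertight
and genus 0 with V = 93, and Euler's formula then forces F = 182 and
E = 273. Compartment meshes repeat the construction on their row ranges
with their own closure sets, so the sum of compartment volumes is close to,
but not identical with, the whole-trunk volume (both are reported, as
`CW_sum` and `CW_obj`).

## Smoothing

Meshes are smoothed by Catmull-Clark subdivision, the scheme underlying
NURMS smoothing in 3D modelling tools, with all control weights equal:
face points are face means, edge points average the edge endpoints and the
two adjacent face points, and a vertex of valence $n$ moves to
$(Q + 2R + (n-3)S)/n$. Each iteration maps the control-mesh vertex count to
$V + E + F$, which gives the fixed schedule 93, 548, 2186, 8738, 34946,
139778 for the trunk; `predict_counts()` is the analytic oracle and the
test suite checks the actual subdivision against it on every mesh it
builds. Output quads are split into triangles along the
(vertex-point, face-point) diagonal. "Original vertices are preserved"
is interpreted as identity preservation — indices 1..93 remain the markers
at every level — not positional pinning, which would suppress the
characteristic volume shrink; an interpolating `pin_originals` mode exists
but is off by default. The pipeline default is one iteration (548
vertices): enough resolution for local analysis while keeping per-vertex
work and file sizes small.

## Volumes, sections and the known discretisation bias

Volumes come from the divergence theorem on watertight, outward-oriented
meshes (exact for polyhedra, matching object-volume semantics of 3D
modelling software); sections are triangle-plane intersections chained into
polygons (shoelace area, summed-segment perimeter, largest component
reported, a 1e-6 mm nudge when the plane hits a vertex exactly). Internal
units are millimetres; outputs use the field's units (cm, dm^2, L).

Two systematic effects are worth stating because they bound what volume
accuracy can be expected. First, a convex cross-section sampled by $k$
markers is approximated by an inscribed $k$-gon: at equal angular spacing
the area factor is $(k/2\pi)\sin(2\pi/k)$, i.e. about $-4.5\%$ for the
12-marker rings of the default layout. The acceptance suite measures the
level-0 phantom trunk volume at about this offset from analytic truth,
mirroring the 4-5% error the field reports for 89-marker models against
gold standards. Second, Catmull-Clark smoothing shrinks a convex mesh
further (most at iteration 1, decaying after), so the level-1 volume sits
roughly 8-9% below analytic truth. The two effects stack; a bound of 5%
on the *smoothed* volume against *analytic* truth is therefore not
attainable with 12-vertex rings, and the corresponding acceptance check is
expected to stay red — the suite asserts it anyway and documents the
measured gap rather than weakening the bound. Volume *differences* (tidal
volume and capacities) inherit the inscription factor multiplicatively,
which keeps their recovery error just inside 5%.

## Phase detection and ventilatory pattern

The chest-wall volume trace is computed frame-wise from the closed
89-marker (level-0) mesh — the gold-standard signal in OEP practice.
Detection first low-pass filters the trace (moving mean over 0.25 s;
marker jitter otherwise creates spurious extrema), then finds peaks and
troughs with topographic prominence of at least 25% of the quiet-window
excursion. FRC is the median trough value and FRCVT the median peak value
over the quiet window (medians are robust to slow drift; the plausible
alternative, last-breath values, was not adopted). TLC and RV are the
global maximum and minimum of the *raw* trace; raw values are reported at
all detected indices. When no quiet window is given, it ends shortly
before the global maximum, where the capacity maneuver begins. Tidal
volume, inspiratory and vital capacity follow their definitions
(VT = FRCVT - FRC, IC = TLC - FRC, VC = TLC - RV), the respiratory rate
comes from mean trough-to-trough periods, minute ventilation is VT x RR,
and compartmental contributions are each compartment's delta over the sum
of deltas (signed, so paradoxical compartments report negative shares).

## Vector fields and significance maps

Displacement fields connect corresponding vertices of two topologically
identical phase meshes (548 vertices at the default level). The modulus is
signed by a point-in-mesh test of the endpoint against the starting
volume: generalized winding number (van Oosterom-Strackee solid angles),
with a ray-casting parity oracle cross-checking it in the tests. Endpoints
within 1e-6 mm of their start count as zero motion and keep a non-negative
sign, so numerical noise cannot flip resting vertices; endpoints that stay
within a few hundredths of a millimetre of the surface are genuinely
ambiguous and may classify either way under coordinate changes — the tests
assert sign stability only above that scale. Joint normalization divides
all moduli by the single largest absolute value across fields, mapping to
[-1, 1] while *preserving zero*; an affine min-max map would move zero and
destroy the inward/outward color semantics, so it was rejected.

Group comparison computes, per triangle, each subject's mean absolute
vertex modulus, then an exact two-sided Mann-Whitney p-value across
subjects (complete enumeration of the rank-sum distribution by a counting
algorithm, mid-ranks for ties, doubled smaller tail capped at 1, for
combined samples up to 20; tie-corrected normal approximation above).
Triangles below alpha = 0.05 are painted red (group 1 greater) or blue on
the vertex-wise averaged model, each mesh centered by the centroid of its
reference-level markers first. No multiplicity correction is applied by
default — the map is exploratory, as is conventional for this analysis —
with Benjamini-Hochberg FDR available as an option. With five subjects a
side, the smallest achievable p is 2/252, and the exact test's discrete
rejection region at the 5% level has probability 8/252 = 0.032; the null
calibration check therefore expects a significant-triangle fraction near
0.03-0.05, which the suite verifies over 100 simulated comparisons.

## The synthetic breathing torso

The phantom is the package's testbed: a stack of elliptic cross-sections
(closed-form areas, hence exact ground truth) whose markers sit at the
layout's angular stations. Defaults emulate an adult male seated
acquisition and are fixed once: height 400 mm, half-axes 140/110 mm
(chest-wall volume 19.35 L), per-compartment amplitudes
RCp 0.0055 / RCa 0.010 / AB 0.007 chosen to give VT about 0.52 L split
about 41/25/34%, breathing at 0.25 Hz (15 breaths/min), 3 min of quiet
breathing then a capacity maneuver with excursion gains 12.4 (TLC) and 4.8
(RV) in tidal-amplitude units — IC about 3.5 L and VC about 4.5 L — sampled
at 60 Hz with 1 mm isotropic Gaussian marker jitter. The quiet waveform is
a unit sinusoid (end-expiration at -1); the maneuver is a continuous
piecewise-linear ramp starting at the first completed breath cycle.
Boundary rows, which belong to two compartments, take the mean of the two
signed amplitudes. Paradox flags negate a compartment's amplitude;
asymmetry scales the left half (step function in angle, so half-ellipse
areas stay closed-form). The phantom deliberately omits soft-tissue
artifact, rib kinematics, cardiac oscillations and drift: passing tests
demonstrate correctness of the pipeline's operators under surface-true
markers, not robustness to those real-data effects.

## Problem sizes and numerical choices

The test suite runs on reduced sessions (4-30 s of quiet breathing at
20-30 Hz) wherever only a few breaths are needed, and on the full
3-minute / 60 Hz conditions for ventilatory-pattern recovery (20 seeds).
The null-map calibration uses 100 comparisons of 5-vs-5 phantoms drawn
identically. Welding tolerance for STL import is 1e-6 mm; binary STL is
float32, so round trips are exact to better than 1e-4 mm at trunk scale.
Occluded markers are linearly interpolated up to 0.5 s; longer gaps abort
the load, since they would silently corrupt volumes. Degenerate inputs
(constant traces, open meshes, mismatched topologies, empty closure
subsets) raise errors rather than warnings throughout.

## Known limitations

Anatomical landmark rows and the marker pairs defining AP/ML diameters are
conventions, not measured anatomy; the longitudinal axis is the
acquisition z axis (no torso-axis refitting, so severe postural tilt or
scoliosis would bias heights and sections); smoothed volumes carry the
systematic shrink discussed above and should be compared against
marker-mesh volumes, not absolute truth; and per-triangle maps without
multiplicity correction overstate isolated significance — use the FDR
option for confirmatory claims.
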