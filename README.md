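# thoraco

Quantitative analysis of thoraco-abdominal surface shape and breathing
motion from opto-electronic plethysmography (OEP) marker trajectories.

OEP tracks ~89 reflective markers on the trunk of a seated subject and is
the reference technique for measuring chest-wall volumes and their split
over the three compartments (pulmonary ribcage RC,p; abdominal ribcage
RC,a; abdomen AB). `thoraco` extends that global analysis to **local**
surface analysis, for respiratory physiologists and clinical researchers
studying paradoxical or asymmetric breathing (Hoover sign, diaphragmatic
paralysis, post-surgical restriction):

- closes the marker cloud with four virtual markers (means of defining
  marker subsets) and builds a watertight, genus-0 trunk mesh from a
  layout-derived triangulation (V = 93, hence F = 182, E = 273 by Euler's
  formula), plus per-compartment meshes;
- smooths meshes by Catmull-Clark (NURMS) subdivision; each iteration maps
  the vertex count to V + E + F, giving the fixed trunk schedule
  93 → 548 → 2186 → 8738 → 34946 → 139778 (one iteration is the default);
- measures trunk geometry at the four static respiratory volumes
  (RV, FRC, FRC+VT, TLC): divergence-theorem volumes, surface area, plane
  sections (area, perimeter), AP/ML diameters, trunk height, shape factors;
- detects the respiratory phases on the chest-wall volume trace
  (prominence-based extrema; FRC/FRCVT as medians of quiet-breathing
  troughs/peaks, TLC/RV as raw global extrema) and derives the ventilatory
  pattern: VT = FRCVT − FRC, IC = TLC − FRC, VC = TLC − RV, RR,
  MV = VT × RR, signed compartmental contributions;
- builds per-vertex displacement vector fields between phase meshes, signed
  negative when the endpoint falls **inside** the starting volume
  (generalized winding number), with joint zero-preserving normalization to
  [−1, 1] for cross-subject figures;
- compares two groups triangle-by-triangle with the **exact**
  Wilcoxon-Mann-Whitney test (complete enumeration, mid-ranks) and paints
  red/blue significance maps on a vertex-averaged model;
- renders 3D heatmaps and arrow plots with the diverging blue-white-red
  convention (outward = red, inward = blue);
- ships a **synthetic breathing-torso phantom** — stacked elliptic
  cross-sections with closed-form volumes, per-compartment amplitudes,
  paradox/asymmetry switches, and marker jitter — so the whole pipeline is
  testable against analytic ground truth.

## Worked example

```r
library(thoraco)

layout  <- default_layout()                      # canonical 89-marker seated layout
cfg     <- phantom_config(layout, quiet_duration = 30, sample_rate = 30,
                          jitter_sd = 1, seed = 42)
phantom <- generate_phantom(cfg)                 # trajectories + analytic truth

res <- run_subject(phantom$traj, quiet_window = cfg$maneuver_start,
                   subject_id = "phantom-42")
print(res)
#> Single-subject OEP analysis: phantom-42
#> Respiratory phases [L]: RV 17.28, FRC 18.25, FRCVT 18.74, TLC 21.74
#>   7 quiet breaths detected
#> Ventilatory pattern: VT 0.49 L, IC 3.49 L, VC 4.46 L, RR 15.2 /min, MV 7.48 L/min
#>   compartment contributions [% CW]:
#>     RCp  RCa   AB
#> VT 46.0  9.9 44.1
#> IC 43.6 19.4 36.9
#> VC 43.4 20.6 36.1
```

The recovered pattern sits a few percent below the phantom's analytic
truth (VT 0.52 L, IC 3.64 L, VC 4.61 L): a 12-marker ring inscribes its
ellipse, which costs ~4.5% of volume — the same order as the error the
field reports for 89-marker models against gold standards.

```r
print(res$geometry$FRC)
#> Chest-wall geometry (FRC, frame 215)
#>   trunk height 40.0 cm; surface 37.4 dm^2
#>   volumes [L]: RCp 8.52, RCa 2.60, AB 5.57; sum 16.68; object 17.48
#>   louis_angle  AP 21.9 cm, ML 27.6 cm, perimeter 75.7 cm, area 4.44 dm^2
#>   xiphoid      AP 21.6 cm, ML 27.8 cm, perimeter 75.8 cm, area 4.44 dm^2
#>   umbilicus    AP 22.0 cm, ML 27.8 cm, perimeter 76.2 cm, area 4.49 dm^2

sub <- subdivide(res$meshes$FRC, 0)              # smoothed phase meshes are in res$meshes
frc_frame <- res$phases$idx[["FRC"]]
print(subdivide(build_trunk_mesh(add_closure_markers(
  matrix(phantom$traj$positions[frc_frame, , ], ncol = 3), layout, "trunk"),
  layout), 2))
#> Subdivision result: level 2
#>  level vertices volume_L
#>      0       93  18.2434
#>      1      548  17.4830
#>      2     2186  17.2586
```

`res$fields` holds the three signed vector fields (FRC→FRCVT, FRC→TLC,
TLC→RV); `render_heatmap()` / `render_arrow_plot()` draw them, and
`compare_groups()` produces the per-triangle Mann-Whitney maps for two
groups of subjects.

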