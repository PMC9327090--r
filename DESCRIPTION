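Package: thoraco
Title: Thoraco-Abdominal Surface Reconstruction and Breathing Kinematics
    from Optoelectronic Marker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of chest-wall shape and
    breathing motion from optoelectronic plethysmography (OEP) marker
    trajectories. Closes the thoraco-abdominal marker cloud with virtual
    markers, builds watertight trunk and compartment triangle meshes from a
    layout-derived triangulation, smooths them by Catmull-Clark (NURMS)
    subdivision, measures trunk geometry (volumes, areas, sections,
    diameters, shape factors), detects the static respiratory volumes on
    the chest-wall volume trace, derives the ventilatory pattern, builds
    signed per-vertex breathing displacement vector fields (inward
    negative), and compares groups triangle-by-triangle with the exact
    Wilcoxon-Mann-Whitney test painted on an averaged model. Includes a
    synthetic breathing-torso phantom with analytic ground-truth volumes
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
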