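Package: lvmech
Title: Laplace-Law Estimates of Left-Ventricular Wall Stress and Power
    Against Semi-Analytic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the accuracy of Laplace-law estimators of
    left-ventricular (LV) wall stress, mechanical power, work and efficiency.
    A semi-analytic solver for the inflation of an incompressible hyperelastic
    thick-walled spherical shell (Demiray and Guccione constitutive laws,
    phenomenological active tension) provides exact volume-averaged Cauchy
    stresses, internal power and work. A lumped active-sphere LV coupled to a
    three-element Windkessel afterload generates synthetic patient-like
    hemodynamic traces and deforming endocardial/epicardial surface meshes.
    Short-axis slicing of triangulated surfaces recovers the mean radius and
    wall width that clinical Laplace analysis would use, and a comparison
    pipeline scores the thin-wall, thick-wall and volume-based Laplace stress
    formulas, Laplace power, internal heart power (IHP), external heart power
    (EHP) and power efficiency against the ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
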