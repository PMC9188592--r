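Package: coaflow
Title: Patient-Specific Hemodynamics of Aortic Coarctation and Bypass Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled desk-scale toolkit for hemodynamic assessment of coarctation
    of the aorta (COA) before and after extra-anatomical bypass grafting. Provides
    a Doppler-calibrated lumped-parameter (0D) model of the left heart and systemic
    circulation with time-varying elastance chambers, energy-loss valve and
    stenosis elements and a bypass-graft branch; patient-specific calibration
    against stroke volume, brachial pressures and Doppler flow splits; clinical
    indices (simplified-Bernoulli gradients, systemic arterial compliance, per-beat
    flow bookkeeping); a lattice-Boltzmann flow kernel (D2Q9/D3Q19, BGK with
    Smagorinsky large-eddy closure, interpolated bounce-back for curved walls,
    velocity inlet with smooth startup) with wall-shear-stress extraction on
    programmatically generated vessel geometries; and velocity-field comparison
    statistics (trilinear down-sampling, penalized least-squares smoothing with
    generalized cross-validation, Bland-Altman and Pearson agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
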