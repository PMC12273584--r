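Package: ligrad
Title: Ligand Concentration Gradients Near the Plasma Membrane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantifies concentration gradients of soluble receptor
    ligands (such as EGF) in the aqueous layer above the plasma membrane.
    Provides fluorescence correlation spectroscopy (FCS) autocorrelation
    modelling, fitting and unit conversion with beam-waist calibration;
    closed-form steady-state solutions of the spherically symmetric diffusion
    and Fokker-Planck equations, the latter with a spatially varying diffusion
    coefficient; a conservative finite-volume reaction-diffusion simulator of
    ligand-receptor binding kinetics with membrane-source scenarios; Hill
    equation machinery for quantifying how membrane-proximal ligand enrichment
    distorts apparent binding affinity and cooperativity; molecular budget
    calculators for exocytosis-driven ligand release; and seeded synthetic-data
    generators for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
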