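Package: ldhtraj
Title: Trajectory Analysis of Carboxylate Anions Confined in Layered Double
    Hydroxide Interlayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    hybrid layered double hydroxides (LDHs) intercalating dicarboxylate
    anions (succinate, aspartate, glutamate). Computes infrared spectra from
    dipole time-correlation functions using maximum-entropy (Burg) spectral
    estimation, extracts the symmetric/antisymmetric carboxylate band gap,
    classifies anion orientational states and anti/gauche conformers,
    and produces number-density profiles along the surface normal and
    interlayer-restricted radial distribution functions. A synthetic
    slab-trajectory generator with presets for the standard hydration states
    of [Mg4Al2(OH)12]A.XH2O systems provides reproducible test systems
    without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
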