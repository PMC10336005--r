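Package: pcmscaffold
Title: Self-Assembly Thermodynamics and MINFLUX Geometry of Pericentriolar
    Scaffold Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying concentration-dependent self-assembly of
    coiled-coil heterotetramer building blocks into higher-order cylindrical
    scaffolds of the pericentriolar material. Implements a square-lattice
    mass-action model of tetramer self-association with classical-nucleation
    free-energy profiles, a sedimentation-equilibrium forward simulator and
    global fitter for reversible self-association models with mass
    conservation and F-statistic confidence scans, and a MINFLUX
    single-molecule localization pipeline (trace filtering, photon-weighted
    collapse, precision estimation, least-squares circle fitting, cylindrical
    shell statistics, in-shell concentration, density rendering, and
    labeling-efficiency calibration). Seed-deterministic synthetic-data
    generators provide localization tables, equilibrium absorbance profiles
    and particle-mass samples with the statistical structure each stage
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
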