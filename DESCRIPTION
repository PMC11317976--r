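Package: ccsa
Title: Cluster-Continuum Solvation Free Energies for Ions in Acetonitrile
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the cluster-continuum static approximation (CCSA) for
    single-ion solvation free energies in acetonitrile: a damped explicit-
    solvent correction over a continuum (CPCM-A) baseline, the quasichemical
    cluster-continuum (CCQC) comparator, thermodynamic cycles that turn pKa
    and gas-phase acidity data into single-ion reference values on a stated
    proton scale, solution-phase reaction free-energy assembly, a
    union-of-spheres molecular surface-area module, and benchmark error
    statistics with a synthetic-data generator for parameter-recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
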