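Package: demonmd
Title: Coarse-Grained Maxwell's-Demon Molecular Dynamics for Parkin-Like Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale coarse-grained molecular modelling toolkit built around
    the conformational activation of the E3 ubiquitin ligase Parkin. Provides a
    bead-level energy model with elastic-network restraints and phospho/mutant
    site parameterization, thermostatted velocity-Verlet dynamics with staged
    equilibration, elastic-network low-mode conformer and guidepost generation,
    a Maxwell's-demon biased sampler that chains unbiased MD sprints between
    guidepost conformations under an RMSD collective variable, zone-equilibrated
    mutation ddG scoring with a FoldX-style interaction decomposition, and the
    trajectory metrics used to characterize domain release: residue-set
    center-of-mass distances, Shrake-Rupley solvent-accessible surface area,
    pocket hydration counts, pair distances, RMSD/RMSF series and pseudo
    phi/psi dihedrals. Includes a synthetic multi-domain system generator and a
    config-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tibble,
    rlang,
    ggplot2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
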