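Package: photofibril
Title: Photocontrolled Reversible Peptide Fibrillization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for photoswitchable amyloid-forming
    peptides carrying an azobenzene (AMPB) pseudo-residue. Provides sequence
    profiling (formal charges, windowed hydropathy), two-state cis/trans
    photoisomer population dynamics under illumination schedules,
    nucleation-elongation fibrillization kinetics with closed-form thioflavin T
    curve models and fitting, idealized cross-beta fibril lattice construction
    with prediction of diffraction repeats and inter-residue distances,
    constraint-based ranking of fibril topologies against WAXS and solid-state
    NMR observables, a coupled photoswitch-aggregation simulator for multi-cycle
    fibrillization/degradation experiments, and synthetic-data generators so the
    whole pipeline is testable without wet-lab inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
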