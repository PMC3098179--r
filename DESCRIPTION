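Package: dockscreen
Title: Multilevel Parallel Virtual Screening with a Grid-Map Lamarckian
    Genetic Algorithm Docking Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained desk-scale virtual-screening stack built around
    a simplified grid-map docking engine. Ligand poses are searched with a
    Lamarckian genetic algorithm (genetic search with Solis-Wets local
    refinement and write-back of improved genomes), scored by trilinear
    interpolation of precomputed per-atom-type affinity, electrostatic and
    desolvation grid maps plus a simple intramolecular term. Screens are
    driven by a master-worker scheduler with per-worker grid-map caches
    (reuse or reload policies), three progress logs (submitted, successful,
    failed), per-docking phase profiling, and optional torsion-sorted
    dispatch. Deterministic per-run seeding makes screen output bit-identical
    across worker and thread counts. Includes readers and writers for the
    text formats involved (PDBQT ligands with torsion trees, key-value
    docking parameter files, ASCII grid maps and grid indexes, docking logs,
    job lists) and a synthetic fixture generator that builds complete toy
    screens (point-atom receptors, analytic maps with a constructed energy
    well, ligands with 0-6 torsions) so everything runs with no external
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
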