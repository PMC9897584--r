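Package: homolot
Title: Remote-Homology Annotation Transfer for Non-Model Membrane Receptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage transfer of membrane-receptor annotations from a model
    organism to a distant non-model organism. Stage one processes remote-homology
    hit tables (HHblits-style HHR results): threshold filtering, top-hit and
    non-redundant target maps, best-bidirectional-hit resolution, and
    multi-organism consensus tallies. Stage two applies structure/function
    plausibility filters: Ballesteros-Weinstein pocket conservation and
    retinal-binding rules for GPCR candidates, PROSITE pattern scanning with
    topology-aware domain placement for Toll-like receptor candidates, and
    protein-protein interaction evidence (tripartite triangle motifs,
    cross-species network overlay, and in-silico binding-site perturbation)
    for G-protein candidates. Includes a deterministic synthetic-data
    generator so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
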