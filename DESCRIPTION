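Package: coalt
Title: Transdiagnostic Co-Alteration Network Analysis of Cortical Effect Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of coordinated ("co-altered") case-control effects on
    cortical thickness across neuropsychiatric disorders. Builds inter-regional
    co-alteration matrices from parcel-wise Cohen's d maps, maps degree-centrality
    hubs and connectome-based disease epicenters, decomposes co-alteration into
    low-dimensional gradients via diffusion map embedding with a normalized-angle
    kernel, assesses significance with spherical rotation (spin) permutation
    tests, and contextualizes gradients with cytoarchitectonic classes,
    meta-analytic term maps, and gene expression. Includes a synthetic-data
    generator with planted latent structure, connectome epicenters, and
    annotation maps so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
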