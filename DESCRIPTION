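Package: strainpick
Title: Automated Strain Prioritization from MALDI-TOF Protein and
    Metabolite Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds microbial strain libraries from MALDI-TOF mass
    spectra. Replicate peak lists per bacterial isolate are merged into
    consensus fingerprints, split into a protein region (2-15 kDa) used
    for pseudo-phylogenetic grouping and a small-molecule region
    (200-2000 Da) used for metabolite association networks, and a greedy
    per-group selection picks a minimal set of isolates capturing a
    user-defined fraction of the distinct natural-product mass features
    in each group. Includes a seeded synthetic-collection generator with
    planted group structure, readers for mzML and delimited peak tables,
    and Newick, GraphML and JSON report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mzR,
    stats,
    tools,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
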