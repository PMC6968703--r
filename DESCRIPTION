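Package: selprof
Title: Ligand-Based Selectivity Profiling of Enzyme Isoform Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Curation and structure-selectivity analysis of multi-target
    inhibition data for enzyme isoform families such as the human carbonic
    anhydrases. Ingests bioactivity tables of Ki measurements, curates them
    (metric, provenance, replicate aggregation with outlier removal, and
    zinc-binding-group substructure filters), computes path-based and
    MACCS-key molecular fingerprints with Tanimoto similarity matrices,
    clusters ligands by single-linkage on Tanimoto distance, and scores each
    cluster's selectivity for an on-target versus an off-target isoform,
    including double-selectivity against two on-targets. Ships a synthetic
    bioactivity generator with planted structure-selectivity relationships
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
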