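Package: radvar
Title: Intragenomic and Intraspecies rDNA Variation from Single-Specimen
    Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("radvar", "maintainers", email = "radvar@example.org",
           role = c("aut", "cre"))
Description: Post-denoising analysis of intragenomic and intraspecies 18S
    rDNA variation in single-specimen long-read amplicon data sets, with a
    focus on polycystine Radiolaria. Provides occurrence-chart input/output
    and PR2-style lineage parsing, taxonomy- and abundance-based ASV
    vetting with an auditable report, IUPAC-aware primer matching and V4
    sub-region extraction/merging, per-specimen richness and rank-abundance
    profiling, shared-ASV classification of morphospecies variation,
    hierarchical p-distance summaries (intragenomic, intraspecies,
    interspecies), chimera-candidate flagging on a supplied phylogeny, a
    ground-truthed synthetic read-table generator, and a pipeline driver
    with a machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
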