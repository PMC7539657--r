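Package: rcdProfiler
Title: Phylogenetic Profiling of Regulated Cell Death Gene Families in Protists
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based presence/absence calling of regulated cell death (RCD)
    gene families (apoptosis, autophagy, regulated necrosis) across protist
    proteomes. Filters tabular protein homology hits by E-value, identity and
    query-coverage thresholds with iterative bait expansion; evaluates boolean
    Pfam domain-architecture formulas per protein; reduces homolog-based calls
    to ortholog-based calls through a largest-ortholog-group rule; assembles
    binary phylogenetic profiles as a SummarizedExperiment; clusters species by
    Ward variance-minimisation linkage with a deterministic cluster-number
    vote; and compares mitochondrial-phenotype and lifestyle groups with
    two-tailed Mann-Whitney U tests. A fully self-consistent synthetic-data
    generator with planted group structure makes every pipeline stage testable
    without downloading proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: Software, Clustering, Phylogenetics, ComparativeGenomics
RoxygenNote: 7.3.3
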