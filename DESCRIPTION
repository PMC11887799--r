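Package: wildIg
Title: Antibody-Bound Microbiota Scoring and B Cell Receptor Clonal Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two linked analyses of humoral immunity against the gut
    microbiota. The first arm scores antibody targeting of individual taxa from
    IgG-seq/IgM-seq experiments: per-taxon log2 enrichment of relative abundance
    in the antibody-bound fraction over the unbound fraction, correlation-based
    sample ordination by principal coordinates analysis, PERMANOVA group tests
    with exact enumeration on small designs, and per-taxon Mann-Whitney U tests
    with exact tie-aware null enumeration. The second arm infers B cell clones
    from annotated single-cell receptor rearrangements (AIRR tab-separated
    schema): a quality-control filter cascade, partitioning by V gene, J gene
    and junction length, nearest-neighbor junction Hamming distances with a
    Gaussian-mixture distance threshold, single-linkage clonal clustering,
    duplicate collapse, somatic-hypermutation profiling, clone diversity with
    bootstrap group deltas, constant-region usage and clonal networks. A
    synthetic-data module generates sorted-fraction 16S count tables and
    clonally expanded repertoires with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'clonal.R'
    'repertoire.R'
    'ordination.R'
    'scoring.R'
    'simulate.R'
    'cli.R'
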