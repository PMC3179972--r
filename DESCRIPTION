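Package: orthomerge
Title: Integrative Ortholog Prediction with Consensus Scoring, GO-Based
    Weighting, Alignment Display and Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates ortholog predictions from multiple source tools into a
    single scored, filterable table. Heterogeneous gene and protein identifiers
    are normalized to one integer gene-ID namespace and isoform-level
    predictions are collapsed to gene level. Each integrated gene pair carries
    a simple score (the number of supporting tools) and a weighted score in
    which tools are weighted by the mean Gene Ontology molecular-function
    semantic similarity of the pairs they predict, median-normalized to one.
    Also provides Smith-Waterman local protein alignment with an EMBOSS-style
    match line and overall plus domain-region percent identity, benchmarking of
    predictors against curated reference pair sets and lineage-specific
    negative gene sets (sensitivity, specificity, coverage), normalization of
    free-text disease and trait terms to MeSH disease categories to link human
    disease genes to model-organism orthologs, and a fully synthetic fixture
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
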