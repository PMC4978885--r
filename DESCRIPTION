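Package: ltrtracer
Title: Tracer k-mer Graph Clustering for Comparative LTR Retrotransposon
    Abundance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the genomic repetitive fraction and the abundance of
    gypsy and copia LTR retrotransposon sublineages across species from
    low-coverage short-read data.  Full-length reference elements are
    decomposed into overlapping 100 bp tracer kmers that are clustered
    jointly with sampled reads in an all-by-all similarity graph (>=90%
    identity over >=55% overlap); clusters inherit the sublineage identity
    of the tracers they contain.  Includes a synthetic-genome and read
    simulator with known family composition for validation, a
    mismatch-counting read-mapping alternative for divergence-bias
    comparisons, and genome-size correlation statistics (Pearson and
    phylogenetically independent contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
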