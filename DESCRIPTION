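Package: popclust
Title: Population-Structure Clustering from VCF Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Streams multi-sample VCF genotypes into a sample-major sparse
    dosage matrix (Hamming distance to the reference genotype), optionally
    drops singleton variants and subsamples variants genome-wide, clusters
    individuals with a from-scratch Lloyd's k-means over sparse rows, scores
    the clustering against annotated population labels with the adjusted
    Rand index, and exports a Gephi-loadable GEXF graph of the clusters.
    Includes a Balding-Nichols cohort simulator that produces structured
    diploid populations with ground-truth labels for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
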