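Package: ssapcluster
Title: Semi-Supervised Affinity Propagation Clustering of Full-Text Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exemplar-based clustering of document corpora represented as sparse
    term-frequency tuples. Pairwise cosine similarities are computed in the
    sub-space spanned by each document pair rather than a global vocabulary,
    affinity propagation message passing selects exemplars, and an optional
    semi-supervised step merges clusters that share labeled seed documents.
    Includes a vector-space k-means baseline, clustering evaluation by global
    F-measure and entropy, construction of directed journal relationship
    networks from class-by-cluster contingency matrices with small-world
    statistics, and a synthetic topic-corpus generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
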