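Package: litsim
Title: Literature-Based Similarity Analysis of Biomedical Entities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and visualizes similarities among sets of biomedical
    entities (genes, diseases, researchers, ...) from the literature. Entities
    are linked to PubMed abstracts by query search or curated PMID lists,
    distilled into a binary entity-by-term matrix of their most frequent words
    or PubTator concept annotations, and compared via hierarchical clustering
    and low-dimensional embeddings. Agreement between text-derived clusters and
    user-supplied grouping variables is measured with the adjusted Rand index.
    A topic-structured synthetic-corpus generator with known ground truth makes
    the full pipeline testable offline, and retrieval clients accept an
    injectable transport so packaged fixtures can replace the live services.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    Rtsne,
    stats,
    utils,
    uwot,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
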