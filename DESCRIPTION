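Package: mirdisnet
Title: Signed miRNA-Based Disease Similarity Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed disease-disease similarity networks from curated
    miRNA-disease association records in the HMDD (Human MicroRNA Disease
    Database) dialect. Each disease is represented as a signed miRNA weight
    vector in which up/down expression records are summed and penalized by
    the miRNA's disease spectrum width (an IDF-style log(N/n) term); pairwise
    disease similarity is the Tanimoto coefficient of these vectors, and
    diseases whose similarity exceeds a threshold in absolute value are
    connected by signed edges. Includes the accompanying statistics suite
    (intra- versus inter-class network distances, link-sign contingency with
    exact Fisher tests, signed-triangle coherence with a record-shuffle
    randomization null, degree-preserving neighbor-class enrichment, and
    focal-disease neighborhood reports), a synthetic HMDD-style data
    generator with planted class structure for end-to-end testing, and a
    one-command reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
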