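Package: kfnet
Title: Host-Microbial Covariance Networks and Bi-Partite Betweenness Key-Factor Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds host-microbial covariance networks from co-measured
    microbial abundance (OTU counts) and host gene-expression matrices.
    Normalizes and collapses OTU tables via reference best-hit maps,
    computes all-pairs Spearman rank correlations, thresholds them into an
    undirected network, corrects coherence-based false-positive and
    false-negative edges using differential-expression regulation labels,
    and ranks candidate key risk factors by bi-partite betweenness
    centrality between the microbe sub-network and functional gene groups.
    Includes a seeded synthetic-data generator with planted monotone
    associations so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
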