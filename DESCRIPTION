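Package: pinmod
Title: Module Detection and Benchmarking in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community (module) detection for undirected biological networks,
    centred on four correlation-distance methods that cluster nodes by the
    similarity of their shortest-path profiles, together with native
    fast-greedy modularity agglomeration and label propagation, adapters for
    walktrap, spinglass and multilevel detection, Newman modularity and
    normalized mutual information for evaluating partitions, a
    planted-community benchmark generator with edge-addition and
    edge-deletion perturbation experiments, and module-wise gene-set
    overrepresentation analysis with Fisher's exact test and Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
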