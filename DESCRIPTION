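Package: gcan
Title: Drug Repositioning for Rare Diseases via Biased Walks over Bridged
    Disease-Gene-Drug Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate drugs for rare diseases by embedding two bridged
    heterogeneous disease-gene-drug networks. Path corpora are sampled with a
    father-son-biased random walk that crosses between a network of parent
    (father) disease nodes and a network of subtype (son) disease nodes, and a
    GRU sequence model with a cooperation mechanism and history attention
    (GCAN) is trained on the paths with a negative-sampling objective. Held-out
    therapeutic links are scored by ranking all drug entities for a disease
    query, reported as Hits@k and mean reciprocal rank. Includes a synthetic
    benchmark generator with planted father-son drug sharing and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
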