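Package: avpconnect
Title: Connectomic Analysis of the Drosophila Anterior Visual Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse synapse-level connectomes of the Drosophila
    anterior visual pathway (medulla -> anterior optic tubercle -> bulb ->
    ellipsoid body). Starting from raw synapse tables and neuron annotations,
    the package filters synaptic contacts, builds region-restricted synaptic
    weight matrices at the individual-neuron and cell-type level, derives
    medulla column/layer coordinate systems and eye maps from hexagonal
    lattice alignment, classifies MeTu projection neurons from connectivity
    feature vectors (embedding, dendrogram and explicit threshold rules),
    computes dendritic-span morphometrics with axial circular statistics,
    and predicts visual receptive fields of ring (ER) neurons by back-tracing
    synaptic pathways onto medulla columns. A synthetic-connectome generator
    with planted ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    mclust,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
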