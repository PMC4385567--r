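Package: mirmodule
Title: Subtype-Specific miRNA-mRNA Functional Regulatory Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers subtype-specific miRNA-mRNA functional regulatory
    modules from matched miRNA and mRNA expression profiles. Comodules
    (joint sets of miRNAs, mRNAs and samples with coherent expression) are
    found by an alternating ping-pong projection-and-threshold iteration
    over the two paired expression matrices; within each comodule a
    constrained three-objective genetic algorithm extracts functional
    regulatory modules that are enriched in disease-associated Gene
    Ontology biological processes, anticorrelated and strongly targeted,
    and variable between disease subtypes. Downstream utilities rank the
    modules by aggregated objective ranks, build bipartite miRNA-mRNA
    regulatory networks, and generate fully synthetic benchmark data sets
    with planted modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
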