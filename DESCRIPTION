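Package: medianet
Title: Indirect Effects and Mediator Proteins in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies walk-based indirect effects among disease proteins in
    undirected protein-protein interaction (PPI) networks. Builds disease-protein
    plus interacting-partner (DPIP) and interacting-partner (IP) subnetworks from a
    PPI edge list and a disease annotation table, computes n-step effect matrices
    from receiver-degree reciprocals, topological importance indices, aggregate
    effects between disease-protein sets, and two-step mediator contributions (M2)
    used to rank the proteins that indirectly connect disease modules. Includes
    deterministic toy fixtures, seeded random disease-network generators and
    brute-force enumeration oracles for validation, plus a small command-line
    driver.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
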