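Package: edgeprior
Title: Evolutionary Distinctiveness and EDGE Conservation Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds species-level dated phylogenies by grafting a taxonomy onto a
    higher-taxon backbone, dates unresolved nodes with a pure-birth (Yule)
    interpolation, computes fair-proportion Evolutionary Distinctiveness (ED)
    with a polytomy correction based on the expected ED over resolutions of
    each polytomy, ranks species under several ED-by-threat weighting schemes
    (EDGE, expected loss, IUCN500), assembles Data Deficient candidate lists,
    and quantifies the robustness of top-100 priority lists under simulated
    uncertainty in topology, Red List status, and Data Deficient reassignment.
    Includes a synthetic-data generator emulating the statistical structure of
    a class-wide amphibian assessment so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
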