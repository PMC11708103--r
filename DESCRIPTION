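Package: pmcindex
Title: Policy Modeling Consistency Index Evaluation for Health Emergency Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates Policy Modeling Consistency (PMC) index
    models for policy documents, with a bundled indicator system for
    traditional-medicine emergency-health governance. Provides a two-level
    indicator schema, binary scoring of policy texts, per-indicator
    normalization, the PMC and depression indices with level classification
    and ranking, PMC surface matrices, radar and release-timeline summaries,
    a generic term-frequency and co-occurrence text-mining front end, and a
    seeded synthetic-data generator for testing every stage without the
    original policy corpus.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
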