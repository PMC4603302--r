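Package: dataflux
Title: Event-Driven Data Integration for Heterogeneous Bioinformatics Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reactive, event-driven extract-transform-load framework for
    life-sciences data. Configurable agents monitor heterogeneous origin
    resources (CSV/TSV files, XML documents and Atom-like feeds, JSON
    documents, and SQL query results), an atomic fingerprint cache turns
    content changes into events, and a template engine delivers transformed
    event payloads to heterogeneous destinations (SQL databases, emails,
    workspace files, and HTTP endpoints). Includes seeds for the dynamic
    instantiation of agents over identifier lists, a FIFO job queue with
    bounded concurrency, a token-authenticated service layer for remote
    agents and pushed events, and synthetic fixture generators, including a
    locus-specific variant feed emulating aggregation from Leiden Open-source
    Variation Database installations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    digest,
    DBI,
    RSQLite,
    openssl,
    curl,
    utils
Suggests:
    testthat (>= 3.0.0),
    httpuv,
    optparse
Config/testthat/edition: 3
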