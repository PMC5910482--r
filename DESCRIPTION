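Package: mwtabr
Title: Parse, Validate and Convert Metabolomics Workbench mwTab Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the mwTab flat-file format of the Metabolomics
    Workbench Data Repository. Tokenizes and parses mwTab text (MS and NMR
    analyses) into an ordered in-memory document model, converts losslessly
    between mwTab and an equivalent JSON representation, validates files
    against per-block schema definitions with cross-block consistency
    checks, streams documents from files, directories, zip/tar archives,
    URLs or bare analysis identifiers, and ships a convert/validate
    command-line interface plus a deterministic synthetic-fixture
    generator with a corruption injector for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    utils,
    tools,
    stats,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
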