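Package: provreplay
Title: Provenance Replay for Zipped Bioinformatics Result Archives
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates the integrity of zipped bioinformatics result archives
    via MD5 checksum manifests, parses the decentralized retrospective
    provenance they carry (per-result YAML action records with execution
    identifiers, parameters including defaults, software environments, and
    timestamps) into a directed acyclic graph, and generates deterministic,
    self-documenting replay scripts (shell and API dialects), collated BibTeX
    bibliographies, and single-command reproducibility supplements. Includes a
    seeded synthetic-analysis generator that writes fully valid archives with
    known ground truth, for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
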