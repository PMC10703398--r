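test_that("VERSION dialect round-trips and rejects garbled input", {
  v <- parseVersionInfo("FORMAT: result-archive\narchive: 2\nframework: 2023.9.0\n")
  expect_identical(v@archiveVersion, 2L)
  expect_identical(v@frameworkVersion, "2023.9.0")
  expect_equal(parseVersionInfo(provreplay:::renderVersionInfo(v)), v)
  expect_error(parseVersionInfo("FORMAT: result-archive\narchive: 0\nframework: 1.0\n"),
               class = "pr_unparseable_version")
  expect_error(parseVersionInfo("archive: 2\n"),
               class = "pr_unparseable_version")
})

test_that("action records parse with order and nulls preserved", {
  text <- paste(
    "execution:",
    paste0("  uuid: ", fixedUuid(9L)),
    "  runtime:",
    "    start: 2023-06-01T12:00:00+00:00",
    "    end: 2023-06-01T12:01:00+00:00",
    "action:",
    "  type: method",
    "  plugin: diversity",
    "  action: core-metrics",
    "  inputs:",
    paste0("  - table: ", fixedUuid(1L)),
    "  parameters:",
    "  - sampling-depth: 1000",
    "  - metric: ~",
    "  - verbose: yes",
    "  output-name: rarefied_table",
    "environment:",
    "  platform: Linux test",
    "  language: Python 3.11",
    "  framework: 2023.9.0",
    "  plugins:",
    "    diversity: 2023.9.2",
    "citations:",
    "- k1",
    sep = "\n")
  parsed <- parseActionYaml(text)
  a <- parsed$action
  expect_identical(actionType(a), "method")
  expect_identical(names(a@parameters),
                   c("sampling-depth", "metric", "verbose"))
  expect_true("metric" %in% names(a@parameters))
  expect_null(a@parameters$metric)
  expect_identical(a@parameters$verbose, TRUE)
  expect_identical(a@inputs$table, fixedUuid(1L))
  expect_identical(parsed$environment@pluginVersions[["diversity"]],
                   "2023.9.2")
  # the writer reproduces the record exactly
  rerendered <- provreplay:::renderActionYaml(a, parsed$environment)
  expect_equal(parseActionYaml(rerendered)$action, a)
})

test_that("import records carry manifests and admit no inputs", {
  node <- mkImportNode(fixedUuid(5L))
  text <- provreplay:::renderActionYaml(actionRecord(node),
                                        environmentRecord(node))
  parsed <- parseActionYaml(text)
  expect_identical(actionType(parsed$action), "import")
  expect_length(parsed$action@inputs, 0L)
  expect_identical(parsed$action@importManifest$name, "reads.fastq.gz")
  # an import that declares inputs violates the schema
  bad <- sub("type: import", "type: import\n  inputs:\n  - x: ~", text)
  expect_error(parseActionYaml(bad), class = "pr_schema_error")
})

test_that("schema violations are rejected", {
  node <- mkActionNode(fixedUuid(6L), inputs = list(table = fixedUuid(5L)))
  text <- provreplay:::renderActionYaml(actionRecord(node), mkEnvironment())
  expect_error(parseActionYaml(sub("type: method", "type: magic", text)),
               class = "pr_schema_error")
  expect_error(parseActionYaml(sub("uuid: .*", "uuid: not-a-uuid", text)),
               class = "pr_schema_error")
  # nested parameter structures violate the flat-scalar restriction
  nested <- sub("- sampling-depth: 1000",
                "- sampling-depth:\n      deep: 1", text)
  expect_error(parseActionYaml(nested), class = "pr_schema_error")
})

test_that("provenance trees yield one node per result", {
  res <- simFixture(61, nImports = 1L, nActions = 4L)
  a <- readArchive(res$paths[1])
  nodes <- parseProvenanceTree(a)
  prefix <- paste0(rootUuid(a), "/provenance/artifacts/")
  nAncestors <- length(unique(sub("/.*$", "",
    sub(prefix, "", memberPaths(a)[startsWith(memberPaths(a), prefix)],
        fixed = TRUE))))
  expect_length(nodes, 1L + nAncestors)
  expect_false(anyDuplicated(vapply(nodes, resultUuid, character(1))) > 0)
  expect_true(all(vapply(nodes, hasProvenance, logical(1))))
})

test_that("missing action records degrade to no-provenance nodes", {
  res <- simFixture(67, nImports = 1L, nActions = 3L)
  path <- res$paths[1]
  a0 <- readArchive(path)
  prefix <- paste0(rootUuid(a0), "/provenance/artifacts/")
  anc <- memberPaths(a0)[startsWith(memberPaths(a0), prefix) &
                           endsWith(memberPaths(a0), "action/action.yaml")][1]
  crippled <- tamperArchive(path, anc, "delete",
                            outPath = withr::local_tempfile(fileext = ".qza"))
  a <- readArchive(crippled)
  expect_warning(nodes <- parseProvenanceTree(a),
                 class = "pr_missing_provenance")
  victim <- sub("/action/action\\.yaml$", "", sub(prefix, "", anc))
  expect_false(hasProvenance(nodes[[victim]]))
  others <- nodes[names(nodes) != victim]
  expect_true(all(vapply(others, hasProvenance, logical(1))))
})

test_that("ancestor subtrees must agree with their directory name", {
  root <- fixedUuid(301L); anc <- fixedUuid(302L); other <- fixedUuid(303L)
  metaYaml <- function(u)
    charToRaw(paste0("uuid: ", u, "\ntype: X\nformat: Y\n"))
  path <- withr::local_tempfile(fileext = ".qza")
  provreplay:::writeZip(path, stats::setNames(
    list(charToRaw("FORMAT: result-archive\narchive: 2\nframework: 1.0\n"),
         metaYaml(root),
         metaYaml(other)),  # subtree 'anc' declares a different uuid
    c(paste0(root, "/VERSION"), paste0(root, "/metadata.yaml"),
      paste0(root, "/provenance/artifacts/", anc, "/metadata.yaml"))))
  expect_error(suppressWarnings(parseProvenanceTree(readArchive(path))),
               class = "pr_inconsistent_provenance")
})

test_that("parsing never mutates the archive", {
  res <- simFixture(73, nImports = 1L, nActions = 3L)
  a <- readArchive(res$paths[1])
  invisible(parseProvenanceTree(a))
  invisible(resolveCitationKeys(a, parseProvenanceTree(a)[[1]]))
  expect_identical(validationStatus(validateChecksums(a)), "valid")
})

test_that("citation keys resolve against the node's own bibliography", {
  res <- simFixture(79, nImports = 1L, nActions = 2L)
  a <- readArchive(res$paths[1])
  nodes <- parseProvenanceTree(a)
  node <- nodes[[rootUuid(a)]]
  entries <- resolveCitationKeys(a, node)
  expect_identical(vapply(entries, citationKey, character(1)),
                   actionRecord(node)@citationKeys)
  # an unmatched key warns and is dropped, matched keys still resolve
  node@action@citationKeys <- c(node@action@citationKeys, "missing|key")
  expect_warning(entries2 <- resolveCitationKeys(a, node),
                 class = "pr_unmatched_citation")
  expect_length(entries2, length(entries))
  # nodes without keys yield an empty list
  node@action@citationKeys <- character(0)
  expect_identical(resolveCitationKeys(a, node), list())
})

test_that("parse-generate identity holds field by field across seeds", {
  for (seed in c(83, 89, 97)) {
    res <- simFixture(seed, nImports = 1L, nActions = 4L)
    pu <- parseUnion(res$paths)
    expectDagMatchesTruth(pu$dag, res$dag)
  }
})
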