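test_that("variable naming sanitizes, deduplicates, and is stable", {
  reg <- newVariableRegistry()
  expect_identical(nameVariable("table", reg, fixedUuid(1L)), "table")
  expect_identical(nameVariable("Taxa Bar-Plot!", reg, fixedUuid(2L)),
                   "taxa_bar_plot")
  # second distinct uuid with the same base name gets a numeric suffix
  expect_identical(nameVariable("table", reg, fixedUuid(3L)), "table_0")
  expect_identical(nameVariable("table", reg, fixedUuid(4L)), "table_1")
  # asking again for a known uuid returns its existing name
  expect_identical(nameVariable("table", reg, fixedUuid(1L)), "table")
  expect_identical(nameVariable("1sample", reg, fixedUuid(5L)), "r_1sample")
})

test_that("plans follow topological order with def-before-use", {
  chain <- buildDag(mkChainNodes())
  plan <- planReplay(chain)
  expect_length(plan, 3L)
  expect_identical(vapply(plan, function(s) s@kind, character(1)),
                   c("import", "action", "action"))
  # a stub input yields a no-provenance comment before its consumer
  orphan <- mkActionNode(fixedUuid(2L), inputs = list(table = fixedUuid(99L)))
  plan2 <- planReplay(buildDag(list(orphan)))
  kinds <- vapply(plan2, function(s) s@kind, character(1))
  expect_identical(kinds, c("no-provenance-comment", "action"))
  placeholderVar <- plan2[[1]]@outputBindings[["result"]]
  expect_identical(unname(plan2[[2]]@inputBindings["table"]), placeholderVar)
})

test_that("every variable used is defined earlier, across random fixtures", {
  for (seed in 141:150) {
    res <- simFixture(seed, nImports = 1L, nActions = 5L)
    dag <- res$dag
    if (seed %% 3L == 0L) {
      # drop an import node so its consumers see a no-provenance stub
      nodes <- provNodes(dag)
      imports <- names(nodes)[vapply(nodes, function(n)
        actionType(actionRecord(n)) == "import", logical(1))]
      dag <- buildDag(nodes[setdiff(names(nodes), imports[1])])
    }
    script <- replayDag(dag, "cli", pinTimestamp = TRUE)$cli
    expectDefBeforeUseCli(renderedText(script))
  }
})

test_that("rendered parameters reproduce the record, defaults and nulls included", {
  res <- simFixture(151, nImports = 1L, nActions = 6L,
                    metadataParamFraction = 1)
  plan <- planReplay(res$dag)
  groups <- groupByExecution(res$dag)
  actionStatements <- Filter(function(s) s@kind %in% c("action", "import"),
                             plan)
  fullGroups <- Filter(function(g) hasProvenance(g$nodes[[1]]), groups)
  expect_length(actionStatements, length(fullGroups))
  for (g in fullGroups) {
    a <- actionRecord(g$nodes[[1]])
    st <- Filter(function(s)
      identical(s@executionUuid, executionUuid(a)), actionStatements)[[1]]
    expect_identical(st@parameterBindings, a@parameters)
  }
  # cli text: one command per action statement, boolean and null forms
  text <- renderedText(replayDag(res$dag, "cli", pinTimestamp = TRUE)$cli)
  nCommands <- length(gregexpr("(^|\n)qiime ", text)[[1]])
  expect_identical(nCommands, length(actionStatements))
})

test_that("boolean, null, and metadata parameters render per dialect rules", {
  node <- mkActionNode(
    fixedUuid(2L), inputs = list(table = fixedUuid(1L)),
    plugin = "feature-table", action = "filter-samples",
    parameters = list(verbose = TRUE, quiet = FALSE, `where` = NULL,
                      metadata = "sample-metadata.tsv"))
  dag <- buildDag(list(mkImportNode(fixedUuid(1L)), node))
  scripts <- replayDag(dag, pinTimestamp = TRUE)
  cli <- renderedText(scripts$cli)
  expect_match(cli, "--p-verbose( \\\\)?\n", perl = TRUE)
  expect_match(cli, "--p-no-quiet")
  expect_false(grepl("--p-verbose true", cli))
  expect_false(grepl("--p-where", cli))       # null: omitted ...
  expect_match(cli, "'where' was recorded as null")  # ... with a comment
  expect_match(cli, "--m-metadata-file table_metadata\\.tsv")
  expect_match(cli, "TODO: supply sample metadata")
  api <- renderedText(scripts$api)
  expect_match(api, "verbose=True")
  expect_match(api, "quiet=False")
  expect_match(api, "where=None")             # null: explicit in the api
  expect_match(api, "metadata=Metadata\\.load\\(\"table_metadata\\.tsv\"\\)")
})

test_that("headers identify sources once and carry numbered instructions", {
  sources <- c(fixedUuid(1L), fixedUuid(2L))
  header <- buildHeader(sources, "1.0.0", "2024-01-01T00:00:00+00:00")
  joined <- paste(header, collapse = "\n")
  for (s in sources)
    expect_identical(length(gregexpr(s, joined, fixed = TRUE)[[1]]), 1L)
  expect_true(sum(grepl("^\\s+[0-9]+\\.", header)) >= 3L)
  expect_error(buildHeader(character(0)), class = "pr_format_error")
  # in the cli dialect the whole header is comment-prefixed
  chain <- buildDag(mkChainNodes())
  cli <- renderCli(planReplay(chain), header)
  lines <- strsplit(renderedText(cli), "\n")[[1]]
  headerRegion <- lines[2:(1 + length(header))]
  expect_true(all(startsWith(headerRegion, "#")))
})

test_that("both dialects share one variable namespace and render deterministically", {
  res <- simFixture(157, nImports = 2L, nActions = 5L)
  s1 <- replayDag(res$dag, pinTimestamp = TRUE)
  s2 <- replayDag(res$dag, pinTimestamp = TRUE)
  expect_identical(renderedText(s1$cli), renderedText(s2$cli))
  expect_identical(renderedText(s1$api), renderedText(s2$api))
  varsOf <- function(script) lapply(replayStatements(script),
                                    function(s) s@outputBindings)
  expect_identical(varsOf(s1$cli), varsOf(s1$api))
})

test_that("rendered scripts satisfy their dialects' grammars", {
  res <- simFixture(163, nImports = 1L, nActions = 6L,
                    metadataParamFraction = 0.5)
  scripts <- replayDag(res$dag, pinTimestamp = TRUE)
  shFile <- withr::local_tempfile(fileext = ".sh")
  pyFile <- withr::local_tempfile(fileext = ".py")
  writeLines(renderedText(scripts$cli), shFile)
  writeLines(renderedText(scripts$api), pyFile)
  expect_identical(system2("bash", c("-n", shFile)), 0L)
  expect_identical(
    system2("python", c("-c", shQuote(sprintf(
      "import ast; ast.parse(open(%s).read())", dQuote(pyFile, '"')))),
      stdout = FALSE, stderr = FALSE), 0L)
})
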