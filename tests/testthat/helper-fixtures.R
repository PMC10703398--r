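# Shared helpers: deterministic UUIDs, hand-built provenance records, and
# compact wrappers around the synthetic-analysis generator.

fixedUuid <- function(i) {
  sprintf("%08x-0000-4000-8000-%012x", i, i)
}

isoInstant <- function(i) {
  sprintf("2023-06-01T12:%02d:%02d+00:00", (i %/% 60) %% 60, i %% 60)
}

emptyManifest <- function() {
  data.frame(name = character(0), md5sum = character(0),
             stringsAsFactors = FALSE)
}

mkMetadata <- function(uuid, type = "FeatureTable[Frequency]",
                       format = "BIOMV210DirFmt") {
  new("ResultMetadata", uuid = uuid, semanticType = type, dataFormat = format)
}

mkEnvironment <- function() {
  new("EnvironmentRecord", platform = "Linux test", language = "R 4.3",
      frameworkVersion = "2023.9.0", pluginVersions = c(test = "1.0"))
}

mkImportNode <- function(uuid, execUuid = fixedUuid(1000L), t = 1L) {
  record <- new("ActionRecord", executionUuid = execUuid,
                actionType = "import", plugin = NULL, actionName = NULL,
                inputs = list(), parameters = list(),
                outputName = "imported",
                startTime = isoInstant(t), endTime = isoInstant(t + 1L),
                citationKeys = character(0),
                importManifest = data.frame(
                  name = "reads.fastq.gz",
                  md5sum = "d41d8cd98f00b204e9800998ecf8427e",
                  stringsAsFactors = FALSE),
                extras = list())
  new("ProvNode", resultUuid = uuid,
      metadata = mkMetadata(uuid, "EMPSingleEndSequences", "EMPDirFmt"),
      action = record, environment = mkEnvironment(), hasProvenance = TRUE)
}

mkActionNode <- function(uuid, inputs, execUuid = NULL, t = 2L,
                         plugin = "diversity", action = "core-metrics",
                         type = "method", outputName = "table",
                         parameters = list(`sampling-depth` = 1000L),
                         citationKeys = character(0)) {
  if (is.null(execUuid)) execUuid <- fixedUuid(2000L + t)
  record <- new("ActionRecord", executionUuid = execUuid,
                actionType = type, plugin = plugin, actionName = action,
                inputs = inputs, parameters = parameters,
                outputName = outputName,
                startTime = isoInstant(t), endTime = isoInstant(t + 1L),
                citationKeys = citationKeys,
                importManifest = emptyManifest(), extras = list())
  new("ProvNode", resultUuid = uuid, metadata = mkMetadata(uuid),
      action = record, environment = mkEnvironment(), hasProvenance = TRUE)
}

# A linear import -> method -> visualizer chain of hand-built nodes.
mkChainNodes <- function() {
  u <- vapply(1:3, fixedUuid, character(1))
  list(
    mkImportNode(u[1], t = 1L),
    mkActionNode(u[2], inputs = list(table = u[1]), t = 10L),
    mkActionNode(u[3], inputs = list(table = u[2]), t = 20L,
                 plugin = "taxa", action = "barplot", type = "visualizer",
                 outputName = "visualization"))
}

# Simulate a small analysis into a fresh temp dir.
simFixture <- function(seed, nImports = 1L, nActions = 4L, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  res <- simulateAnalysis(
    analysisSpec(seed, nImports = nImports, nActions = nActions, ...), dir)
  res$dir <- dir
  res
}

parseUnion <- function(paths) {
  archives <- discoverArchives(paths, verbose = FALSE)
  dag <- unionDags(lapply(archives, function(a)
    suppressWarnings(buildDag(parseProvenanceTree(a)))))
  list(archives = archives, dag = dag)
}

edgeKey <- function(dag) {
  e <- provEdges(dag)
  sort(paste(e$from, e$to))
}

canonicalRecord <- function(node) {
  a <- actionRecord(node)
  list(executionUuid = a@executionUuid, actionType = a@actionType,
       plugin = a@plugin, actionName = a@actionName, inputs = a@inputs,
       parameters = a@parameters, outputName = a@outputName,
       startTime = a@startTime, endTime = a@endTime,
       citationKeys = a@citationKeys, importManifest = a@importManifest)
}

# Same-graph check against generator ground truth: node set, edge set, and
# per-node action-record fields.
expectDagMatchesTruth <- function(dag, truth) {
  expect_setequal(names(provNodes(dag)), names(provNodes(truth)))
  expect_identical(edgeKey(dag), edgeKey(truth))
  for (u in names(provNodes(truth))) {
    a <- provNodes(dag)[[u]]
    b <- provNodes(truth)[[u]]
    expect_identical(hasProvenance(a), hasProvenance(b))
    if (hasProvenance(b))
      expect_identical(canonicalRecord(a), canonicalRecord(b))
  }
}

# Def-before-use scan over rendered shell text: every file consumed via
# --i- must have been produced earlier by --output-path/--o- or announced
# as a TODO placeholder.
expectDefBeforeUseCli <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  defined <- character(0)
  ok <- TRUE
  for (line in lines) {
    m <- regmatches(line,
                    regexec("--i-[a-z0-9-]+ ([A-Za-z0-9_.]+\\.qz[av])", line))[[1]]
    if (length(m) == 2L && !(m[2] %in% defined)) ok <- FALSE
    m <- regmatches(line, regexec(
      "(--o-[a-z0-9-]+|--output-path) ([A-Za-z0-9_.]+\\.qz[av])", line))[[1]]
    if (length(m) == 3L) defined <- c(defined, m[3])
    m <- regmatches(line, regexec(
      "supply it manually as '([A-Za-z0-9_.]+\\.qz[av])'", line))[[1]]
    if (length(m) == 2L) defined <- c(defined, m[2])
  }
  expect_true(ok)
}
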