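# Synthetic-analysis generator: builds random but realistic amplicon-style
# analysis DAGs with known ground truth and writes them as fully valid
# result archives (nested per-result provenance, correct checksum
# manifests).  Each action's first input is the previous execution's first
# output, so the final result's ancestry always covers the whole analysis;
# extra inputs branch to earlier results.  All content is synthetic
# (reserved 10.5555 DOI prefix for citations).

.importTypes <- data.frame(
  type = c("EMPSingleEndSequences", "SampleData[SequencesWithQuality]",
           "FeatureData[Sequence]"),
  format = c("EMPSingleEndDirFmt", "SingleLanePerSampleSingleEndFastqDirFmt",
             "DNASequencesDirectoryFormat"),
  stringsAsFactors = FALSE)

.pluginVersions <- c(demux = "2023.9.0", dada2 = "2023.9.1",
                     `feature-classifier` = "2023.9.0", taxa = "2023.9.0",
                     diversity = "2023.9.2", `feature-table` = "2023.9.0")

.frameworkVersion <- "2023.9.0"

.actionVocab <- list(
  list(plugin = "demux", action = "emp-single", type = "method",
       inputs = c("seqs"),
       outputs = c(per_sample_sequences = "SampleData[SequencesWithQuality]"),
       params = function() list(
         list(`rev-comp-barcodes` = FALSE),
         list(`golay-error-correction` = TRUE)),
       metadataOk = FALSE),
  list(plugin = "dada2", action = "denoise-single", type = "method",
       inputs = c("demultiplexed-seqs"),
       outputs = c(table = "FeatureTable[Frequency]",
                   representative_sequences = "FeatureData[Sequence]",
                   denoising_stats = "SampleData[DADA2Stats]"),
       params = function() list(
         list(`trunc-len` = sample(c(120L, 150L, 250L), 1L)),
         list(`trim-left` = 0L),
         list(`max-ee` = 2.0),
         list(`pooling-method` = "independent"),
         list(`n-threads` = NULL)),
       metadataOk = FALSE),
  list(plugin = "feature-classifier", action = "classify-sklearn",
       type = "method",
       inputs = c("reads", "classifier"),
       outputs = c(classification = "FeatureData[Taxonomy]"),
       params = function() list(
         list(confidence = 0.7),
         list(`read-orientation` = "auto")),
       metadataOk = FALSE),
  list(plugin = "feature-table", action = "filter-samples", type = "method",
       inputs = c("table"),
       outputs = c(filtered_table = "FeatureTable[Frequency]"),
       params = function() list(
         list(`min-frequency` = sample(c(0L, 500L, 1000L), 1L)),
         list(`min-features` = 0L),
         list(`where` = NULL)),
       metadataOk = TRUE),
  list(plugin = "diversity", action = "core-metrics", type = "pipeline",
       inputs = c("table"),
       outputs = c(rarefied_table = "FeatureTable[Frequency]",
                   observed_features_vector = "SampleData[AlphaDiversity]",
                   shannon_vector = "SampleData[AlphaDiversity]"),
       params = function() list(
         list(`sampling-depth` = sample(c(500L, 1000L, 2000L), 1L))),
       metadataOk = TRUE),
  list(plugin = "taxa", action = "barplot", type = "visualizer",
       inputs = c("table", "taxonomy"),
       outputs = c(visualization = "Visualization"),
       params = function() list(),
       metadataOk = TRUE))

dataFormatFor <- function(semanticType) {
  i <- match(semanticType, .importTypes$type)
  if (!is.na(i)) return(.importTypes$format[i])
  switch(semanticType,
         "FeatureTable[Frequency]" = "BIOMV210DirFmt",
         "FeatureData[Sequence]" = "DNASequencesDirectoryFormat",
         "FeatureData[Taxonomy]" = "TSVTaxonomyDirectoryFormat",
         "SampleData[DADA2Stats]" = "DADA2StatsDirFmt",
         "SampleData[AlphaDiversity]" = "AlphaDiversityDirectoryFormat",
         "Visualization" = "Visualization",
         "DirectoryFormat")
}

#' Describe one synthetic analysis
#'
#' Constructor with validation for \linkS4class{AnalysisSpec}; the defaults
#' emulate a small amplicon workflow (one import feeding a handful of
#' downstream actions, occasional multi-output steps, occasional
#' sample-metadata parameters) at current archive-format version 2.
#'
#' @param seed Integer RNG seed; identical specs generate byte-identical
#'   archives.
#' @param nImports Number of import executions (>= 1).
#' @param nActions Number of downstream action executions (>= 0).
#' @param maxInputsPerAction Cap on inputs bound per action (>= 1).
#' @param multiOutputFraction Probability an action uses a multi-output
#'   template.
#' @param metadataParamFraction Probability an eligible action records a
#'   sample-metadata parameter.
#' @param archiveVersion Archive-format version to write; version 1
#'   archives carry no checksum manifest.
#' @return An \linkS4class{AnalysisSpec}.
#' @export
analysisSpec <- function(seed, nImports = 1L, nActions = 5L,
                         maxInputsPerAction = 2L,
                         multiOutputFraction = 0.25,
                         metadataParamFraction = 0.25,
                         archiveVersion = 2L) {
  seed <- as.integer(seed)
  if (is.na(seed)) prStop("seed must be an integer", "pr_spec_error")
  if (nImports < 1L)
    prStop("impossible spec: analyses need at least one import",
           "pr_spec_error")
  if (nActions < 0L || maxInputsPerAction < 1L || archiveVersion < 1L ||
      multiOutputFraction < 0 || multiOutputFraction > 1 ||
      metadataParamFraction < 0 || metadataParamFraction > 1)
    prStop("invalid analysis spec", "pr_spec_error")
  new("AnalysisSpec", seed = seed, nImports = as.integer(nImports),
      nActions = as.integer(nActions),
      maxInputsPerAction = as.integer(maxInputsPerAction),
      multiOutputFraction = multiOutputFraction,
      metadataParamFraction = metadataParamFraction,
      archiveVersion = as.integer(archiveVersion))
}

syntheticEnvironment <- function(plugin = NULL) {
  plugins <- c(framework = .frameworkVersion)
  if (!is.null(plugin)) plugins[plugin] <- .pluginVersions[[plugin]]
  new("EnvironmentRecord",
      platform = "Linux 5.15.0-synthetic x86_64",
      language = "Python 3.11.15",
      frameworkVersion = .frameworkVersion,
      pluginVersions = plugins)
}

frameworkCitation <- function() {
  key <- paste0("framework|synthq2|", .frameworkVersion)
  new("CitationEntry", key = key, entryType = "article",
      fields = c(title = "The synthq2 analysis framework",
                 author = "Framework Authors",
                 journal = "Journal of Synthetic Methods", year = "2023",
                 doi = paste0("10.5555/synthq2.",
                              sub("\\.[0-9]+$", "", .frameworkVersion))))
}

pluginCitation <- function(plugin) {
  key <- paste0("plugin|", plugin, "|", .pluginVersions[[plugin]])
  new("CitationEntry", key = key, entryType = "article",
      fields = c(title = paste0("The ", plugin, " plugin"),
                 author = "Plugin Authors",
                 journal = "Journal of Synthetic Methods", year = "2023",
                 doi = paste0("10.5555/plugin.", plugin)))
}

actionCitation <- function(plugin, action) {
  key <- paste0("action|", plugin, "|", action, "|0")
  new("CitationEntry", key = key, entryType = "misc",
      fields = c(title = paste0("Method notes for ", plugin, " ", action),
                 author = "Plugin Authors", year = "2023"))
}

executionTimes <- function(index) {
  base <- as.POSIXct("2023-06-01 12:00:00", tz = "UTC")
  start <- base + (index - 1L) * 90
  list(start = formatInstant(start),
       end = formatInstant(start + 10 + sample.int(50L, 1L)))
}

# Core generator.  `preset` (internal state of another analysis) seeds the
# shared-ancestry case: generation continues after its executions.
generateAnalysis <- function(spec, preset = NULL) {
  state <- if (is.null(preset)) {
    list(nodes = list(), bibs = list(), execOutputs = list(),
         execIndex = 0L, prevFirst = NULL)
  } else preset
  version <- new("VersionInfo", frameworkVersion = .frameworkVersion,
                 archiveVersion = spec@archiveVersion)

  addExecution <- function(record0, env, outputs, entries) {
    # record0: shared fields; outputs: named chr outputName -> semanticType
    uuids <- uuid4(length(outputs))
    for (i in seq_along(outputs)) {
      record <- record0
      record@outputName <- names(outputs)[i]
      methods::validObject(record)
      node <- new("ProvNode", resultUuid = uuids[i],
                  metadata = new("ResultMetadata", uuid = uuids[i],
                                 semanticType = unname(outputs[i]),
                                 dataFormat = dataFormatFor(outputs[i])),
                  action = record, environment = env, hasProvenance = TRUE)
      state$nodes[[uuids[i]]] <<- node
      state$bibs[[uuids[i]]] <<- entries
    }
    state$execOutputs[[record0@executionUuid]] <<- uuids
    # visualizations are endpoints; never chain or branch from them
    if (outputs[1] != "Visualization") state$prevFirst <<- uuids[1]
    uuids
  }

  nImportsToAdd <- if (is.null(preset)) spec@nImports else 0L
  for (i in seq_len(nImportsToAdd)) {
    state$execIndex <- state$execIndex + 1L
    it <- .importTypes[((state$execIndex - 1L) %% nrow(.importTypes)) + 1L, ]
    nFiles <- sample.int(3L, 1L)
    manifest <- data.frame(
      name = sprintf("import_%d_file_%d.fastq.gz", state$execIndex,
                     seq_len(nFiles)),
      md5sum = vapply(seq_len(nFiles), function(j)
        computeMD5(as.raw(sample.int(256L, 48L, replace = TRUE) - 1L)),
        character(1)),
      stringsAsFactors = FALSE)
    times <- executionTimes(state$execIndex)
    entries <- list(frameworkCitation())
    record <- new("ActionRecord", executionUuid = uuid4(),
                  actionType = "import", plugin = NULL, actionName = NULL,
                  inputs = list(), parameters = list(),
                  outputName = "imported",
                  startTime = times$start, endTime = times$end,
                  citationKeys = vapply(entries, citationKey, character(1)),
                  importManifest = manifest, extras = list())
    addExecution(record, syntheticEnvironment(),
                 stats::setNames(it$type, "imported"), entries)
  }

  multiVocab <- Filter(function(v) length(v$outputs) > 1L, .actionVocab)
  singleVocab <- Filter(function(v) length(v$outputs) == 1L, .actionVocab)
  for (j in seq_len(spec@nActions)) {
    state$execIndex <- state$execIndex + 1L
    vocab <- if (stats::runif(1) < spec@multiOutputFraction)
      multiVocab else singleVocab
    tmpl <- vocab[[sample.int(length(vocab), 1L)]]
    inputNames <- tmpl$inputs[
      seq_len(min(length(tmpl$inputs), spec@maxInputsPerAction))]
    existing <- names(Filter(function(n)
      n@metadata@semanticType != "Visualization", state$nodes))
    inputs <- list()
    inputs[[inputNames[1]]] <- state$prevFirst
    for (nm in inputNames[-1])
      inputs[[nm]] <- existing[sample.int(length(existing), 1L)]
    params <- singleKeyMapsToList(tmpl$params(), "parameters")
    if (tmpl$metadataOk && stats::runif(1) < spec@metadataParamFraction)
      params["metadata"] <- list("sample-metadata.tsv")
    times <- executionTimes(state$execIndex)
    entries <- list(frameworkCitation(), pluginCitation(tmpl$plugin),
                    actionCitation(tmpl$plugin, tmpl$action))
    record <- new("ActionRecord", executionUuid = uuid4(),
                  actionType = tmpl$type, plugin = tmpl$plugin,
                  actionName = tmpl$action, inputs = inputs,
                  parameters = params, outputName = names(tmpl$outputs)[1],
                  startTime = times$start, endTime = times$end,
                  citationKeys = vapply(entries, citationKey, character(1)),
                  importManifest = data.frame(name = character(0),
                                              md5sum = character(0),
                                              stringsAsFactors = FALSE),
                  extras = list())
    addExecution(record, syntheticEnvironment(tmpl$plugin), tmpl$outputs,
                 entries)
  }
  state$version <- version
  state
}

ancestorsOf <- function(nodes, uuid) {
  keep <- character(0)
  frontier <- uuid
  while (length(frontier)) {
    preds <- unique(unlist(lapply(frontier, function(u) {
      n <- nodes[[u]]
      if (!is.null(n) && n@hasProvenance) unlist(n@action@inputs) else NULL
    })))
    frontier <- setdiff(preds, c(keep, uuid))
    keep <- union(keep, frontier)
  }
  keep
}

composeArchiveMembers <- function(state, terminal) {
  nodes <- state$nodes
  root <- terminal
  members <- list()
  nodeMembers <- function(node, base) {
    out <- list()
    out[[paste0(base, "/VERSION")]] <-
      charToRaw(renderVersionInfo(state$version))
    out[[paste0(base, "/metadata.yaml")]] <-
      charToRaw(renderResultMetadata(node@metadata))
    out[[paste0(base, "/citations.bib")]] <-
      charToRaw(renderBibtex(state$bibs[[node@resultUuid]]))
    out[[paste0(base, "/action/action.yaml")]] <-
      charToRaw(renderActionYaml(node@action, node@environment))
    out
  }
  node <- nodes[[terminal]]
  members[[paste0(root, "/VERSION")]] <-
    charToRaw(renderVersionInfo(state$version))
  members[[paste0(root, "/metadata.yaml")]] <-
    charToRaw(renderResultMetadata(node@metadata))
  members[[paste0(root, "/data/payload.txt")]] <-
    charToRaw(paste0("synthetic payload for ", terminal, "\n"))
  members <- c(members, nodeMembers(node, paste0(root, "/provenance")))
  for (anc in sort(ancestorsOf(nodes, terminal)))
    members <- c(members, nodeMembers(
      nodes[[anc]], paste0(root, "/provenance/artifacts/", anc)))
  if (state$version@archiveVersion >= 2L) {
    rel <- sub(paste0("^", root, "/"), "", names(members))
    ord <- order(rel)
    digests <- vapply(members[ord], computeMD5, character(1))
    manifest <- new("ChecksumManifest",
                    entries = data.frame(path = rel[ord], digest = digests,
                                         stringsAsFactors = FALSE))
    members[[paste0(root, "/", manifestBasename)]] <-
      charToRaw(renderChecksumManifest(manifest))
  }
  members
}

writeAnalysisArchives <- function(state, outDir, uuids) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  vapply(uuids, function(u) {
    node <- state$nodes[[u]]
    ext <- if (node@metadata@semanticType == "Visualization") ".qzv"
           else ".qza"
    path <- file.path(outDir, paste0(u, ext))
    writeZip(path, composeArchiveMembers(state, u))
    path
  }, character(1))
}

stateTerminals <- function(state) {
  consumed <- unique(unlist(lapply(state$nodes, function(n)
    if (n@hasProvenance) unlist(n@action@inputs) else NULL)))
  sort(setdiff(names(state$nodes), consumed))
}

#' Simulate an analysis and write its result archives
#'
#' Generates a random analysis DAG under the spec's seed (imports with
#' fingerprinted file manifests, then actions drawn from a small vocabulary
#' of amplicon-workflow plugins, with monotone timestamps, per-execution
#' environments, and namespaced citations with synthetic DOIs), writes one
#' fully valid archive per terminal result (nested provenance plus checksum
#' manifest), and returns the archive paths together with the ground-truth
#' provenance DAG for assertions.
#'
#' @param spec An \linkS4class{AnalysisSpec}.
#' @param outDir Writable output directory (created if needed).
#' @param archiveUuids Result UUIDs to archive; defaults to every terminal.
#'   \code{"final"} archives only the last execution's first output (whose
#'   ancestry spans the whole analysis by construction). The returned
#'   ground truth is restricted to the archived results' combined ancestry.
#' @return A list: \code{paths} (character vector of archive paths),
#'   \code{dag} (ground-truth \linkS4class{ProvDAG}), \code{terminals}
#'   (archived UUIDs), and \code{state} (internal generator state).
#' @export
simulateAnalysis <- function(spec, outDir, archiveUuids = NULL) {
  state <- withSeed(spec@seed, generateAnalysis(spec))
  targets <- if (is.null(archiveUuids)) stateTerminals(state)
             else if (identical(archiveUuids, "final")) state$prevFirst
             else archiveUuids
  if (!all(targets %in% names(state$nodes)))
    prStop("archiveUuids must name generated results", "pr_spec_error")
  paths <- writeAnalysisArchives(state, outDir, targets)
  keep <- unique(c(targets, unlist(lapply(targets, function(u)
    ancestorsOf(state$nodes, u)))))
  truth <- buildDag(state$nodes[keep])
  list(paths = unname(paths), dag = truth, terminals = unname(targets),
       state = state)
}

#' Generate two analyses with known shared ancestry
#'
#' Builds analysis A, then derives analysis B by continuing from a shared
#' prefix of A's executions (identical results, records, and timestamps)
#' with newly generated actions, so the two archive sets overlap by a known
#' number of result nodes — the ground truth for union/dedup tests.
#'
#' @param seed Integer seed (analysis B continues under \code{seed + 1}).
#' @param outDirA,outDirB Output directories for the two archive sets.
#' @param nSharedActions Number of post-import actions in the shared prefix.
#' @param nExtraActions Number of new actions unique to each analysis.
#' @return A list: \code{specA}, \code{specB}, \code{overlapCount},
#'   \code{pathsA}, \code{pathsB}, \code{dagA}, \code{dagB}.
#' @export
makeOverlappingPair <- function(seed, outDirA = tempfile("ovlA-"),
                                outDirB = tempfile("ovlB-"),
                                nSharedActions = 2L, nExtraActions = 3L) {
  specA <- analysisSpec(seed, nImports = 1L,
                        nActions = nSharedActions + nExtraActions)
  stateA <- withSeed(specA@seed, generateAnalysis(specA))
  # shared prefix: the import plus the first nSharedActions executions
  sharedExecs <- seq_len(1L + nSharedActions)
  allExecIds <- names(stateA$execOutputs)
  prefixIds <- allExecIds[sharedExecs]
  prefixUuids <- unlist(stateA$execOutputs[prefixIds], use.names = FALSE)
  preset <- list(nodes = stateA$nodes[prefixUuids],
                 bibs = stateA$bibs[prefixUuids],
                 execOutputs = stateA$execOutputs[prefixIds],
                 execIndex = length(prefixIds),
                 prevFirst = stateA$execOutputs[[prefixIds[length(prefixIds)]]][1])
  specB <- analysisSpec(seed + 1L, nImports = 1L, nActions = nExtraActions)
  stateB <- withSeed(specB@seed, generateAnalysis(specB, preset = preset))
  pathsA <- writeAnalysisArchives(stateA, outDirA, stateTerminals(stateA))
  pathsB <- writeAnalysisArchives(stateB, outDirB, stateTerminals(stateB))
  list(specA = specA, specB = specB,
       overlapCount = length(prefixUuids),
       pathsA = unname(pathsA), pathsB = unname(pathsB),
       dagA = buildDag(stateA$nodes), dagB = buildDag(stateB$nodes))
}

#' Tamper with one archive member
#'
#' Copy-on-write alteration for integrity testing: returns the path of a new
#' archive with exactly the requested change; the original is untouched.
#'
#' @param path An existing archive file.
#' @param memberRelpath Archive-relative member path (must exist except in
#'   append mode, which creates it).
#' @param mode \code{"flip-byte"} (XOR the first byte with 0x01),
#'   \code{"delete"} (remove the member), or \code{"append"} (append bytes
#'   to the member, creating it if absent).
#' @param outPath Where to write the tampered copy.
#' @return The tampered archive's path.
#' @export
tamperArchive <- function(path, memberRelpath,
                          mode = c("flip-byte", "delete", "append"),
                          outPath = file.path(dirname(path),
                                              paste0("tampered-",
                                                     basename(path)))) {
  mode <- match.arg(mode)
  listing <- utils::unzip(path, list = TRUE)
  keep <- !grepl("/$", listing$Name)
  members <- stats::setNames(
    lapply(which(keep), function(i)
      readZipMember(path, listing$Name[i], as.numeric(listing$Length[i]))),
    listing$Name[keep])
  if (!memberRelpath %in% names(members) && mode != "append")
    prStop(sprintf("no member '%s' in '%s'", memberRelpath, path),
           "pr_missing_member")
  if (mode == "flip-byte") {
    bytes <- members[[memberRelpath]]
    if (!length(bytes)) bytes <- as.raw(0L)
    bytes[1] <- xor(bytes[1], as.raw(0x01))
    members[[memberRelpath]] <- bytes
  } else if (mode == "delete") {
    members[[memberRelpath]] <- NULL
  } else {
    members[[memberRelpath]] <- c(members[[memberRelpath]],
                                  charToRaw("tampered\n"))
  }
  writeZip(outPath, members)
  outPath
}

readAnalysisSpecYaml <- function(path) {
  y <- yaml::yaml.load_file(path)
  getOr <- function(nm, default) if (is.null(y[[nm]])) default else y[[nm]]
  analysisSpec(seed = getOr("seed", 1L),
               nImports = getOr("n_imports", 1L),
               nActions = getOr("n_actions", 5L),
               maxInputsPerAction = getOr("max_inputs_per_action", 2L),
               multiOutputFraction = getOr("multi_output_fraction", 0.25),
               metadataParamFraction = getOr("metadata_param_fraction", 0.25),
               archiveVersion = getOr("archive_version", 2L))
}
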