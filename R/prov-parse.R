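# Parsing a result's decentralized provenance tree: the VERSION dialect, the
# per-execution action.yaml records, and per-node citation lookups.
#
# action.yaml schema (one record per executed action, stored once per output
# it produced):
#   execution: {uuid, runtime: {start, end}}
#   action:    {type, plugin, action, inputs: [{name: uuid-or-null}...],
#               parameters: [{name: value}...], output-name,
#               manifest: [{name, md5sum}...]}         # imports only
#   environment: {platform, language, framework, plugins: {name: version}}
#   citations: [key, ...]
# Inputs/parameters are lists of single-key maps so key order survives YAML
# round-trips.  Unknown top-level keys pass through untouched.

#' Parse a VERSION record
#'
#' The VERSION member is a three-line dialect:
#' \preformatted{FORMAT: result-archive
#' archive: <positive integer>
#' framework: <dotted version>}
#'
#' @param text VERSION file content.
#' @return A \linkS4class{VersionInfo}.
#' @export
parseVersionInfo <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != 3L || lines[1] != "FORMAT: result-archive")
    prStop("unparseable VERSION record (expected three-line result-archive dialect)",
           "pr_unparseable_version")
  av <- regmatches(lines[2], regexec("^archive: ([0-9]+)$", lines[2]))[[1]]
  fv <- regmatches(lines[3], regexec("^framework: (\\S+)$", lines[3]))[[1]]
  if (length(av) != 2L || length(fv) != 2L)
    prStop("unparseable VERSION record (garbled archive/framework lines)",
           "pr_unparseable_version")
  avNum <- as.integer(av[2])
  if (is.na(avNum) || avNum < 1L)
    prStop(sprintf("unparseable VERSION record: archive version %s < 1",
                   av[2]), "pr_unparseable_version")
  new("VersionInfo", frameworkVersion = fv[2], archiveVersion = avNum)
}

renderVersionInfo <- function(version) {
  sprintf("FORMAT: result-archive\narchive: %d\nframework: %s\n",
          version@archiveVersion, version@frameworkVersion)
}

# Converts a YAML list of single-key maps into an order-preserving named
# list (NULL values retained).
singleKeyMapsToList <- function(items, what) {
  out <- list()
  for (item in items) {
    if (!is.list(item) || length(item) != 1L || is.null(names(item)))
      prStop(sprintf("%s entries must be single-key maps", what),
             "pr_schema_error")
    out[names(item)] <- item  # keeps NULL elements
  }
  out
}

listToSingleKeyMaps <- function(x) {
  lapply(seq_along(x), function(i) {
    item <- list()
    item[names(x)[i]] <- x[i]
    item
  })
}

isScalarValue <- function(v) {
  is.null(v) ||
    ((is.character(v) || is.numeric(v) || is.logical(v)) && length(v) == 1L)
}

# Parameters are scalars or flat lists of scalars; nested structures are
# rejected to keep code generation faithful.
checkParameterValue <- function(name, v) {
  if (isScalarValue(v)) return(invisible(TRUE))
  if (is.list(v) && is.null(names(v)) &&
      all(vapply(v, function(e) isScalarValue(e) && !is.null(e), logical(1))))
    return(invisible(TRUE))
  if (is.atomic(v) && is.null(names(v)))  # yaml collapses uniform sequences
    return(invisible(TRUE))
  prStop(sprintf("parameter '%s' is not a scalar or flat list of scalars",
                 name), "pr_schema_error")
}

#' Parse one action.yaml provenance record
#'
#' Maps an execution's YAML record to a typed
#' (\linkS4class{ActionRecord}, \linkS4class{EnvironmentRecord}) pair. Input
#' and parameter key order is preserved exactly as written, nulls and
#' default-valued parameters included; unrecognized top-level keys are kept
#' in the record's pass-through bag.
#'
#' @param text action.yaml content.
#' @return A list with elements \code{action} and \code{environment}.
#' @export
parseActionYaml <- function(text) {
  y <- tryCatch(yaml::yaml.load(text),
                error = function(e) prStop(
                  paste0("unparseable action.yaml: ", conditionMessage(e)),
                  "pr_schema_error"))
  if (!is.list(y) || is.null(y$execution) || is.null(y$action))
    prStop("action.yaml must carry execution and action blocks",
           "pr_schema_error")
  ex <- y$execution
  if (is.null(ex$uuid) || !isUuid4(as.character(ex$uuid)))
    prStop("missing or invalid execution uuid", "pr_schema_error")
  if (is.null(ex$runtime$start) || is.null(ex$runtime$end))
    prStop("missing execution runtime start/end", "pr_schema_error")
  act <- y$action
  type <- as.character(act$type)
  if (length(type) != 1L || !type %in% .actionTypes)
    prStop(sprintf("action type '%s' outside {%s}",
                   paste(act$type, collapse = ","),
                   paste(.actionTypes, collapse = ", ")), "pr_schema_error")
  inputs <- singleKeyMapsToList(act$inputs, "inputs")
  parameters <- singleKeyMapsToList(act$parameters, "parameters")
  for (nm in names(parameters)) checkParameterValue(nm, parameters[[nm]])
  if (type == "import" && length(inputs))
    prStop("import records must not declare inputs", "pr_schema_error")
  manifest <- data.frame(name = character(0), md5sum = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(act$manifest)) {
    manifest <- data.frame(
      name = vapply(act$manifest, function(e) as.character(e$name),
                    character(1)),
      md5sum = vapply(act$manifest, function(e) as.character(e$md5sum),
                      character(1)),
      stringsAsFactors = FALSE)
    if (nrow(manifest) && !all(grepl("^[0-9a-f]{32}$", manifest$md5sum)))
      prStop("import manifest digests must be 32-char lowercase hex",
             "pr_schema_error")
  }
  known <- c("execution", "action", "environment", "citations")
  extras <- y[setdiff(names(y), known)]
  record <- new("ActionRecord",
    executionUuid = as.character(ex$uuid),
    actionType = type,
    plugin = if (is.null(act$plugin)) NULL else as.character(act$plugin),
    actionName = if (is.null(act$action)) NULL else as.character(act$action),
    inputs = lapply(inputs, function(v) if (is.null(v)) NULL
                    else as.character(v)),
    parameters = parameters,
    outputName = as.character(act[["output-name"]]),
    startTime = as.character(ex$runtime$start),
    endTime = as.character(ex$runtime$end),
    citationKeys = as.character(unlist(y$citations)),
    importManifest = manifest,
    extras = extras)
  envBlock <- y$environment
  if (is.null(envBlock))
    prStop("action.yaml must carry an environment block", "pr_schema_error")
  plugins <- character(0)
  if (length(envBlock$plugins))
    plugins <- vapply(envBlock$plugins, as.character, character(1))
  environment <- new("EnvironmentRecord",
    platform = as.character(envBlock$platform),
    language = as.character(envBlock$language),
    frameworkVersion = as.character(envBlock$framework),
    pluginVersions = plugins)
  list(action = record, environment = environment)
}

renderActionYaml <- function(record, environment) {
  actBlock <- list(type = record@actionType)
  if (!is.null(record@plugin)) actBlock$plugin <- record@plugin
  if (!is.null(record@actionName)) actBlock$action <- record@actionName
  if (length(record@inputs))
    actBlock$inputs <- listToSingleKeyMaps(record@inputs)
  if (length(record@parameters))
    actBlock$parameters <- listToSingleKeyMaps(record@parameters)
  actBlock[["output-name"]] <- record@outputName
  if (nrow(record@importManifest))
    actBlock$manifest <- lapply(seq_len(nrow(record@importManifest)),
      function(i) list(name = record@importManifest$name[i],
                       md5sum = record@importManifest$md5sum[i]))
  doc <- list(
    execution = list(uuid = record@executionUuid,
                     runtime = list(start = record@startTime,
                                    end = record@endTime)),
    action = actBlock,
    environment = list(platform = environment@platform,
                       language = environment@language,
                       framework = environment@frameworkVersion,
                       plugins = as.list(environment@pluginVersions)),
    citations = as.list(record@citationKeys))
  doc <- c(doc, record@extras)
  yaml::as.yaml(doc)
}

provenancePaths <- function(root, ancestorUuid = NULL) {
  base <- if (is.null(ancestorUuid)) paste0(root, "/provenance")
          else paste0(root, "/provenance/artifacts/", ancestorUuid)
  list(metadata = paste0(base, "/metadata.yaml"),
       action = paste0(base, "/action/action.yaml"),
       citations = paste0(base, "/citations.bib"),
       version = paste0(base, "/VERSION"))
}

parseOneNode <- function(archive, uuid, paths) {
  members <- archive@memberPaths
  metadata <- if (paths$metadata %in% members)
    parseResultMetadata(readMemberText(archive, paths$metadata))
  else
    new("ResultMetadata", uuid = uuid, semanticType = "Unknown",
        dataFormat = "Unknown")
  if (metadata@uuid != uuid)
    prStop(sprintf(
      "inconsistent provenance in '%s': subtree '%s' declares uuid %s",
      archive@rootPath, uuid, metadata@uuid), "pr_inconsistent_provenance")
  if (!paths$action %in% members) {
    prWarn(sprintf(
      "result %s has no action record in '%s'; retained without provenance",
      uuid, archive@rootPath), "pr_missing_provenance")
    return(new("ProvNode", resultUuid = uuid, metadata = metadata,
               action = NULL, environment = NULL, hasProvenance = FALSE))
  }
  parsed <- parseActionYaml(readMemberText(archive, paths$action))
  new("ProvNode", resultUuid = uuid, metadata = metadata,
      action = parsed$action, environment = parsed$environment,
      hasProvenance = TRUE)
}

#' Parse an archive's full provenance tree
#'
#' Returns one \linkS4class{ProvNode} for the archive's root result and one
#' per ancestor subtree under \code{provenance/artifacts/}. A subtree whose
#' declared metadata UUID disagrees with its directory name is an error; a
#' subtree lacking an action record becomes a retained node with
#' \code{hasProvenance = FALSE} (with a warning) so downstream replay can
#' surface it as a user-supplied input.
#'
#' @param archive A \linkS4class{ResultArchive}.
#' @return A list of \linkS4class{ProvNode} with unique result UUIDs.
#' @export
parseProvenanceTree <- function(archive) {
  root <- archive@rootUuid
  nodes <- list(parseOneNode(archive, root, provenancePaths(root)))
  prefix <- paste0(root, "/provenance/artifacts/")
  under <- archive@memberPaths[startsWith(archive@memberPaths, prefix)]
  ancestors <- unique(sub("/.*$", "", sub(prefix, "", under, fixed = TRUE)))
  for (anc in sort(ancestors))
    nodes[[length(nodes) + 1L]] <-
      parseOneNode(archive, anc, provenancePaths(root, anc))
  names(nodes) <- vapply(nodes, resultUuid, character(1))
  nodes
}

#' Resolve a node's citation keys against its own bibliography
#'
#' Looks up every citation key recorded in the node's action record in the
#' node's own \code{citations.bib}. Keys without a matching entry produce
#' warnings, not errors.
#'
#' @param archive The \linkS4class{ResultArchive} the node was parsed from.
#' @param node A \linkS4class{ProvNode}.
#' @return A list of \linkS4class{CitationEntry} (possibly empty).
#' @export
resolveCitationKeys <- function(archive, node) {
  if (!node@hasProvenance || !length(node@action@citationKeys))
    return(list())
  paths <- if (node@resultUuid == archive@rootUuid)
    provenancePaths(archive@rootUuid)
  else provenancePaths(archive@rootUuid, node@resultUuid)
  if (!paths$citations %in% archive@memberPaths) {
    prWarn(sprintf("no citations.bib for result %s in '%s'",
                   node@resultUuid, archive@rootPath),
           "pr_missing_citations")
    return(list())
  }
  entries <- tryCatch(
    parseBibtex(readMemberText(archive, paths$citations)),
    provreplay_error = function(e) prStop(
      sprintf("cannot parse '%s': %s", paths$citations,
              conditionMessage(e)), "pr_bib_parse_error"))
  keys <- vapply(entries, citationKey, character(1))
  out <- list()
  for (k in node@action@citationKeys) {
    idx <- match(k, keys)
    if (is.na(idx)) {
      prWarn(sprintf("citation key '%s' of result %s not found in %s",
                     k, node@resultUuid, paths$citations),
             "pr_unmatched_citation")
    } else {
      out[[length(out) + 1L]] <- entries[[idx]]
    }
  }
  out
}
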