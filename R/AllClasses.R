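# Central S4 containers: archive-level records, provenance records, the
# provenance DAG, replay plans/scripts, and citation entries.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ResultMetadata: identity of one result
#'
#' Identity record stored with every result: its version-4 UUID, a semantic
#' type label, and a data-format label.
#'
#' @slot uuid Version-4 UUID string identifying the result.
#' @slot semanticType Free-text semantic type label (e.g.
#'   \code{"FeatureTable[Frequency]"}).
#' @slot dataFormat Free-text on-disk format label.
#' @export
setClass("ResultMetadata",
  representation(uuid = "character", semanticType = "character",
                 dataFormat = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@uuid) != 1L || !isUuid4(object@uuid))
      msg <- c(msg, "uuid must be a version-4 UUID string")
    if (length(object@semanticType) != 1L || !nzchar(object@semanticType))
      msg <- c(msg, "semanticType must be non-empty")
    if (length(object@dataFormat) != 1L || !nzchar(object@dataFormat))
      msg <- c(msg, "dataFormat must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' VersionInfo: archive-format and framework versions
#'
#' @slot frameworkVersion Dotted version string of the framework that wrote
#'   the result.
#' @slot archiveVersion Integer archive-format version (>= 1); version 1
#'   archives predate checksum manifests.
#' @export
setClass("VersionInfo",
  representation(frameworkVersion = "character", archiveVersion = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@frameworkVersion) != 1L ||
        !nzchar(object@frameworkVersion))
      msg <- c(msg, "frameworkVersion must be non-empty")
    if (length(object@archiveVersion) != 1L ||
        is.na(object@archiveVersion) || object@archiveVersion < 1L)
      msg <- c(msg, "archiveVersion must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' ResultArchive: an on-disk zipped result
#'
#' In-memory handle on one zipped result archive: its path, root UUID, parsed
#' metadata and version records, and the index of member paths. Payload bytes
#' are indexed, never extracted.
#'
#' @slot rootPath Filesystem path of the \code{.zip}/\code{.qza}/\code{.qzv}.
#' @slot rootUuid UUID of the archive's single top-level directory.
#' @slot metadata A \linkS4class{ResultMetadata} for the root result.
#' @slot version A \linkS4class{VersionInfo}.
#' @slot memberPaths Character vector of archive-relative member paths.
#' @slot memberSizes Numeric vector of uncompressed member sizes (parallel to
#'   \code{memberPaths}).
#' @export
setClass("ResultArchive",
  representation(rootPath = "character", rootUuid = "character",
                 metadata = "ResultMetadata", version = "VersionInfo",
                 memberPaths = "character", memberSizes = "numeric"),
  validity = function(object) {
    msg <- character(0)
    tops <- unique(sub("/.*$", "", object@memberPaths))
    if (length(tops) != 1L || tops != object@rootUuid)
      msg <- c(msg, "archive must contain exactly one top-level directory named by rootUuid")
    if (object@metadata@uuid != object@rootUuid)
      msg <- c(msg, "metadata uuid must equal rootUuid")
    need <- paste0(object@rootUuid, c("/metadata.yaml", "/VERSION"))
    if (!all(need %in% object@memberPaths))
      msg <- c(msg, "archive must contain <rootUuid>/metadata.yaml and <rootUuid>/VERSION")
    if (length(object@memberSizes) != length(object@memberPaths))
      msg <- c(msg, "memberSizes must parallel memberPaths")
    if (length(msg)) msg else TRUE
  })

#' EnvironmentRecord: where an action ran
#'
#' @slot platform Operating system name and version string.
#' @slot language Language name and version string.
#' @slot frameworkVersion Framework version the action ran under.
#' @slot pluginVersions Named character vector, plugin name -> version (may
#'   be empty for import records).
#' @export
setClass("EnvironmentRecord",
  representation(platform = "character", language = "character",
                 frameworkVersion = "character",
                 pluginVersions = "character"),
  validity = function(object) {
    if (length(object@frameworkVersion) != 1L ||
        !nzchar(object@frameworkVersion))
      return("frameworkVersion must be non-empty")
    TRUE
  })

.actionTypes <- c("import", "method", "visualizer", "pipeline")

#' ActionRecord: one executed analysis step
#'
#' The retrospective record of a single execution: what ran (plugin/action or
#' an import), with which inputs and parameters (defaults and nulls
#' included), when, and which output this result is.
#'
#' @slot executionUuid Version-4 UUID minted per execution; shared by all of
#'   the execution's outputs.
#' @slot actionType One of \code{"import"}, \code{"method"},
#'   \code{"visualizer"}, \code{"pipeline"}.
#' @slot plugin Plugin name, or \code{NULL} for imports.
#' @slot actionName Action name, or \code{NULL} for imports.
#' @slot inputs Ordered named list, input name -> producing result UUID (or
#'   \code{NULL}); empty for imports.
#' @slot parameters Ordered named list of scalars / flat scalar lists; every
#'   parameter of the action including defaults and nulls.
#' @slot outputName Name of the output this result corresponds to.
#' @slot startTime,endTime ISO-8601 instants with timezone offset.
#' @slot citationKeys Character vector of BibTeX keys recorded for the
#'   action/plugin/framework.
#' @slot importManifest Data frame with columns \code{name}, \code{md5sum}
#'   fingerprinting imported files (imports only; otherwise zero rows).
#' @slot extras Pass-through list of unrecognized top-level record keys.
#' @export
setClass("ActionRecord",
  representation(executionUuid = "character", actionType = "character",
                 plugin = "characterOrNULL", actionName = "characterOrNULL",
                 inputs = "list", parameters = "list",
                 outputName = "character", startTime = "character",
                 endTime = "character", citationKeys = "character",
                 importManifest = "data.frame", extras = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!isUuid4(object@executionUuid))
      msg <- c(msg, "executionUuid must be a version-4 UUID")
    if (!object@actionType %in% .actionTypes)
      msg <- c(msg, sprintf("actionType must be one of: %s",
                            paste(.actionTypes, collapse = ", ")))
    if (object@actionType == "import") {
      if (length(object@inputs))
        msg <- c(msg, "import records must have no inputs")
      if (!is.null(object@plugin) || !is.null(object@actionName))
        msg <- c(msg, "import records must not name a plugin/action")
      if (nrow(object@importManifest) == 0L)
        msg <- c(msg, "import records require a non-empty import manifest")
    } else {
      if (is.null(object@plugin) || is.null(object@actionName))
        msg <- c(msg, "non-import records require plugin and actionName")
    }
    st <- tryCatch(parseInstant(object@startTime), error = function(e) NULL)
    et <- tryCatch(parseInstant(object@endTime), error = function(e) NULL)
    if (is.null(st) || is.null(et))
      msg <- c(msg, "startTime/endTime must be ISO-8601 with offset")
    else if (st > et)
      msg <- c(msg, "startTime must not exceed endTime")
    if (length(msg)) msg else TRUE
  })

setClassUnion("ActionRecordOrNULL", c("ActionRecord", "NULL"))
setClassUnion("EnvironmentRecordOrNULL", c("EnvironmentRecord", "NULL"))

#' ProvNode: one result in the provenance graph
#'
#' @slot resultUuid UUID of the result.
#' @slot metadata A \linkS4class{ResultMetadata}.
#' @slot action The producing \linkS4class{ActionRecord}, or \code{NULL} when
#'   no provenance was captured for this result.
#' @slot environment The \linkS4class{EnvironmentRecord}, or \code{NULL}.
#' @slot hasProvenance \code{TRUE} iff action and environment are present.
#' @export
setClass("ProvNode",
  representation(resultUuid = "character", metadata = "ResultMetadata",
                 action = "ActionRecordOrNULL",
                 environment = "EnvironmentRecordOrNULL",
                 hasProvenance = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (!isUuid4(object@resultUuid))
      msg <- c(msg, "resultUuid must be a version-4 UUID")
    if (object@hasProvenance != !is.null(object@action) ||
        object@hasProvenance != !is.null(object@environment))
      msg <- c(msg, "hasProvenance must match presence of action and environment")
    if (length(msg)) msg else TRUE
  })

#' ProvDAG: the provenance graph of one or more results
#'
#' Results are nodes keyed by UUID; each edge (producer -> consumer) is
#' derived from the consumer's recorded inputs. Acyclicity is enforced at
#' construction; terminals are the nodes no parsed result consumes.
#'
#' @slot nodes Named list of \linkS4class{ProvNode}, names = result UUIDs.
#' @slot edges Data frame with character columns \code{from}, \code{to}.
#' @slot terminalUuids Character vector of out-degree-0 node UUIDs.
#' @export
setClass("ProvDAG",
  representation(nodes = "list", edges = "data.frame",
                 terminalUuids = "character"),
  validity = function(object) {
    msg <- character(0)
    nm <- names(object@nodes)
    if (is.null(nm) || anyDuplicated(nm))
      msg <- c(msg, "nodes must be uniquely named by result UUID")
    if (!all(c("from", "to") %in% names(object@edges)))
      msg <- c(msg, "edges must have columns from, to")
    else if (!all(c(object@edges$from, object@edges$to) %in% nm))
      msg <- c(msg, "every edge endpoint must be a known node")
    expectTerm <- sort(setdiff(nm, object@edges$from))
    if (!identical(sort(object@terminalUuids), expectTerm))
      msg <- c(msg, "terminalUuids must equal the out-degree-0 nodes")
    if (length(msg)) msg else TRUE
  })

.statementKinds <- c("header-comment", "import", "action",
                     "metadata-placeholder", "no-provenance-comment")

#' ReplayStatement: one planned step of a replay
#'
#' @slot kind One of \code{"header-comment"}, \code{"import"},
#'   \code{"action"}, \code{"metadata-placeholder"},
#'   \code{"no-provenance-comment"}.
#' @slot executionUuid Execution UUID, or \code{NULL}.
#' @slot plugin,actionName Plugin/action names, or \code{NULL}.
#' @slot inputBindings Ordered named character vector, input name -> variable.
#' @slot parameterBindings Ordered named list, parameter name -> scalar.
#' @slot outputBindings Ordered named character vector, output name ->
#'   variable.
#' @slot notes Character vector of annotations (manifest filenames, TODOs).
#' @export
setClass("ReplayStatement",
  representation(kind = "character", executionUuid = "characterOrNULL",
                 plugin = "characterOrNULL", actionName = "characterOrNULL",
                 inputBindings = "character", parameterBindings = "list",
                 outputBindings = "character", notes = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% .statementKinds)
      msg <- c(msg, "unknown statement kind")
    if (object@kind == "action" &&
        (is.null(object@plugin) || is.null(object@actionName) ||
         length(object@outputBindings) < 1L))
      msg <- c(msg, "action statements need plugin, actionName, >=1 output binding")
    if (object@kind == "import" && length(object@inputBindings))
      msg <- c(msg, "import statements must have no input bindings")
    if (length(msg)) msg else TRUE
  })

#' ReplayScript: a rendered executable replay document
#'
#' @slot dialect \code{"cli"} (shell) or \code{"api"} (scripting API).
#' @slot header Character vector of header lines (tool id, sources, usage).
#' @slot statements List of \linkS4class{ReplayStatement}.
#' @slot renderedText Full document text, UTF-8, LF line endings.
#' @export
setClass("ReplayScript",
  representation(dialect = "character", header = "character",
                 statements = "list", renderedText = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@dialect %in% c("cli", "api"))
      msg <- c(msg, "dialect must be 'cli' or 'api'")
    if (grepl("\r", object@renderedText, fixed = TRUE))
      msg <- c(msg, "renderedText must use LF line endings")
    if (length(msg)) msg else TRUE
  })

#' ChecksumManifest: the per-archive MD5 manifest
#'
#' @slot entries Data frame with character columns \code{path} (archive paths
#'   relative to the root-UUID directory, \code{/}-separated) and
#'   \code{digest} (32-char lowercase hex), in file order.
#' @export
setClass("ChecksumManifest",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    msg <- character(0)
    if (!all(c("path", "digest") %in% names(e)))
      msg <- c(msg, "entries must have columns path, digest")
    else {
      if (nrow(e) && !all(grepl("^[0-9a-f]{32}$", e$digest)))
        msg <- c(msg, "digests must be 32-char lowercase hex")
      if (anyDuplicated(e$path))
        msg <- c(msg, "paths must be unique")
      if (any(grepl("(^|/)checksums\\.md5$", e$path)))
        msg <- c(msg, "manifest must not list itself")
    }
    if (length(msg)) msg else TRUE
  })

.validationStatuses <- c("valid", "invalid", "predates-checksums",
                         "unparseable")

#' ValidationReport: outcome of checksum validation for one archive
#'
#' @slot archivePath Path of the validated archive.
#' @slot status \code{"valid"}, \code{"invalid"},
#'   \code{"predates-checksums"} (no manifest; archive format predates
#'   checksum capture), or \code{"unparseable"}.
#' @slot mismatches Data frame with columns \code{path}, \code{expected},
#'   \code{observed} (\code{"missing"} when the listed file is absent).
#' @slot extras Character vector of member paths present but unlisted.
#' @export
setClass("ValidationReport",
  representation(archivePath = "character", status = "character",
                 mismatches = "data.frame", extras = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@status %in% .validationStatuses)
      msg <- c(msg, "unknown status")
    if (object@status == "valid" &&
        (nrow(object@mismatches) > 0L || length(object@extras) > 0L))
      msg <- c(msg, "valid reports must have no mismatches or extras")
    if (length(msg)) msg else TRUE
  })

#' CitationEntry: one BibTeX record
#'
#' @slot key BibTeX citation key.
#' @slot entryType Lowercase BibTeX entry type (\code{article},
#'   \code{misc}, ...).
#' @slot fields Ordered named character vector of field values.
#' @export
setClass("CitationEntry",
  representation(key = "character", entryType = "character",
                 fields = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@key) != 1L || !nzchar(object@key))
      msg <- c(msg, "key must be non-empty")
    if (object@entryType != tolower(object@entryType))
      msg <- c(msg, "entryType must be lowercase")
    if (length(msg)) msg else TRUE
  })

#' AnalysisSpec: parameters of one synthetic analysis
#'
#' Describes the simulated study a fixture generator run emulates: how many
#' imports seed the analysis, how many downstream actions run, how branched
#' the graph is, and how often actions emit multiple outputs or take
#' sample-metadata parameters. Identical specs (same seed) yield
#' byte-identical archives.
#'
#' @slot seed Integer RNG seed.
#' @slot nImports Positive number of import executions.
#' @slot nActions Non-negative number of downstream executions.
#' @slot maxInputsPerAction Cap on extra inputs drawn per action.
#' @slot multiOutputFraction Probability an action uses a multi-output
#'   template.
#' @slot metadataParamFraction Probability an eligible action records a
#'   sample-metadata parameter.
#' @slot archiveVersion Archive-format version to write (1 = no checksum
#'   manifest).
#' @export
setClass("AnalysisSpec",
  representation(seed = "integer", nImports = "integer",
                 nActions = "integer", maxInputsPerAction = "integer",
                 multiOutputFraction = "numeric",
                 metadataParamFraction = "numeric",
                 archiveVersion = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nImports < 1L)
      msg <- c(msg, "nImports must be >= 1")
    if (object@nActions < 0L)
      msg <- c(msg, "nActions must be >= 0")
    if (object@maxInputsPerAction < 1L)
      msg <- c(msg, "maxInputsPerAction must be >= 1")
    for (p in c(object@multiOutputFraction, object@metadataParamFraction))
      if (is.na(p) || p < 0 || p > 1)
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@archiveVersion < 1L)
      msg <- c(msg, "archiveVersion must be >= 1")
    if (length(msg)) msg else TRUE
  })
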