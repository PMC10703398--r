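# Accessor generics for the S4 containers (slots are implementation detail;
# user code goes through these).

#' @rdname accessors
#' @export
setGeneric("rootUuid", function(x) standardGeneric("rootUuid"))

#' @rdname accessors
#' @export
setGeneric("resultUuid", function(x) standardGeneric("resultUuid"))

#' @rdname accessors
#' @export
setGeneric("semanticType", function(x) standardGeneric("semanticType"))

#' @rdname accessors
#' @export
setGeneric("memberPaths", function(x) standardGeneric("memberPaths"))

#' @rdname accessors
#' @export
setGeneric("actionRecord", function(x) standardGeneric("actionRecord"))

#' @rdname accessors
#' @export
setGeneric("environmentRecord",
           function(x) standardGeneric("environmentRecord"))

#' @rdname accessors
#' @export
setGeneric("hasProvenance", function(x) standardGeneric("hasProvenance"))

#' @rdname accessors
#' @export
setGeneric("executionUuid", function(x) standardGeneric("executionUuid"))

#' @rdname accessors
#' @export
setGeneric("actionType", function(x) standardGeneric("actionType"))

#' @rdname accessors
#' @export
setGeneric("provNodes", function(x) standardGeneric("provNodes"))

#' @rdname accessors
#' @export
setGeneric("provEdges", function(x) standardGeneric("provEdges"))

#' @rdname accessors
#' @export
setGeneric("terminalUuids", function(x) standardGeneric("terminalUuids"))

#' @rdname accessors
#' @export
setGeneric("renderedText", function(x) standardGeneric("renderedText"))

#' @rdname accessors
#' @export
setGeneric("replayStatements", function(x) standardGeneric("replayStatements"))

#' @rdname accessors
#' @export
setGeneric("validationStatus", function(x) standardGeneric("validationStatus"))

#' @rdname accessors
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))

#' @rdname accessors
#' @export
setGeneric("citationKey", function(x) standardGeneric("citationKey"))

#' @rdname accessors
#' @export
setGeneric("citationFields", function(x) standardGeneric("citationFields"))

#' Accessors for provreplay objects
#'
#' Small read-only accessors exposing the public view of each container:
#' UUIDs, provenance records, graph structure, rendered text, validation
#' status, and citation content.
#'
#' @param x A provreplay S4 object.
#' @return The corresponding component (see each method).
#' @name accessors
#' @aliases rootUuid,ResultArchive-method resultUuid,ProvNode-method
NULL

#' @rdname accessors
setMethod("rootUuid", "ResultArchive", function(x) x@rootUuid)
#' @rdname accessors
setMethod("memberPaths", "ResultArchive", function(x) x@memberPaths)
#' @rdname accessors
setMethod("semanticType", "ResultMetadata", function(x) x@semanticType)
#' @rdname accessors
setMethod("semanticType", "ProvNode", function(x) x@metadata@semanticType)
#' @rdname accessors
setMethod("resultUuid", "ProvNode", function(x) x@resultUuid)
#' @rdname accessors
setMethod("actionRecord", "ProvNode", function(x) x@action)
#' @rdname accessors
setMethod("environmentRecord", "ProvNode", function(x) x@environment)
#' @rdname accessors
setMethod("hasProvenance", "ProvNode", function(x) x@hasProvenance)
#' @rdname accessors
setMethod("executionUuid", "ActionRecord", function(x) x@executionUuid)
#' @rdname accessors
setMethod("actionType", "ActionRecord", function(x) x@actionType)
#' @rdname accessors
setMethod("provNodes", "ProvDAG", function(x) x@nodes)
#' @rdname accessors
setMethod("provEdges", "ProvDAG", function(x) x@edges)
#' @rdname accessors
setMethod("terminalUuids", "ProvDAG", function(x) x@terminalUuids)
#' @rdname accessors
setMethod("renderedText", "ReplayScript", function(x) x@renderedText)
#' @rdname accessors
setMethod("replayStatements", "ReplayScript", function(x) x@statements)
#' @rdname accessors
setMethod("validationStatus", "ValidationReport", function(x) x@status)
#' @rdname accessors
setMethod("manifestEntries", "ChecksumManifest", function(x) x@entries)
#' @rdname accessors
setMethod("citationKey", "CitationEntry", function(x) x@key)
#' @rdname accessors
setMethod("citationFields", "CitationEntry", function(x) x@fields)
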