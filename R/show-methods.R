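setMethod("show", "ResultArchive", function(object) {
  cat("ResultArchive:", basename(object@rootPath), "\n")
  cat("  root uuid:    ", object@rootUuid, "\n")
  cat("  semantic type:", object@metadata@semanticType, "\n")
  cat("  data format:  ", object@metadata@dataFormat, "\n")
  cat(sprintf("  archive v%d (framework %s), %d members\n",
              object@version@archiveVersion,
              object@version@frameworkVersion,
              length(object@memberPaths)))
})

setMethod("show", "ProvNode", function(object) {
  cat("ProvNode", object@resultUuid, "\n")
  cat("  type:", object@metadata@semanticType, "\n")
  if (object@hasProvenance) {
    a <- object@action
    what <- if (a@actionType == "import") "import"
            else paste0(a@plugin, ":", a@actionName)
    cat(sprintf("  produced by %s (%s) as output '%s'\n",
                what, a@actionType, a@outputName))
    cat("  execution:", a@executionUuid, "\n")
  } else {
    cat("  (no provenance captured)\n")
  }
})

setMethod("show", "ProvDAG", function(object) {
  nProv <- sum(vapply(object@nodes, function(n) n@hasProvenance, logical(1)))
  cat(sprintf("ProvDAG: %d result(s) (%d with provenance), %d edge(s), %d terminal(s)\n",
              length(object@nodes), nProv, nrow(object@edges),
              length(object@terminalUuids)))
  for (t in sort(object@terminalUuids))
    cat("  terminal:", t, "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport [%s]: %s\n", object@status,
              object@archivePath))
  if (nrow(object@mismatches)) {
    cat("  mismatches:\n")
    for (i in seq_len(nrow(object@mismatches)))
      cat(sprintf("    %s (expected %s, observed %s)\n",
                  object@mismatches$path[i], object@mismatches$expected[i],
                  object@mismatches$observed[i]))
  }
  if (length(object@extras))
    cat("  unlisted extras:", paste(object@extras, collapse = ", "), "\n")
})

setMethod("show", "ReplayScript", function(object) {
  cat(sprintf("ReplayScript [%s dialect]: %d statement(s), %d line(s)\n",
              object@dialect, length(object@statements),
              length(strsplit(object@renderedText, "\n", fixed = TRUE)[[1]])))
})

setMethod("show", "CitationEntry", function(object) {
  cat(sprintf("@%s{%s} (%d field(s))\n", object@entryType, object@key,
              length(object@fields)))
})

setMethod("show", "AnalysisSpec", function(object) {
  cat(sprintf(
    "AnalysisSpec: seed %d, %d import(s) + %d action(s), archive v%d\n",
    object@seed, object@nImports, object@nActions, object@archiveVersion))
})
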