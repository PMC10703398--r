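# Replay code generation.  planReplay() turns a provenance DAG into an
# ordered list of ReplayStatements (one per execution group, deterministic
# topological order, def-before-use guaranteed); renderCli()/renderApi()
# turn the plan into executable documents sharing one variable namespace.
#
# Statements carry machine-readable notes used by the renderers:
#   "produces: <uuid> as <var>"          self-documentation (comment lines)
#   "semantic-type: <type>"              import output types, binding order
#   "manifest-file: <name> (md5 <d>)"    imported-file fingerprints
#   "input-file: <input>=<file>"         cli filename of each input
#   "output-file: <output>=<file>"       cli filename of each output
#   "null-parameter: <name>"             parameters recorded as null
#   "metadata-parameter: <name>=<file>"  metadata params -> placeholder file
#   "placeholder-file: <file>"           metadata-placeholder statements

pinnedTimestampToken <- "(timestamp pinned for reproducibility)"

toolVersion <- function() {
  tryCatch(as.character(utils::packageVersion("provreplay")),
           error = function(e) "dev")
}

#' Create an empty variable registry
#'
#' A registry assigns each result UUID a unique, sanitized variable name
#' shared by every rendered dialect.
#'
#' @return A variable registry (mutable environment).
#' @export
newVariableRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$byUuid <- character(0)    # uuid -> variable
  reg$byVar <- character(0)     # variable -> uuid
  reg$counters <- integer(0)    # base name -> next suffix
  reg
}

sanitizeName <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  s <- gsub("^_+|_+$", "", s)
  if (!nzchar(s)) s <- "result"
  if (grepl("^[0-9]", s)) s <- paste0("r_", s)
  s
}

#' Assign a variable name for a result
#'
#' Sanitizes the recorded output name (lowercase, runs of non-alphanumerics
#' collapse to \code{_}, edge underscores stripped, digit-led names prefixed
#' \code{r_}) and disambiguates collisions between distinct results with
#' \code{_0}, \code{_1}, ... suffixes. Asking again for a known UUID returns
#' its existing name.
#'
#' @param outputName Recorded output name to derive the variable from.
#' @param registry A registry from \code{\link{newVariableRegistry}}.
#' @param uuid Result UUID the variable stands for.
#' @return The assigned variable name.
#' @export
nameVariable <- function(outputName, registry, uuid) {
  if (uuid %in% names(registry$byUuid))
    return(unname(registry$byUuid[uuid]))
  base <- sanitizeName(outputName)
  candidate <- base
  while (candidate %in% names(registry$byVar)) {
    k <- if (base %in% names(registry$counters)) registry$counters[base]
         else 0L
    candidate <- paste0(base, "_", k)
    registry$counters[base] <- k + 1L
  }
  registry$byUuid[uuid] <- candidate
  registry$byVar[candidate] <- uuid
  candidate
}

isMetadataParam <- function(name) {
  grepl("(^metadata$)|([-_]metadata$)", name)
}

resultFileName <- function(var, node) {
  ext <- if (node@hasProvenance && node@action@actionType == "visualizer")
    "qzv" else "qza"
  paste0(var, ".", ext)
}

#' Plan a replay from a provenance DAG
#'
#' Emits one \linkS4class{ReplayStatement} per execution group in
#' deterministic topological order: imports carry their import-manifest
#' fingerprints, actions with metadata-typed parameters are preceded by a
#' metadata-placeholder statement, and provenance-less results become
#' comment statements instructing the user to supply them. Every input
#' binding refers to a variable defined by an earlier statement.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @return A list of \linkS4class{ReplayStatement}.
#' @export
planReplay <- function(dag) {
  groups <- groupByExecution(dag)
  registry <- newVariableRegistry()
  fileOf <- character(0)  # uuid -> cli file name
  statements <- list()
  for (g in groups) {
    first <- g$nodes[[1]]
    if (!first@hasProvenance) {
      base <- if (first@metadata@semanticType == "Unknown") "unprovided"
              else first@metadata@semanticType
      var <- nameVariable(base, registry, first@resultUuid)
      file <- resultFileName(var, first)
      fileOf[first@resultUuid] <- file
      statements[[length(statements) + 1L]] <- new("ReplayStatement",
        kind = "no-provenance-comment", executionUuid = NULL,
        plugin = NULL, actionName = NULL,
        inputBindings = stats::setNames(character(0), character(0)),
        parameterBindings = list(),
        outputBindings = stats::setNames(var, "result"),
        notes = c(sprintf("produces: %s as %s", first@resultUuid, var),
                  sprintf("output-file: result=%s", file),
                  sprintf("semantic-type: %s", first@metadata@semanticType),
                  sprintf(
                    "TODO: no provenance was recorded for result %s;",
                    first@resultUuid),
                  sprintf(
                    "supply it manually as '%s' before running dependent steps.",
                    file)))
      next
    }
    action <- first@action
    outVars <- character(0)
    notes <- character(0)
    for (node in g$nodes) {
      var <- nameVariable(node@action@outputName, registry, node@resultUuid)
      outVars[node@action@outputName] <- var
      file <- resultFileName(var, node)
      fileOf[node@resultUuid] <- file
      notes <- c(notes, sprintf("produces: %s as %s", node@resultUuid, var))
    }
    for (node in g$nodes) {
      outNm <- node@action@outputName
      notes <- c(notes, sprintf("output-file: %s=%s", outNm,
                                fileOf[node@resultUuid]))
    }
    if (action@actionType == "import") {
      for (node in g$nodes)
        notes <- c(notes, sprintf("semantic-type: %s",
                                  node@metadata@semanticType))
      if (nrow(action@importManifest))
        notes <- c(notes, sprintf("manifest-file: %s (md5 %s)",
                                  action@importManifest$name,
                                  action@importManifest$md5sum))
      statements[[length(statements) + 1L]] <- new("ReplayStatement",
        kind = "import", executionUuid = action@executionUuid,
        plugin = NULL, actionName = NULL,
        inputBindings = stats::setNames(character(0), character(0)),
        parameterBindings = action@parameters,
        outputBindings = outVars, notes = notes)
      next
    }
    inVars <- character(0)
    for (nm in names(action@inputs)) {
      u <- action@inputs[[nm]]
      if (is.null(u)) {
        notes <- c(notes, sprintf("null-input: %s", nm))
        next
      }
      inVars[nm] <- unname(registry$byUuid[u])
      notes <- c(notes, sprintf("input-file: %s=%s", nm, fileOf[u]))
    }
    metaParams <- names(action@parameters)[
      vapply(names(action@parameters), isMetadataParam, logical(1))]
    if (length(metaParams)) {
      placeholder <- paste0(outVars[[1]], "_metadata.tsv")
      statements[[length(statements) + 1L]] <- new("ReplayStatement",
        kind = "metadata-placeholder", executionUuid = action@executionUuid,
        plugin = action@plugin, actionName = action@actionName,
        inputBindings = stats::setNames(character(0), character(0)),
        parameterBindings = list(),
        outputBindings = stats::setNames(character(0), character(0)),
        notes = c(sprintf("placeholder-file: %s", placeholder),
                  sprintf(
                    "TODO: supply sample metadata as '%s' for the next step",
                    placeholder),
                  "(recorded metadata is never replayed verbatim)"))
      for (mp in metaParams)
        notes <- c(notes, sprintf("metadata-parameter: %s=%s", mp,
                                  placeholder))
    }
    for (nm in names(action@parameters))
      if (is.null(action@parameters[[nm]]))
        notes <- c(notes, sprintf("null-parameter: %s", nm))
    statements[[length(statements) + 1L]] <- new("ReplayStatement",
      kind = "action", executionUuid = action@executionUuid,
      plugin = action@plugin, actionName = action@actionName,
      inputBindings = inVars, parameterBindings = action@parameters,
      outputBindings = outVars, notes = notes)
  }
  statements
}

#' Build a replay-script header
#'
#' Self-documenting header lines: tool identification, generation timestamp,
#' the source result UUIDs (each exactly once), numbered usage instructions,
#' and a caveat that parameters are replayed verbatim.
#'
#' @param sources Character vector of source terminal result UUIDs.
#' @param toolVersion Version string to identify the generator.
#' @param timestamp Generation timestamp string (pass
#'   the pinned token for byte-stable output).
#' @return Character vector of header lines (comment prefixes are added by
#'   the renderers).
#' @export
buildHeader <- function(sources,
                        toolVersion = toolVersionString(),
                        timestamp = formatInstant(Sys.time())) {
  if (!length(sources))
    prStop("buildHeader() needs at least one source uuid", "pr_format_error")
  c(sprintf("provreplay %s - provenance replay script", toolVersion),
    sprintf("generated: %s", timestamp),
    sprintf("generated from result(s): %s",
            paste(sort(unique(sources)), collapse = ", ")),
    "",
    "Usage:",
    "  1. Review the steps below and supply every input marked TODO",
    "     (imported source data, sample metadata files).",
    "  2. Install the framework and plugin versions recorded in the source",
    "     provenance before running.",
    "  3. Execute this script from a working directory containing the",
    "     supplied input files.",
    "  4. Compare the outputs with the source results listed above.",
    "",
    "Parameter values are replayed verbatim from recorded provenance,",
    "including defaults and nulls; review them before applying to new data.")
}

#' @rdname buildHeader
#' @export
toolVersionString <- function() toolVersion()

noteValues <- function(statement, prefix) {
  hits <- statement@notes[startsWith(statement@notes, paste0(prefix, ": "))]
  sub(paste0("^", prefix, ": "), "", hits)
}

notePairs <- function(statement, prefix) {
  vals <- noteValues(statement, prefix)
  if (!length(vals)) return(stats::setNames(character(0), character(0)))
  keys <- sub("=.*$", "", vals)
  stats::setNames(sub("^[^=]*=", "", vals), keys)
}

kebab <- function(x) gsub("_", "-", x)
snake <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

shellQuote <- function(x) {
  if (grepl("^[A-Za-z0-9._/=:-]+$", x)) x
  else paste0("'", gsub("'", "'\\\\''", x), "'")
}

cliParamValue <- function(v) {
  if (is.character(v)) shellQuote(v)
  else if (is.double(v) && !is.na(v) && v == round(v)) sprintf("%.1f", v)
  else format(v, scientific = FALSE)
}

pyLiteral <- function(v) {
  if (is.null(v)) return("None")
  if (is.list(v) || (is.atomic(v) && length(v) > 1L))
    return(paste0("[", paste(vapply(v, pyLiteral, character(1)),
                             collapse = ", "), "]"))
  if (is.logical(v)) return(if (v) "True" else "False")
  if (is.character(v))
    return(paste0("\"", gsub("\"", "\\\\\"",
                             gsub("\\\\", "\\\\\\\\", v)), "\""))
  if (is.double(v) && !is.na(v) && v == round(v)) return(sprintf("%.1f", v))
  format(v, scientific = FALSE)
}

assertRenderableParams <- function(statement) {
  for (nm in names(statement@parameterBindings)) {
    v <- statement@parameterBindings[[nm]]
    ok <- is.null(v) || is.character(v) || is.numeric(v) || is.logical(v) ||
      (is.list(v) && all(vapply(v, function(e)
        is.character(e) || is.numeric(e) || is.logical(e), logical(1))))
    if (!ok)
      prStop(sprintf("cannot render parameter '%s' of unsupported type",
                     nm), "pr_codegen_error")
  }
}

newReplayScript <- function(dialect, header, statements, lines) {
  new("ReplayScript", dialect = dialect, header = header,
      statements = statements,
      renderedText = paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Render a replay plan as a shell script
#'
#' One command per action in \code{--i-}/\code{--p-}/\code{--o-} flag form
#' (kebab-case names, \code{.qza}/\code{.qzv} filenames); booleans render as
#' \code{--p-name} / \code{--p-no-name}; null parameters are omitted with an
#' explanatory comment; placeholders and provenance-less results render as
#' TODO comments. Rendering is byte-deterministic for a given plan.
#'
#' @param statements A plan from \code{\link{planReplay}}.
#' @param header Header lines from \code{\link{buildHeader}}.
#' @return A \linkS4class{ReplayScript} with dialect \code{"cli"}.
#' @export
renderCli <- function(statements, header) {
  lines <- c("#!/usr/bin/env bash", paste0("# ", header), "#",
             "set -e", "")
  for (st in statements) {
    assertRenderableParams(st)
    produced <- noteValues(st, "produces")
    outFiles <- notePairs(st, "output-file")
    if (st@kind == "no-provenance-comment") {
      lines <- c(lines,
                 paste0("# TODO: ", noteValues(st, "TODO")),
                 paste0("# ", st@notes[startsWith(st@notes, "supply it")]),
                 sprintf("# (expected result: %s)", produced), "")
      next
    }
    if (st@kind == "metadata-placeholder") {
      lines <- c(lines, paste0("# TODO: ", noteValues(st, "TODO")),
                 "# (recorded metadata is never replayed verbatim)", "")
      next
    }
    lines <- c(lines, paste0("# ", produced))
    if (st@kind == "import") {
      manifest <- noteValues(st, "manifest-file")
      if (length(manifest))
        lines <- c(lines, paste0("# imported file: ", manifest))
      types <- noteValues(st, "semantic-type")
      lines <- c(lines,
        "# TODO: replace the --input-path below with the source data",
        "qiime tools import \\",
        sprintf("  --type %s \\", shellQuote(types[1])),
        "  --input-path TODO-path-to-source-data \\",
        sprintf("  --output-path %s", outFiles[[1]]), "")
      next
    }
    # action
    metaFiles <- notePairs(st, "metadata-parameter")
    inFiles <- notePairs(st, "input-file")
    tokens <- sprintf("qiime %s %s", st@plugin, st@actionName)
    for (nm in names(st@inputBindings))
      tokens <- c(tokens, sprintf("  --i-%s %s", kebab(nm), inFiles[[nm]]))
    nullParams <- character(0)
    for (nm in names(st@parameterBindings)) {
      v <- st@parameterBindings[[nm]]
      if (nm %in% names(metaFiles)) {
        tokens <- c(tokens, sprintf("  --m-metadata-file %s", metaFiles[[nm]]))
      } else if (is.null(v)) {
        nullParams <- c(nullParams, nm)
      } else if (is.logical(v) && length(v) == 1L) {
        tokens <- c(tokens, sprintf("  --p-%s%s", if (v) "" else "no-",
                                    kebab(nm)))
      } else if (is.list(v) || length(v) > 1L) {
        for (e in v)
          tokens <- c(tokens, sprintf("  --p-%s %s", kebab(nm),
                                      cliParamValue(e)))
      } else {
        tokens <- c(tokens, sprintf("  --p-%s %s", kebab(nm),
                                    cliParamValue(v)))
      }
    }
    for (nm in names(st@outputBindings))
      tokens <- c(tokens, sprintf("  --o-%s %s", kebab(nm), outFiles[[nm]]))
    lines <- c(lines, paste0(tokens, c(rep(" \\", length(tokens) - 1L), "")))
    for (nm in nullParams)
      lines <- c(lines, sprintf(
        "# parameter '%s' was recorded as null; the framework default applies",
        nm))
    lines <- c(lines, "")
  }
  newReplayScript("cli", header, statements, lines)
}

#' Render a replay plan as an API script
#'
#' Emits a Python-style API document: header docstring, one call per action
#' binding named outputs to variables, keyword parameters (nulls as
#' \code{None}), TODO placeholders for imports, metadata, and
#' provenance-less results. Variable names are identical to the shell
#' dialect (shared registry).
#'
#' @inheritParams renderCli
#' @return A \linkS4class{ReplayScript} with dialect \code{"api"}.
#' @export
renderApi <- function(statements, header) {
  lines <- c("#!/usr/bin/env python3", "\"\"\"", header, "\"\"\"", "",
             "from qiime2 import Artifact, Metadata")
  plugins <- sort(unique(unlist(lapply(statements, function(st)
    if (st@kind == "action") st@plugin else NULL))))
  if (length(plugins))
    lines <- c(lines, sprintf("from qiime2.plugins import %s",
                              paste(snake(plugins), collapse = ", ")))
  lines <- c(lines, "")
  resultCounter <- 0L
  for (st in statements) {
    assertRenderableParams(st)
    produced <- noteValues(st, "produces")
    lines <- c(lines, paste0("# ", produced))
    if (st@kind == "no-provenance-comment") {
      var <- st@outputBindings[["result"]]
      lines <- c(lines,
        paste0("# TODO: ", noteValues(st, "TODO")),
        sprintf("%s = Artifact.load(\"%s\")  # TODO: supply this file",
                var, notePairs(st, "output-file")[["result"]]), "")
      next
    }
    if (st@kind == "metadata-placeholder") {
      lines <- c(lines[-length(lines)],  # no produces line for placeholders
        paste0("# TODO: ", noteValues(st, "TODO")))
      next
    }
    if (st@kind == "import") {
      manifest <- noteValues(st, "manifest-file")
      if (length(manifest))
        lines <- c(lines, paste0("# imported file: ", manifest))
      types <- noteValues(st, "semantic-type")
      var <- st@outputBindings[[1]]
      lines <- c(lines, sprintf(
        "%s = Artifact.import_data(%s, \"TODO-path-to-source-data\")",
        var, pyLiteral(types[1])), "")
      next
    }
    metaFiles <- notePairs(st, "metadata-parameter")
    args <- character(0)
    for (nm in names(st@inputBindings))
      args <- c(args, sprintf("%s=%s", snake(nm), st@inputBindings[[nm]]))
    for (nm in names(st@parameterBindings)) {
      v <- st@parameterBindings[[nm]]
      if (nm %in% names(metaFiles))
        args <- c(args, sprintf("%s=Metadata.load(\"%s\")", snake(nm),
                                metaFiles[[nm]]))
      else
        args <- c(args, sprintf("%s=%s", snake(nm), pyLiteral(v)))
    }
    resultCounter <- resultCounter + 1L
    resVar <- sprintf("results_%d", resultCounter)
    lines <- c(lines, sprintf("%s = %s.actions.%s(", resVar,
                              snake(st@plugin), snake(st@actionName)),
               sprintf("    %s,", args), ")")
    for (nm in names(st@outputBindings))
      lines <- c(lines, sprintf("%s = %s.%s", st@outputBindings[[nm]],
                                resVar, snake(nm)))
    lines <- c(lines, "")
  }
  newReplayScript("api", header, statements, lines)
}

#' Replay a provenance DAG into one or both dialects
#'
#' Convenience wrapper: plans once, builds the header from the DAG's
#' terminal results, and renders each requested dialect from the shared
#' plan.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @param dialects Subset of \code{c("cli", "api")}.
#' @param pinTimestamp Replace the generation timestamp with a fixed token
#'   so repeated runs are byte-identical.
#' @return Named list of \linkS4class{ReplayScript}, one per dialect.
#' @export
replayDag <- function(dag, dialects = c("cli", "api"), pinTimestamp = FALSE) {
  dialects <- match.arg(dialects, c("cli", "api"), several.ok = TRUE)
  ts <- if (pinTimestamp) pinnedTimestampToken else formatInstant(Sys.time())
  header <- buildHeader(sort(dag@terminalUuids), toolVersion(), ts)
  plan <- planReplay(dag)
  out <- list()
  if ("cli" %in% dialects) out$cli <- renderCli(plan, header)
  if ("api" %in% dialects) out$api <- renderApi(plan, header)
  out
}
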