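# BibTeX collation: per-node bibliographies are parsed, collected over the
# DAG in topological order of first appearance, deduplicated (DOI first,
# then exact key), and rendered deterministically.

#' Parse BibTeX text
#'
#' Parses \code{@type\{key, field = \{value\}, ...\}} entries with braced or
#' quoted values; field order is preserved. Malformed entries are skipped
#' with a warning; non-empty text (ignoring \code{\%} comment lines) that
#' yields zero entries is an error.
#'
#' @param text BibTeX document text.
#' @return A list of \linkS4class{CitationEntry}.
#' @export
parseBibtex <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*%", lines)]
  body <- paste(lines, collapse = "\n")
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  entries <- list()
  skipWs <- function(i) {
    while (i <= n && grepl("^\\s$", chars[i])) i <- i + 1L
    i
  }
  while (i <= n) {
    if (chars[i] != "@") { i <- i + 1L; next }
    start <- i
    i <- i + 1L
    typeStart <- i
    while (i <= n && grepl("^[A-Za-z]$", chars[i])) i <- i + 1L
    entryType <- tolower(paste(chars[typeStart:(i - 1L)], collapse = ""))
    i <- skipWs(i)
    ok <- i <= n && chars[i] == "{" && nzchar(entryType)
    if (!ok) {
      prWarn(sprintf("skipping malformed bibtex entry near offset %d",
                     start), "pr_bib_skip")
      next
    }
    i <- i + 1L
    keyStart <- i
    while (i <= n && !chars[i] %in% c(",", "}", "\n")) i <- i + 1L
    key <- trimws(paste(chars[keyStart:(i - 1L)], collapse = ""))
    if (i > n || chars[i] != "," || !nzchar(key)) {
      prWarn(sprintf("skipping malformed bibtex entry near offset %d",
                     start), "pr_bib_skip")
      next
    }
    i <- i + 1L
    fields <- character(0)
    bad <- FALSE
    repeat {
      i <- skipWs(i)
      if (i > n) { bad <- TRUE; break }
      if (chars[i] == "}") { i <- i + 1L; break }
      nameStart <- i
      while (i <= n && grepl("^[A-Za-z0-9_-]$", chars[i])) i <- i + 1L
      fieldName <- tolower(paste(chars[nameStart:(i - 1L)], collapse = ""))
      i <- skipWs(i)
      if (!nzchar(fieldName) || i > n || chars[i] != "=") { bad <- TRUE; break }
      i <- skipWs(i + 1L)
      if (i > n) { bad <- TRUE; break }
      if (chars[i] == "{") {
        depth <- 1L
        i <- i + 1L
        valStart <- i
        while (i <= n && depth > 0L) {
          if (chars[i] == "{") depth <- depth + 1L
          if (chars[i] == "}") depth <- depth - 1L
          i <- i + 1L
        }
        if (depth > 0L) { bad <- TRUE; break }
        value <- paste(chars[valStart:(i - 2L)], collapse = "")
      } else if (chars[i] == "\"") {
        i <- i + 1L
        valStart <- i
        while (i <= n && chars[i] != "\"") i <- i + 1L
        if (i > n) { bad <- TRUE; break }
        value <- paste(chars[valStart:(i - 1L)], collapse = "")
        i <- i + 1L
      } else {
        valStart <- i
        while (i <= n && !chars[i] %in% c(",", "}", "\n")) i <- i + 1L
        value <- trimws(paste(chars[valStart:(i - 1L)], collapse = ""))
      }
      fields[fieldName] <- value
      i <- skipWs(i)
      if (i <= n && chars[i] == ",") i <- i + 1L
    }
    if (bad) {
      prWarn(sprintf("skipping malformed bibtex entry '%s'", key),
             "pr_bib_skip")
      next
    }
    entries[[length(entries) + 1L]] <-
      new("CitationEntry", key = key, entryType = entryType, fields = fields)
  }
  if (!length(entries) && nzchar(trimws(body)))
    prStop("no parseable bibtex entries in non-empty text",
           "pr_bib_parse_error")
  entries
}

#' Collect citations across a provenance DAG
#'
#' Resolves the citation keys of every full-provenance node against that
#' node's own bibliography, visiting nodes in topological order of first
#' appearance. Entries are returned as collected — duplicates across nodes
#' are retained so \code{\link{dedupCitations}} can collate them.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @param archives The list of \linkS4class{ResultArchive} the DAG was
#'   parsed from.
#' @return A list of \linkS4class{CitationEntry}.
#' @export
collectCitations <- function(dag, archives) {
  out <- list()
  for (u in topologicalOrder(dag)) {
    node <- dag@nodes[[u]]
    if (!node@hasProvenance) next
    for (archive in archives) {
      paths <- if (u == archive@rootUuid) provenancePaths(archive@rootUuid)
               else provenancePaths(archive@rootUuid, u)
      if (paths$action %in% archive@memberPaths ||
          u == archive@rootUuid && paths$citations %in% archive@memberPaths) {
        out <- c(out, resolveCitationKeys(archive, node))
        break
      }
    }
  }
  out
}

normalizeDoi <- function(doi) {
  d <- tolower(trimws(doi))
  d <- sub("^https?://(dx\\.)?doi\\.org/", "", d)
  sub("^doi:\\s*", "", d)
}

#' Deduplicate citation entries
#'
#' Entries sharing a normalized DOI (case-folded, URL/\code{doi:} prefix
#' stripped) merge into the first occurrence; DOI-less entries deduplicate
#' on exact key. Surviving keys that still collide are disambiguated with
#' \code{_a}, \code{_b}, ... suffixes. Idempotent; never drops a DOI.
#'
#' @param entries A list of \linkS4class{CitationEntry}.
#' @return A list of \linkS4class{CitationEntry} with unique keys.
#' @export
dedupCitations <- function(entries) {
  kept <- list()
  seenDois <- character(0)
  seenKeys <- character(0)
  for (e in entries) {
    doi <- if ("doi" %in% names(e@fields)) normalizeDoi(e@fields[["doi"]])
           else NA_character_
    if (!is.na(doi)) {
      if (doi %in% seenDois) next
      seenDois <- c(seenDois, doi)
    } else {
      if (e@key %in% seenKeys) next
    }
    seenKeys <- c(seenKeys, e@key)
    kept[[length(kept) + 1L]] <- e
  }
  keys <- vapply(kept, citationKey, character(1))
  if (anyDuplicated(keys)) {
    for (dup in unique(keys[duplicated(keys)])) {
      idx <- which(keys == dup)
      for (j in seq_along(idx)) {
        suffix <- paste0("_", letters[j])
        keys[idx[j]] <- paste0(dup, suffix)
        kept[[idx[j]]]@key <- keys[idx[j]]
      }
    }
  }
  kept
}

#' Render citation entries as BibTeX
#'
#' Deterministic rendering: entries in given order, fields in stored order,
#' brace-delimited values, LF line endings. An empty entry list renders a
#' comment-only document.
#'
#' @param entries A list of \linkS4class{CitationEntry} with unique keys.
#' @return A single BibTeX document string.
#' @export
renderBibtex <- function(entries) {
  keys <- vapply(entries, citationKey, character(1))
  if (anyDuplicated(keys))
    prStop(sprintf("duplicate citation keys: %s",
                   paste(unique(keys[duplicated(keys)]), collapse = ", ")),
           "pr_bib_render_error")
  if (!length(entries))
    return("% no citation entries\n")
  blocks <- vapply(entries, function(e) {
    fieldLines <- sprintf("  %s = {%s}", names(e@fields), e@fields)
    paste0("@", e@entryType, "{", e@key, ",\n",
           paste(fieldLines, collapse = ",\n"), "\n}")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}
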