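# Checksum-manifest integrity validation.  Every archive written at format
# version >= 2 carries <root>/checksums.md5: md5sum-compatible lines
# ("<digest><two spaces><path>", paths relative to the root-UUID directory,
# sorted, LF-terminated, never listing the manifest itself).  Validation
# recomputes each member digest and reports — it never raises on mismatch.

manifestBasename <- "checksums.md5"

#' Parse a checksum manifest
#'
#' Parses md5sum-compatible manifest text: one entry per non-empty line,
#' \code{<32-hex-digest>}, two spaces, then the member path relative to the
#' archive's root-UUID directory. Entry order is preserved.
#'
#' @param text Manifest file content (UTF-8 text).
#' @return A \linkS4class{ChecksumManifest}.
#' @export
parseChecksumManifest <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  entries <- data.frame(path = character(0), digest = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([0-9a-f]{32})  (.+)$", line))[[1]]
    if (length(m) != 3L)
      prStop(sprintf("unparseable manifest line %d: '%s'", i, line),
             "pr_unparseable_manifest")
    if (m[3] %in% entries$path)
      prStop(sprintf("duplicate manifest entry for '%s' (line %d)",
                     m[3], i), "pr_duplicate_entry")
    entries <- rbind(entries,
                     data.frame(path = m[3], digest = m[2],
                                stringsAsFactors = FALSE))
  }
  new("ChecksumManifest", entries = entries)
}

renderChecksumManifest <- function(manifest) {
  e <- manifest@entries
  if (!nrow(e)) return("")
  paste0(paste0(e$digest, "  ", e$path, collapse = "\n"), "\n")
}

#' Validate an archive against its checksum manifest
#'
#' Recomputes the MD5 digest of every archive member except the manifest
#' itself and compares against \code{checksums.md5}. Alteration is reported,
#' never raised: the result lists per-path mismatches (including listed but
#' missing files) and unlisted extra members. Archives written before
#' manifests existed (format version 1) yield status
#' \code{"predates-checksums"}.
#'
#' @param archive A \linkS4class{ResultArchive}.
#' @return A \linkS4class{ValidationReport}.
#' @export
validateChecksums <- function(archive) {
  root <- archive@rootUuid
  manifestPath <- paste0(root, "/", manifestBasename)
  noMismatch <- data.frame(path = character(0), expected = character(0),
                           observed = character(0), stringsAsFactors = FALSE)
  if (!manifestPath %in% archive@memberPaths)
    return(new("ValidationReport", archivePath = archive@rootPath,
               status = "predates-checksums", mismatches = noMismatch,
               extras = character(0)))
  manifest <- tryCatch(
    parseChecksumManifest(readMemberText(archive, manifestPath)),
    provreplay_error = function(e) NULL)
  if (is.null(manifest))
    return(new("ValidationReport", archivePath = archive@rootPath,
               status = "unparseable", mismatches = noMismatch,
               extras = character(0)))
  entries <- manifest@entries
  mismatches <- noMismatch
  present <- setdiff(archive@memberPaths, manifestPath)
  presentRel <- sub(paste0("^", root, "/"), "", present)
  for (i in seq_len(nrow(entries))) {
    rel <- entries$path[i]
    expected <- entries$digest[i]
    full <- paste0(root, "/", rel)
    if (!full %in% present) {
      mismatches <- rbind(mismatches, data.frame(
        path = rel, expected = expected, observed = "missing",
        stringsAsFactors = FALSE))
      next
    }
    observed <- computeMD5(readMember(archive, full))
    if (!identical(observed, expected))
      mismatches <- rbind(mismatches, data.frame(
        path = rel, expected = expected, observed = observed,
        stringsAsFactors = FALSE))
  }
  extras <- sort(setdiff(presentRel, entries$path))
  status <- if (nrow(mismatches) == 0L && length(extras) == 0L)
    "valid" else "invalid"
  new("ValidationReport", archivePath = archive@rootPath, status = status,
      mismatches = mismatches, extras = extras)
}
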