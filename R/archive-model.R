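# Reading zipped result archives into memory.  An archive holds exactly one
# top-level directory named by the root result's UUID, containing VERSION,
# metadata.yaml, an optional checksums.md5 manifest, opaque payload under
# data/, and a nested provenance/ tree.

parseResultMetadata <- function(text) {
  y <- tryCatch(yaml::yaml.load(text),
                error = function(e) prStop(
                  paste0("unparseable metadata.yaml: ", conditionMessage(e)),
                  "pr_malformed_archive"))
  if (!is.list(y) || is.null(y$uuid) || is.null(y$type) || is.null(y$format))
    prStop("metadata.yaml must carry uuid, type and format",
           "pr_malformed_archive")
  new("ResultMetadata", uuid = as.character(y$uuid),
      semanticType = as.character(y$type),
      dataFormat = as.character(y$format))
}

renderResultMetadata <- function(metadata) {
  yaml::as.yaml(list(uuid = metadata@uuid, type = metadata@semanticType,
                     format = metadata@dataFormat))
}

#' Read one zipped result archive
#'
#' Opens a zipped result (\code{.zip}, \code{.qza} or \code{.qzv}), checks
#' the single-root structure, and parses the root \code{metadata.yaml} and
#' \code{VERSION} records. Payload files under \code{data/} are indexed but
#' never read or extracted; the provenance tree is parsed separately by
#' \code{\link{parseProvenanceTree}}.
#'
#' @param path Path to a readable zip file.
#' @return A \linkS4class{ResultArchive}.
#' @seealso \code{\link{discoverArchives}}, \code{\link{readMember}},
#'   \code{\link{validateChecksums}}
#' @export
readArchive <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    prStop(sprintf("no such archive file: '%s'", path), "pr_format_error")
  if (!looksLikeZip(path))
    prStop(sprintf("not a zip archive: '%s'", path), "pr_format_error")
  listing <- utils::unzip(path, list = TRUE)
  keep <- !grepl("/$", listing$Name)
  members <- listing$Name[keep]
  sizes <- as.numeric(listing$Length[keep])
  if (!length(members))
    prStop(sprintf("malformed archive (empty): '%s'", path),
           "pr_malformed_archive")
  tops <- unique(sub("/.*$", "", members))
  if (length(tops) != 1L)
    prStop(sprintf(
      "malformed archive '%s': expected one top-level directory, found %d (%s)",
      path, length(tops), paste(tops, collapse = ", ")),
      "pr_malformed_archive")
  root <- tops
  for (req in paste0(root, c("/metadata.yaml", "/VERSION")))
    if (!req %in% members)
      prStop(sprintf("malformed archive '%s': missing member '%s'",
                     path, req), "pr_malformed_archive")
  getText <- function(rel) {
    idx <- match(rel, members)
    rawToUtf8(readZipMember(path, rel, sizes[idx]))
  }
  metadata <- parseResultMetadata(getText(paste0(root, "/metadata.yaml")))
  if (metadata@uuid != root)
    prStop(sprintf(
      "malformed archive '%s': metadata uuid %s != root directory %s",
      path, metadata@uuid, root), "pr_malformed_archive")
  version <- parseVersionInfo(getText(paste0(root, "/VERSION")))
  new("ResultArchive", rootPath = path, rootUuid = root,
      metadata = metadata, version = version,
      memberPaths = members, memberSizes = sizes)
}

#' Discover result archives under files and directories
#'
#' Files are read directly; directories are scanned recursively for
#' \code{.zip}/\code{.qza}/\code{.qzv} candidates. Candidates that fail to
#' read are skipped with a message rather than aborting the scan.
#'
#' @param paths Character vector of file and/or directory paths.
#' @param verbose Emit skip notices for unreadable candidates.
#' @return A list of \linkS4class{ResultArchive}, sorted by root UUID.
#' @export
discoverArchives <- function(paths, verbose = TRUE) {
  candidates <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      candidates <- c(candidates,
                      list.files(p, pattern = "\\.(zip|qza|qzv)$",
                                 recursive = TRUE, full.names = TRUE,
                                 ignore.case = TRUE))
    } else if (file.exists(p)) {
      candidates <- c(candidates, p)
    } else {
      prStop(sprintf("no such path: '%s'", p), "pr_format_error")
    }
  }
  archives <- list()
  for (cand in candidates) {
    a <- tryCatch(readArchive(cand), provreplay_error = function(e) {
      prLog(sprintf("skipping '%s': %s", cand, conditionMessage(e)),
            verbose = verbose)
      NULL
    })
    if (!is.null(a)) archives[[length(archives) + 1L]] <- a
  }
  if (!length(archives))
    prStop("no archives found", "pr_no_archives")
  archives[order(vapply(archives, rootUuid, character(1)))]
}

#' Read one member of an archive
#'
#' Returns the exact stored bytes of an archive member, read through an
#' in-memory connection (nothing is extracted to disk).
#'
#' @param archive A \linkS4class{ResultArchive}.
#' @param relpath Archive-relative member path.
#' @return A raw vector.
#' @export
readMember <- function(archive, relpath) {
  idx <- match(relpath, archive@memberPaths)
  if (is.na(idx))
    prStop(sprintf("archive '%s' has no member '%s'",
                   archive@rootPath, relpath), "pr_missing_member")
  readZipMember(archive@rootPath, relpath, archive@memberSizes[idx])
}

readMemberText <- function(archive, relpath) {
  rawToUtf8(readMember(archive, relpath))
}
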