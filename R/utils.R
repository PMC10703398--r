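# Internal utilities: structured error conditions, hashing, v4 UUIDs,
# timestamps, and a deterministic store-only ZIP writer.

prStop <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "provreplay_error")))
}

prWarn <- function(message, class = "provreplay_warning") {
  warning(warningCondition(message, class = c(class, "provreplay_warning")))
}

prLog <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

#' MD5 digest of a byte stream
#'
#' Computes the RFC 1321 MD5 digest of raw bytes (or a character scalar, taken
#' as its UTF-8 bytes) and returns it as a 32-character lowercase hex string.
#' Used for checksum-manifest validation; empty input is valid.
#'
#' @param content A raw vector, or a length-1 character vector.
#' @return A 32-character lowercase hexadecimal digest string.
#' @examples
#' computeMD5(raw(0))         # digest of the empty stream
#' computeMD5(charToRaw("abc"))
#' @export
computeMD5 <- function(content) {
  if (is.character(content)) {
    stopifnot(length(content) == 1L)
    content <- charToRaw(enc2utf8(content))
  }
  if (!is.raw(content)) {
    prStop("computeMD5() expects a raw vector or a single string",
           "pr_type_error")
  }
  tf <- tempfile("md5-")
  on.exit(unlink(tf), add = TRUE)
  writeBin(content, tf)
  unname(tools::md5sum(tf))
}

# CRC-32 (polynomial 0xEDB88320, as used by ZIP), table-driven.
# bitwShiftR is a logical shift on the 32-bit pattern, so the usual unsigned
# algorithm works on R's signed integers; the final value is returned as a
# non-negative double < 2^32.
.crcEnv <- new.env(parent = emptyenv())

crcTable <- function() {
  if (is.null(.crcEnv$tab)) {
    tab <- integer(256)
    for (i in 0:255) {
      cc <- i
      for (k in 1:8) {
        cc <- if (bitwAnd(cc, 1L))
          bitwXor(-306674912L, bitwShiftR(cc, 1L))  # 0xEDB88320 as signed
        else bitwShiftR(cc, 1L)
      }
      tab[i + 1L] <- cc
    }
    .crcEnv$tab <- tab
  }
  .crcEnv$tab
}

crc32 <- function(bytes) {
  .Call(C_crc32, bytes)
}

# Pure-R reference implementation (kept as an independent cross-check).
crc32R <- function(bytes) {
  tab <- crcTable()
  cc <- -1L
  for (b in as.integer(bytes)) {
    cc <- bitwXor(bitwShiftR(cc, 8L), tab[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  }
  cc <- bitwXor(cc, -1L)
  if (cc < 0) cc + 4294967296 else as.numeric(cc)
}

# Little-endian unsigned integer fields for ZIP headers.
u16 <- function(x) {
  x <- as.numeric(x) %% 65536
  as.raw(c(x %% 256, x %/% 256))
}

u32 <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# Writes `members` (a named list of raw vectors; names are archive paths with
# "/" separators) to a ZIP file at `path`.  Entries are stored uncompressed
# with a fixed DOS timestamp so identical member sets yield byte-identical
# archives.  Store-only keeps the writer simple; provenance members are small.
writeZip <- function(path, members) {
  stopifnot(is.list(members), !is.null(names(members)))
  # fixed DOS date/time: 2023-06-01 12:00:00
  dosTime <- u16(12 * 2048 + 0 * 32 + 0)
  dosDate <- u16((2023 - 1980) * 512 + 6 * 32 + 1)
  locals <- vector("list", length(members))
  centrals <- vector("list", length(members))
  offset <- 0
  for (i in seq_along(members)) {
    nm <- names(members)[i]
    data <- members[[i]]
    stopifnot(is.raw(data))
    fname <- charToRaw(enc2utf8(nm))
    crc <- crc32(data)
    local <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
      dosTime, dosDate, u32(crc), u32(length(data)), u32(length(data)),
      u16(length(fname)), u16(0), fname, data
    )
    centrals[[i]] <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0), u16(0),
      dosTime, dosDate, u32(crc), u32(length(data)), u32(length(data)),
      u16(length(fname)), u16(0), u16(0), u16(0), u16(0), u32(0),
      u32(offset), fname
    )
    locals[[i]] <- local
    offset <- offset + length(local)
  }
  central <- unlist(centrals)
  if (is.null(central)) central <- raw(0)
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
    u16(length(members)), u16(length(members)),
    u32(length(central)), u32(offset), u16(0)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(unlist(c(locals, list(central, list(eocd)))), con)
  invisible(path)
}

# Reads one member of a ZIP file as raw bytes through an unz() connection;
# nothing is extracted to disk.
readZipMember <- function(zipPath, member, size) {
  con <- unz(zipPath, member, open = "rb")
  on.exit(close(con), add = TRUE)
  readBin(con, raw(), n = size + 1L)[seq_len(size)]
}

looksLikeZip <- function(path) {
  if (!file.exists(path) || dir.exists(path)) return(FALSE)
  magic <- readBin(path, raw(), n = 4L)
  length(magic) == 4L && magic[1] == 0x50 && magic[2] == 0x4b &&
    magic[3] %in% as.raw(c(0x03, 0x05, 0x07))
}

# Deterministic v4 UUIDs drawn from the session RNG (seedable).
uuid4 <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
    bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0fL), 0x40L)  # version nibble = 4
    bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3fL), 0x80L)  # RFC 4122 variant
    hex <- paste(sprintf("%02x", bytes), collapse = "")
    paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
          substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
  }, character(1))
}

isUuid4 <- function(x) {
  grepl("^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
        x)
}

# ISO-8601 instants with explicit offset (D: unambiguous absolute ordering).
formatInstant <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")
}

parseInstant <- function(x) {
  # strptime's %z takes +0000 but not the ISO colon form +00:00
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  t <- strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (is.na(t)) prStop(sprintf("unparseable timestamp: '%s'", x),
                       "pr_schema_error")
  as.POSIXct(t)
}

rawToUtf8 <- function(bytes) {
  txt <- rawToChar(bytes)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) prStop("content is not valid UTF-8", "pr_format_error")
  txt
}

# Run code under a seeded RNG without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
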