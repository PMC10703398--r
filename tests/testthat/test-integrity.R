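test_that("computeMD5 matches the RFC 1321 test vectors", {
  # reference digests from the md5sum utility / RFC 1321 appendix
  expect_identical(computeMD5(raw(0)), "d41d8cd98f00b204e9800998ecf8427e")
  expect_identical(computeMD5(charToRaw("abc")),
                   "900150983cd24fb0d6963f7d28e17f72")
  expect_identical(computeMD5("message digest"),
                   "f96b697d7cb7938d525a2f31aaf161d0")
  bytes <- as.raw(sample(0:255, 100, replace = TRUE))
  expect_identical(computeMD5(bytes), computeMD5(bytes))
})

test_that("manifest parsing reads the md5sum dialect and rejects garbage", {
  m <- parseChecksumManifest(
    "d41d8cd98f00b204e9800998ecf8427e  metadata.yaml\n")
  expect_identical(manifestEntries(m)$path, "metadata.yaml")
  expect_identical(manifestEntries(m)$digest,
                   "d41d8cd98f00b204e9800998ecf8427e")
  expect_identical(nrow(manifestEntries(parseChecksumManifest(""))), 0L)
  expect_error(parseChecksumManifest("xyz  file\n"),
               class = "pr_unparseable_manifest")
  expect_error(parseChecksumManifest(paste0(
    "d41d8cd98f00b204e9800998ecf8427e  a\n",
    "d41d8cd98f00b204e9800998ecf8427e  a\n")),
    class = "pr_duplicate_entry")
  # single space separator is not the dialect
  expect_error(parseChecksumManifest(
    "d41d8cd98f00b204e9800998ecf8427e a\n"),
    class = "pr_unparseable_manifest")
})

test_that("untampered archives validate; legacy archives predate checksums", {
  res <- simFixture(41, nImports = 1L, nActions = 3L)
  for (p in res$paths) {
    report <- validateChecksums(readArchive(p))
    expect_identical(validationStatus(report), "valid")
    expect_identical(nrow(report@mismatches), 0L)
    expect_length(report@extras, 0L)
  }
  legacy <- simFixture(41, nImports = 1L, nActions = 2L, archiveVersion = 1L)
  expect_identical(validationStatus(validateChecksums(
    readArchive(legacy$paths[1]))), "predates-checksums")
})

test_that("a flipped byte is reported on exactly the altered path", {
  res <- simFixture(43, nImports = 1L, nActions = 3L)
  path <- res$paths[1]
  a <- readArchive(path)
  root <- rootUuid(a)
  # property over randomly chosen members (manifest handled separately)
  members <- setdiff(memberPaths(a), paste0(root, "/checksums.md5"))
  for (member in sample(members, 4L)) {
    tampered <- tamperArchive(path, member, "flip-byte",
                              outPath = withr::local_tempfile(fileext = ".qza"))
    report <- validateChecksums(readArchive(tampered))
    expect_identical(validationStatus(report), "invalid")
    expect_identical(report@mismatches$path, sub(paste0("^", root, "/"), "",
                                                 member))
    expect_length(report@extras, 0L)
  }
  # the original archive is untouched (copy-on-write tampering)
  expect_identical(validationStatus(validateChecksums(readArchive(path))),
                   "valid")
})

test_that("deleted and extra members are reported", {
  res <- simFixture(47, nImports = 1L, nActions = 2L)
  path <- res$paths[1]
  root <- rootUuid(readArchive(path))
  victim <- paste0(root, "/provenance/action/action.yaml")
  gone <- tamperArchive(path, victim, "delete",
                        outPath = withr::local_tempfile(fileext = ".qza"))
  report <- suppressWarnings(validateChecksums(readArchive(gone)))
  expect_identical(validationStatus(report), "invalid")
  expect_true(sub(paste0("^", root, "/"), "", victim) %in%
                report@mismatches$path)
  expect_identical(report@mismatches$observed, "missing")

  extra <- tamperArchive(path, paste0(root, "/data/unlisted.txt"), "append",
                         outPath = withr::local_tempfile(fileext = ".qza"))
  report <- validateChecksums(readArchive(extra))
  expect_identical(validationStatus(report), "invalid")
  expect_identical(report@extras, "data/unlisted.txt")
})

test_that("the manifest never lists itself", {
  res <- simFixture(53, nImports = 1L, nActions = 2L)
  a <- readArchive(res$paths[1])
  m <- parseChecksumManifest(
    rawToChar(readMember(a, paste0(rootUuid(a), "/checksums.md5"))))
  expect_false(any(grepl("checksums\\.md5$", manifestEntries(m)$path)))
})
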