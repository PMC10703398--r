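test_that("bibtex entries parse with field order preserved", {
  entries <- parseBibtex(paste0(
    "@Article{key1,\n",
    "  title = {A Title, with a comma},\n",
    "  author = \"Someone\",\n",
    "  year = 2023,\n",
    "  doi = {10.5555/x.1}\n",
    "}\n"))
  expect_length(entries, 1L)
  expect_identical(citationKey(entries[[1]]), "key1")
  expect_identical(entries[[1]]@entryType, "article")
  expect_identical(names(citationFields(entries[[1]])),
                   c("title", "author", "year", "doi"))
  expect_identical(citationFields(entries[[1]])[["title"]],
                   "A Title, with a comma")
  expect_identical(parseBibtex(""), list())
  expect_identical(parseBibtex("% only a comment\n"), list())
  expect_error(parseBibtex("no entries here"), class = "pr_bib_parse_error")
  expect_warning(
    mixed <- parseBibtex("@misc{ok, year = 2023}\n@broken{\n"),
    class = "pr_bib_skip")
  expect_length(mixed, 1L)
})

test_that("render and parse round-trip exactly", {
  res <- simFixture(171, nImports = 1L, nActions = 3L)
  pu <- parseUnion(res$paths)
  entries <- dedupCitations(collectCitations(pu$dag, pu$archives))
  text <- renderBibtex(entries)
  expect_equal(parseBibtex(text), entries)
  expect_identical(renderBibtex(entries), text)  # deterministic
  expect_match(renderBibtex(list()), "^%")
  dup <- c(entries, entries[1])
  expect_error(renderBibtex(dup), class = "pr_bib_render_error")
})

test_that("collection retains duplicates; dedup collates them", {
  n1 <- mkImportNode(fixedUuid(1L))
  n1@action@citationKeys <- "k1"
  n2 <- mkActionNode(fixedUuid(2L), inputs = list(table = fixedUuid(1L)))
  n2@action@citationKeys <- c("k1", "k2")
  mkEntry <- function(key, doi = NULL) {
    fields <- c(title = paste("Work", key), year = "2023")
    if (!is.null(doi)) fields["doi"] <- doi
    new("CitationEntry", key = key, entryType = "misc", fields = fields)
  }
  collected <- list(mkEntry("k1", "10.5555/a"), mkEntry("k1", "10.5555/a"),
                    mkEntry("k2", "10.5555/b"))
  deduped <- dedupCitations(collected)
  expect_length(deduped, 2L)
  expect_identical(vapply(deduped, citationKey, character(1)), c("k1", "k2"))
})

test_that("dedup merges on normalized DOI and disambiguates colliding keys", {
  e <- function(key, doi) new("CitationEntry", key = key, entryType = "misc",
                              fields = c(title = key, doi = doi))
  # same DOI under different spellings merges, keeping the first entry
  merged <- dedupCitations(list(e("a", "10.5555/X.1"),
                                e("b", "https://doi.org/10.5555/x.1")))
  expect_length(merged, 1L)
  expect_identical(citationKey(merged[[1]]), "a")
  # DOI-less entries with distinct keys are both kept
  noDoi <- function(key) new("CitationEntry", key = key, entryType = "misc",
                             fields = c(title = key))
  expect_length(dedupCitations(list(noDoi("x"), noDoi("y"))), 2L)
  # surviving key collisions get letter suffixes; dedup is idempotent
  collided <- dedupCitations(list(e("same", "10.5555/p.1"),
                                  e("same", "10.5555/p.2")))
  expect_identical(vapply(collided, citationKey, character(1)),
                   c("same_a", "same_b"))
  once <- dedupCitations(list(e("a", "10.5555/q.1"), noDoi("x"), noDoi("x")))
  expect_equal(dedupCitations(once), once)
})

test_that("the bibliography covers exactly the generator's DOIs", {
  res <- simFixture(173, nImports = 2L, nActions = 5L)
  pu <- parseUnion(res$paths)
  entries <- dedupCitations(collectCitations(pu$dag, pu$archives))
  renderedDois <- sort(unlist(lapply(entries, function(e)
    unname(citationFields(e)["doi"]))))
  truthDois <- sort(unique(unlist(lapply(res$state$bibs, function(bib)
    lapply(bib, function(e) unname(citationFields(e)["doi"]))))))
  truthDois <- truthDois[!is.na(truthDois)]
  expect_identical(renderedDois[!is.na(renderedDois)], truthDois)
})
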