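test_that("buildDag derives edges from recorded inputs", {
  imp <- mkImportNode(fixedUuid(1L))
  dag1 <- buildDag(list(imp))
  expect_length(provNodes(dag1), 1L)
  expect_identical(nrow(provEdges(dag1)), 0L)
  expect_identical(terminalUuids(dag1), fixedUuid(1L))

  chain <- buildDag(mkChainNodes())
  expect_identical(edgeKey(chain),
                   sort(paste(c(fixedUuid(1L), fixedUuid(2L)),
                              c(fixedUuid(2L), fixedUuid(3L)))))
  expect_identical(terminalUuids(chain), fixedUuid(3L))
})

test_that("unknown input uuids become no-provenance stubs", {
  orphan <- mkActionNode(fixedUuid(2L),
                         inputs = list(table = fixedUuid(99L)))
  dag <- buildDag(list(orphan))
  expect_length(provNodes(dag), 2L)
  expect_false(hasProvenance(provNodes(dag)[[fixedUuid(99L)]]))
})

test_that("cycles are rejected as corrupt provenance", {
  n1 <- mkActionNode(fixedUuid(1L), inputs = list(x = fixedUuid(2L)), t = 1L)
  n2 <- mkActionNode(fixedUuid(2L), inputs = list(x = fixedUuid(1L)), t = 2L)
  expect_error(buildDag(list(n1, n2)), class = "pr_corrupt_provenance")
})

test_that("union merges shared ancestry exactly once", {
  pair <- makeOverlappingPair(101)
  a <- parseUnion(pair$pathsA)$dag
  b <- parseUnion(pair$pathsB)$dag
  u <- unionDags(list(a, b))
  expect_length(provNodes(u),
                length(provNodes(a)) + length(provNodes(b)) -
                  pair$overlapCount)
  # idempotence and commutativity on node/edge sets
  expect_identical(sort(names(provNodes(unionDags(list(a, a))))),
                   sort(names(provNodes(a))))
  u2 <- unionDags(list(b, a))
  expect_identical(sort(names(provNodes(u))), sort(names(provNodes(u2))))
  expect_identical(edgeKey(u), edgeKey(u2))
})

test_that("union of disjoint dags concatenates; conflicts are refused", {
  resA <- simFixture(103, nImports = 1L, nActions = 2L)
  resB <- simFixture(104, nImports = 1L, nActions = 2L)
  a <- parseUnion(resA$paths)$dag
  b <- parseUnion(resB$paths)$dag
  expect_length(provNodes(unionDags(list(a, b))),
                length(provNodes(a)) + length(provNodes(b)))
  # a full-provenance node always replaces a stub for the same uuid
  stubbed <- buildDag(list(mkActionNode(fixedUuid(2L),
                                        inputs = list(x = fixedUuid(1L)))))
  full <- buildDag(list(mkImportNode(fixedUuid(1L))))
  merged <- unionDags(list(stubbed, full))
  expect_true(hasProvenance(provNodes(merged)[[fixedUuid(1L)]]))
  # conflicting records for one uuid violate immutability
  v1 <- mkActionNode(fixedUuid(7L), inputs = list(x = fixedUuid(1L)),
                     parameters = list(`sampling-depth` = 1000L))
  v2 <- mkActionNode(fixedUuid(7L), inputs = list(x = fixedUuid(1L)),
                     parameters = list(`sampling-depth` = 2000L))
  d1 <- buildDag(list(mkImportNode(fixedUuid(1L)), v1))
  d2 <- buildDag(list(mkImportNode(fixedUuid(1L)), v2))
  expect_error(unionDags(list(d1, d2)), class = "pr_conflict")
})

test_that("ancestry matches brute-force reverse reachability", {
  chain <- buildDag(mkChainNodes())
  expect_length(provNodes(dagAncestry(chain, fixedUuid(1L))), 1L)
  expect_length(provNodes(dagAncestry(chain, fixedUuid(3L))), 3L)
  expect_error(dagAncestry(chain, fixedUuid(99L)), class = "pr_missing_node")

  skip_if_not_installed("igraph")
  for (seed in c(107, 109)) {
    res <- simFixture(seed, nImports = 2L, nActions = 6L)
    dag <- res$dag
    g <- igraph::graph_from_data_frame(provEdges(dag), directed = TRUE,
                                       vertices = names(provNodes(dag)))
    for (u in sample(names(provNodes(dag)), 3L)) {
      mine <- sort(names(provNodes(dagAncestry(dag, u))))
      ref <- sort(names(igraph::subcomponent(g, u, mode = "in")))
      expect_identical(mine, ref)
      expect_identical(terminalUuids(dagAncestry(dag, u)), u)
    }
  }
})

test_that("topological order is valid and deterministically tie-broken", {
  # two roots with equal timestamps order by ascending uuid
  r1 <- mkImportNode(fixedUuid(10L), execUuid = fixedUuid(900L), t = 1L)
  r2 <- mkImportNode(fixedUuid(11L), execUuid = fixedUuid(901L), t = 1L)
  dag <- buildDag(list(r2, r1))
  expect_identical(topologicalOrder(dag)[1:2],
                   c(fixedUuid(10L), fixedUuid(11L)))

  chain <- buildDag(mkChainNodes())
  expect_identical(topologicalOrder(chain),
                   vapply(1:3, fixedUuid, character(1)))

  for (seed in 111:118) {
    res <- simFixture(seed, nImports = 2L, nActions = 5L)
    ord <- topologicalOrder(res$dag)
    pos <- stats::setNames(seq_along(ord), ord)
    e <- provEdges(res$dag)
    # brute-force pairwise check: every producer precedes its consumers
    expect_true(all(pos[e$from] < pos[e$to]))
  }
})

test_that("nodes group by execution with one group per action run", {
  res <- simFixture(119, nImports = 1L, nActions = 5L,
                    multiOutputFraction = 1)
  groups <- groupByExecution(res$dag)
  execIds <- unique(vapply(provNodes(res$dag), function(n)
    executionUuid(actionRecord(n)), character(1)))
  expect_length(groups, length(execIds))
  sizes <- vapply(groups, function(g) length(g$nodes), integer(1))
  expect_true(any(sizes > 1L))  # multi-output actions group together
  # disagreeing records within one execution are refused
  x1 <- mkActionNode(fixedUuid(20L), inputs = list(x = fixedUuid(1L)),
                     execUuid = fixedUuid(800L), outputName = "a",
                     parameters = list(p = 1L))
  x2 <- mkActionNode(fixedUuid(21L), inputs = list(x = fixedUuid(1L)),
                     execUuid = fixedUuid(800L), outputName = "b",
                     parameters = list(p = 2L))
  dag <- buildDag(list(mkImportNode(fixedUuid(1L)), x1, x2))
  expect_error(groupByExecution(dag), class = "pr_conflict")
})

test_that("rebuilt DAGs equal generator ground truth", {
  for (seed in c(121, 127)) {
    res <- simFixture(seed, nImports = 2L, nActions = 6L)
    pu <- parseUnion(res$paths)
    expectDagMatchesTruth(pu$dag, res$dag)
  }
})

test_that("DOT export emits one box per execution group", {
  res <- simFixture(131, nImports = 1L, nActions = 3L)
  dot <- exportDot(res$dag)
  expect_match(dot, "^digraph provenance \\{")
  nGroups <- length(groupByExecution(res$dag))
  expect_identical(length(gregexpr("label=", dot)[[1]]) -
                     nrow(provEdges(res$dag)), nGroups)
})
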