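# The provenance DAG: results are nodes keyed by UUID; each consumer's
# recorded inputs induce producer -> consumer edges.  Actions annotate their
# output nodes; an execution with several outputs is recovered by grouping
# nodes on the shared execution UUID.

makeStubNode <- function(uuid) {
  new("ProvNode", resultUuid = uuid,
      metadata = new("ResultMetadata", uuid = uuid,
                     semanticType = "Unknown", dataFormat = "Unknown"),
      action = NULL, environment = NULL, hasProvenance = FALSE)
}

# Canonical list form of an ActionRecord for equality checks (immutability:
# two results claiming the same uuid/execution must agree).
canonicalAction <- function(a, ignoreOutput = FALSE) {
  list(executionUuid = a@executionUuid, actionType = a@actionType,
       plugin = a@plugin, actionName = a@actionName, inputs = a@inputs,
       parameters = a@parameters,
       outputName = if (ignoreOutput) NULL else a@outputName,
       startTime = a@startTime, endTime = a@endTime,
       citationKeys = a@citationKeys,
       importManifest = a@importManifest)
}

nodeStartInstant <- function(node) {
  if (!node@hasProvenance) return(-Inf)
  as.numeric(parseInstant(node@action@startTime))
}

dagEdgesFromNodes <- function(nodes) {
  from <- character(0); to <- character(0)
  for (node in nodes) {
    if (!node@hasProvenance) next
    for (inp in node@action@inputs) {
      if (is.null(inp)) next
      from <- c(from, inp)
      to <- c(to, node@resultUuid)
    }
  }
  unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

# Kahn's algorithm with deterministic candidate choice; returns NULL when a
# cycle blocks completion.
kahnOrder <- function(uuids, edges, startKey) {
  indeg <- stats::setNames(integer(length(uuids)), uuids)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  remainingEdges <- edges
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    keys <- startKey[ready]
    pick <- ready[order(keys, ready)][1]
    order <- c(order, pick)
    ready <- setdiff(ready, pick)
    out <- remainingEdges$from == pick
    for (v in remainingEdges$to[out]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) ready <- c(ready, v)
    }
    remainingEdges <- remainingEdges[!out, , drop = FALSE]
  }
  if (length(order) != length(uuids)) return(NULL)
  order
}

findOneCycle <- function(uuids, edges) {
  adj <- split(edges$to, factor(edges$from, levels = uuids))
  state <- stats::setNames(integer(length(uuids)), uuids)  # 0 new 1 open 2 done
  path <- character(0)
  cycle <- NULL
  visit <- function(u) {
    if (!is.null(cycle)) return()
    state[u] <<- 1L
    path <<- c(path, u)
    for (v in adj[[u]]) {
      if (state[v] == 1L) {
        cycle <<- c(path[which(path == v)[1]:length(path)], v)
        return()
      }
      if (state[v] == 0L) visit(v)
      if (!is.null(cycle)) return()
    }
    state[u] <<- 2L
    path <<- path[-length(path)]
  }
  for (u in uuids) if (state[u] == 0L) visit(u)
  cycle
}

#' Build a provenance DAG from parsed nodes
#'
#' Derives one edge per (input UUID -> consuming result) pair across all
#' action records, creates provenance-less stub nodes for inputs that name
#' unknown results, and verifies acyclicity.
#'
#' @param nodes A list of \linkS4class{ProvNode} with unique result UUIDs.
#' @return A \linkS4class{ProvDAG}.
#' @export
buildDag <- function(nodes) {
  if (length(nodes)) names(nodes) <- vapply(nodes, resultUuid, character(1))
  if (anyDuplicated(names(nodes)))
    prStop("node result uuids must be unique", "pr_conflict")
  referenced <- unique(unlist(lapply(nodes, function(n) {
    if (n@hasProvenance) unlist(n@action@inputs) else NULL
  })))
  for (miss in setdiff(referenced, names(nodes)))
    nodes[[miss]] <- makeStubNode(miss)
  edges <- dagEdgesFromNodes(nodes)
  startKey <- vapply(nodes, nodeStartInstant, numeric(1))
  ord <- kahnOrder(names(nodes), edges, startKey)
  if (is.null(ord)) {
    cyc <- findOneCycle(names(nodes), edges)
    prStop(sprintf("corrupt provenance: cycle %s",
                   paste(cyc, collapse = " -> ")), "pr_corrupt_provenance")
  }
  new("ProvDAG", nodes = nodes, edges = edges,
      terminalUuids = sort(setdiff(names(nodes), edges$from)))
}

#' Union provenance DAGs across results
#'
#' Merges node sets by result UUID: a node with provenance always replaces a
#' stub, the first-seen record wins among equals, and two full-provenance
#' records that disagree for the same UUID violate result immutability and
#' raise a conflict error. Edges and terminals are recomputed, so shared
#' ancestry appears exactly once.
#'
#' @param dags Non-empty list of \linkS4class{ProvDAG}.
#' @return A \linkS4class{ProvDAG}.
#' @export
unionDags <- function(dags) {
  if (!length(dags)) prStop("unionDags() needs at least one DAG",
                            "pr_format_error")
  merged <- list()
  for (dag in dags) {
    for (node in dag@nodes) {
      u <- node@resultUuid
      existing <- merged[[u]]
      if (is.null(existing)) {
        merged[[u]] <- node
      } else if (!existing@hasProvenance && node@hasProvenance) {
        merged[[u]] <- node
      } else if (existing@hasProvenance && node@hasProvenance &&
                 !identical(canonicalAction(existing@action),
                            canonicalAction(node@action))) {
        prStop(sprintf(
          "conflicting provenance for result %s (results are immutable)", u),
          "pr_conflict")
      }
    }
  }
  buildDag(merged)
}

#' Ancestry sub-DAG of one result
#'
#' Returns the induced sub-DAG containing \code{uuid} and every transitive
#' predecessor; its single terminal is \code{uuid}.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @param uuid A result UUID present in the DAG.
#' @return A \linkS4class{ProvDAG}.
#' @export
dagAncestry <- function(dag, uuid) {
  if (!uuid %in% names(dag@nodes))
    prStop(sprintf("no node %s in DAG", uuid), "pr_missing_node")
  keep <- uuid
  frontier <- uuid
  while (length(frontier)) {
    preds <- dag@edges$from[dag@edges$to %in% frontier]
    frontier <- setdiff(preds, keep)
    keep <- union(keep, frontier)
  }
  buildDag(dag@nodes[keep])
}

#' Deterministic topological order of a provenance DAG
#'
#' Every producer precedes its consumers; ties are broken by ascending
#' (start time, result UUID), nodes without provenance first, so the order
#' is stable across runs and input permutations.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @return Character vector of result UUIDs.
#' @export
topologicalOrder <- function(dag) {
  startKey <- vapply(dag@nodes, nodeStartInstant, numeric(1))
  kahnOrder(names(dag@nodes), dag@edges, startKey)
}

#' Group DAG nodes by execution
#'
#' Nodes sharing an execution UUID are the several outputs of one action and
#' must replay as a single statement. Groups are ordered by the topological
#' position of their earliest member; nodes without provenance form
#' singleton groups. Members of one execution whose records disagree on
#' plugin, action, or parameters raise a conflict error.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @return Ordered list of \code{list(executionUuid =, nodes =)}; the
#'   execution UUID is \code{NA} for provenance-less groups.
#' @export
groupByExecution <- function(dag) {
  ord <- topologicalOrder(dag)
  pos <- stats::setNames(seq_along(ord), ord)
  groups <- list()
  firstPos <- numeric(0)
  keyOf <- function(node) {
    if (node@hasProvenance) node@action@executionUuid
    else paste0("no-provenance:", node@resultUuid)
  }
  for (u in ord) {
    node <- dag@nodes[[u]]
    key <- keyOf(node)
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(node)
      firstPos[key] <- pos[u]
    } else {
      ref <- groups[[key]][[1]]
      if (!identical(canonicalAction(ref@action, ignoreOutput = TRUE),
                     canonicalAction(node@action, ignoreOutput = TRUE)))
        prStop(sprintf(
          "nodes of execution %s disagree on plugin/action/parameters",
          node@action@executionUuid), "pr_conflict")
      groups[[key]] <- c(groups[[key]], list(node))
    }
  }
  keys <- names(groups)[order(firstPos[names(groups)])]
  lapply(keys, function(k) {
    nodes <- groups[[k]]
    list(executionUuid = if (startsWith(k, "no-provenance:")) NA_character_
         else k,
         nodes = nodes)
  })
}

#' Export a provenance DAG to DOT
#'
#' Renders one box per execution group labeled \code{plugin:action} (or
#' \code{import}), with result-labeled edges, for graph viewers.
#'
#' @param dag A \linkS4class{ProvDAG}.
#' @return A single DOT document string.
#' @export
exportDot <- function(dag) {
  groups <- groupByExecution(dag)
  groupOf <- integer(0)
  labels <- character(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    node <- g$nodes[[1]]
    labels[i] <- if (!node@hasProvenance)
      sprintf("no provenance\\n%s", node@resultUuid)
    else if (node@action@actionType == "import") "import"
    else paste0(node@action@plugin, ":", node@action@actionName)
    for (n in g$nodes) groupOf[n@resultUuid] <- i
  }
  lines <- c("digraph provenance {", "  node [shape=box];")
  for (i in seq_along(groups))
    lines <- c(lines, sprintf("  g%d [label=\"%s\"];", i, labels[i]))
  e <- dag@edges
  for (j in seq_len(nrow(e)))
    lines <- c(lines, sprintf("  g%d -> g%d [label=\"%s\"];",
                              groupOf[e$from[j]], groupOf[e$to[j]],
                              e$from[j]))
  paste0(paste(lines, collapse = "\n"), "\n}\n")
}
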