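#' Directed graph over named variables
#'
#' Lightweight directed-graph container used for Bayesian network
#' structures.  Node identity is by name and every deterministic order
#' (topological ties, serialized edge lists) follows the declaration order
#' of `nodes`.
#'
#' @param nodes Character vector of unique node names.
#' @param edges Edges as a two-column matrix or data frame
#'   (parent, child), or `NULL`/zero rows for the empty graph.
#' @param check_acyclic If `TRUE` (default), reject cyclic inputs.
#' @return An object of class `bn_graph` with elements `nodes` (character)
#'   and `parents` (named list mapping each node to its parent names,
#'   in declaration order).
#' @examples
#' g <- bn_graph(c("X", "Y", "Z"), rbind(c("X", "Z"), c("Y", "Z")))
#' topological_order(g)
#' @export
bn_graph <- function(nodes, edges = NULL, check_acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
    storage.mode(edges) <- "character"
    bad <- !(edges %in% nodes)
    if (any(bad)) stop("unknown node in edge list: ", edges[bad][1])
    if (any(edges[, 1] == edges[, 2])) stop("self-loop not allowed")
    key <- paste(edges[, 1], edges[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge")
    for (r in seq_len(nrow(edges))) {
      ch <- edges[r, 2]
      parents[[ch]] <- c(parents[[ch]], edges[r, 1])
    }
    # parents kept in declaration order for deterministic serialization
    parents <- lapply(parents, function(p) unname(p[order(match(p, nodes))]))
  }
  g <- structure(list(nodes = nodes, parents = parents), class = "bn_graph")
  if (check_acyclic) topological_order(g)  # errors on a cycle
  g
}

#' @export
print.bn_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat("bn_graph:", length(x$nodes), "nodes,", nrow(e), "edges\n")
  if (nrow(e) > 0)
    cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Edge matrix of a graph
#'
#' @param graph A `bn_graph`.
#' @return Two-column character matrix (parent, child), rows ordered by
#'   child then parent declaration order.
#' @export
graph_edges <- function(graph) {
  out <- matrix(character(0), 0, 2,
                dimnames = list(NULL, c("parent", "child")))
  for (ch in graph$nodes) {
    ps <- graph$parents[[ch]]
    if (length(ps))
      out <- rbind(out, cbind(parent = ps, child = rep(ch, length(ps))))
  }
  out
}

#' Number of edges
#' @param graph A `bn_graph`.
#' @export
n_edges <- function(graph) sum(lengths(graph$parents))

#' Topological order of a DAG
#'
#' Kahn's algorithm with deterministic tie-breaking: among nodes whose
#' parents are all placed, the earliest-declared node comes first, so an
#' edgeless graph returns its nodes in declaration order.
#'
#' @param graph A `bn_graph`.
#' @return Character vector of node names; every parent precedes each of
#'   its children.
#' @export
topological_order <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  indeg <- lengths(graph$parents)[nodes]
  children <- children_map(graph)
  placed <- character(0)
  avail <- indeg == 0
  while (length(placed) < n) {
    i <- which(avail)[1]
    if (is.na(i)) {
      stop("graph is cyclic: ", format_cycle(graph, nodes[indeg > 0]))
    }
    v <- nodes[i]
    avail[i] <- FALSE
    indeg[i] <- NA_integer_  # placed
    placed <- c(placed, v)
    for (ch in children[[v]]) {
      j <- match(ch, nodes)
      indeg[j] <- indeg[j] - 1L
      if (!is.na(indeg[j]) && indeg[j] == 0L) avail[j] <- TRUE
    }
  }
  placed
}

children_map <- function(graph) {
  out <- stats::setNames(rep(list(character(0)), length(graph$nodes)),
                         graph$nodes)
  for (ch in graph$nodes)
    for (p in graph$parents[[ch]])
      out[[p]] <- c(out[[p]], ch)
  out
}

# walk parent pointers among the still-unplaced nodes until a repeat
format_cycle <- function(graph, remaining) {
  v <- remaining[1]
  seen <- character(0)
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    ps <- intersect(graph$parents[[v]], remaining)
    v <- ps[1]
  }
  cyc <- c(seen[seq(match(v, seen), length(seen))], v)
  paste(cyc, collapse = " <- ")
}

#' Test acyclicity without raising an error
#' @param graph A `bn_graph` (possibly built with `check_acyclic = FALSE`).
#' @return `TRUE` if a topological order exists.
#' @export
is_acyclic <- function(graph) {
  !inherits(try(topological_order(graph), silent = TRUE), "try-error")
}

#' Is there a directed path from one node to another?
#' @param graph A `bn_graph`.
#' @param from,to Node names.
#' @return Logical.
#' @export
has_path <- function(graph, from, to) {
  if (from == to) return(TRUE)
  children <- children_map(graph)
  stack <- from
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(children[[v]], stack)
  }
  FALSE
}

#' Adjacency matrix (parents in rows, children in columns)
#' @param graph A `bn_graph`.
#' @export
adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (ch in graph$nodes) {
    ps <- graph$parents[[ch]]
    if (length(ps)) A[ps, ch] <- 1L
  }
  A
}

has_edge <- function(graph, from, to) from %in% graph$parents[[to]]

# Pure edge-operation helpers used by the hill climber; they do not check
# acyclicity (the caller guards with has_path).
add_edge <- function(graph, from, to) {
  graph$parents[[to]] <-
    sort_by_declaration(c(graph$parents[[to]], from), graph$nodes)
  graph
}
remove_edge <- function(graph, from, to) {
  graph$parents[[to]] <- setdiff(graph$parents[[to]], from)
  graph
}
reverse_edge <- function(graph, from, to) {
  add_edge(remove_edge(graph, from, to), to, from)
}

sort_by_declaration <- function(x, nodes) x[order(match(x, nodes))]

#' Write a graph as a plain-text edge list
#'
#' One `parent<TAB>child` line per edge, ordered deterministically.
#' @param graph A `bn_graph`.
#' @param path Output file path.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph_edges(graph)
  writeLines(if (nrow(e)) paste(e[, 1], e[, 2], sep = "\t") else character(0),
             path)
}
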