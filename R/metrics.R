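#' Edge confusion counts between a gold and a learned DAG
#'
#' Counts over the `n(n-1)/2` unordered variable pairs: a pair carrying
#' the same directed edge in both graphs is a TP; a pair with an edge in
#' neither is a TN; an edge only in the learned graph is an FP; an edge
#' only in the gold graph is an FN; and a pair adjacent in both but with
#' opposite orientation counts as both an FP and an FN.
#'
#' @param gold,learned `bn_graph`s on the same node set.
#' @return Object of class `bn_confusion` with fields `tp`, `tn`, `fp`,
#'   `fn` and `n` (variable count).
#' @export
edge_confusion <- function(gold, learned) {
  if (!setequal(gold$nodes, learned$nodes))
    stop("graphs must share the same node set")
  nodes <- gold$nodes
  n <- length(nodes)
  tp <- tn <- fp <- fn <- 0L
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    u <- nodes[a]; v <- nodes[b]
    g <- pair_state_dag(gold, u, v)
    l <- pair_state_dag(learned, u, v)
    if (g == l) {
      if (g == 0L) tn <- tn + 1L else tp <- tp + 1L
    } else if (g == 0L) {
      fp <- fp + 1L
    } else if (l == 0L) {
      fn <- fn + 1L
    } else {
      fp <- fp + 1L; fn <- fn + 1L  # wrong direction
    }
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n),
            class = "bn_confusion")
}

# 0 = no edge, 1 = u -> v, 2 = v -> u
pair_state_dag <- function(graph, u, v) {
  if (has_edge(graph, u, v)) 1L else if (has_edge(graph, v, u)) 2L else 0L
}

#' DAG comparison metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
#' `ahd = (FP+FN)/n` (average Hamming distance).  When the gold graph has
#' no edges (so `TP + FN = 0`) sensitivity is 1 by convention, and when
#' no pair carries any count (single-variable graphs) accuracy is 1:
#' with no possible errors, the graphs agree perfectly.
#'
#' @param conf A `bn_confusion`.
#' @export
accuracy <- function(conf) {
  denom <- conf$tp + conf$tn + conf$fp + conf$fn
  if (denom == 0) 1 else (conf$tp + conf$tn) / denom
}

#' @rdname accuracy
#' @export
sensitivity <- function(conf) {
  denom <- conf$tp + conf$fn
  if (denom == 0) 1 else conf$tp / denom
}

#' @rdname accuracy
#' @export
ahd <- function(conf) (conf$fp + conf$fn) / conf$n

#' Convert a DAG to its completed PDAG (CPDAG)
#'
#' Identifies the equivalence class of a DAG by labelling every edge
#' compelled or reversible with Chickering's edge-ordering algorithm;
#' compelled edges stay directed, reversible edges become undirected.
#' Edges of v-structures are always compelled.
#'
#' @param dag An acyclic `bn_graph`.
#' @return Object of class `bn_pdag`: `nodes`, `directed` (two-column
#'   matrix, parent then child), `undirected` (two-column matrix, each
#'   pair with the earlier-declared node first).
#' @export
to_cpdag <- function(dag) {
  nodes <- dag$nodes
  ord <- topological_order(dag)  # errors on cyclic input
  rank <- stats::setNames(seq_along(ord), ord)
  E <- graph_edges(dag)
  m <- nrow(E)
  if (m == 0)
    return(new_pdag(nodes, E, E))
  # --- order the edges ---
  eorder <- integer(m)  # position in the total order, 1..m
  next_pos <- 1L
  unord <- rep(TRUE, m)
  while (any(unord)) {
    child_rank <- rank[E[, 2]]
    y_rank <- min(child_rank[unord])
    cand <- which(unord & child_rank == y_rank)
    x <- cand[which.max(rank[E[cand, 1]])]
    eorder[x] <- next_pos
    next_pos <- next_pos + 1L
    unord[x] <- FALSE
  }
  # --- label the edges ---
  lab <- rep("unknown", m)
  edges_into <- function(v) which(E[, 2] == v)
  is_parent <- function(p, v) has_edge(dag, p, v)
  repeat {
    unknown <- which(lab == "unknown")
    if (length(unknown) == 0) break
    e <- unknown[which.min(eorder[unknown])]
    x <- E[e, 1]; y <- E[e, 2]
    resolved <- FALSE
    for (we in edges_into(x)) {
      if (lab[we] != "compelled") next
      w <- E[we, 1]
      if (!is_parent(w, y)) {
        lab[edges_into(y)] <- "compelled"
        resolved <- TRUE
        break
      } else {
        lab[which(E[, 1] == w & E[, 2] == y)] <- "compelled"
      }
    }
    if (resolved) next
    zs <- E[edges_into(y), 1]
    if (any(zs != x & !vapply(zs, is_parent, logical(1), v = x))) {
      idx <- edges_into(y)
      lab[idx[lab[idx] == "unknown"]] <- "compelled"
      lab[e] <- "compelled"
    } else {
      idx <- edges_into(y)
      lab[idx[lab[idx] == "unknown"]] <- "reversible"
      lab[e] <- "reversible"
    }
  }
  new_pdag(nodes, E[lab == "compelled", , drop = FALSE],
           E[lab == "reversible", , drop = FALSE])
}

new_pdag <- function(nodes, directed, undirected) {
  und <- undirected
  if (nrow(und)) {
    flip <- match(und[, 1], nodes) > match(und[, 2], nodes)
    und[flip, ] <- und[flip, c(2, 1)]
  }
  colnames(directed) <- c("parent", "child")
  colnames(und) <- c("a", "b")
  structure(list(nodes = nodes, directed = directed, undirected = und),
            class = "bn_pdag")
}

#' @export
print.bn_pdag <- function(x, ...) {
  cat("bn_pdag:", length(x$nodes), "nodes;",
      nrow(x$directed), "compelled,", nrow(x$undirected),
      "reversible edges\n")
  invisible(x)
}

# 0 none; 1 a->b; 2 b->a; 3 undirected (a, b in declaration order)
pair_state_pdag <- function(pdag, a, b) {
  d <- pdag$directed
  if (nrow(d)) {
    if (any(d[, 1] == a & d[, 2] == b)) return(1L)
    if (any(d[, 1] == b & d[, 2] == a)) return(2L)
  }
  u <- pdag$undirected
  if (nrow(u) && any((u[, 1] == a & u[, 2] == b) |
                     (u[, 1] == b & u[, 2] == a))) return(3L)
  0L
}

#' Are two PDAGs identical?
#' @param a,b `bn_pdag`s on the same node set.
#' @export
pdag_equal <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  nodes <- a$nodes
  n <- length(nodes)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (pair_state_pdag(a, nodes[i], nodes[j]) !=
        pair_state_pdag(b, nodes[i], nodes[j])) return(FALSE)
  }
  TRUE
}

#' Structural Hamming distance between equivalence classes
#'
#' Converts both DAGs to CPDAGs and counts, per unordered variable pair,
#' one unit for every adjacency or edge-type difference.  The
#' decomposition mirrors the structural-error bookkeeping of the study:
#' `add` — adjacency present only in the learned CPDAG; `delete` —
#' adjacency present only in the gold CPDAG; `rev` — both directed but
#' oppositely oriented; `mis` — adjacent in both but with mismatched
#' compelled/reversible status (directed in one, undirected in the
#' other).  `shd = add + delete + rev + mis`; two DAGs in the same
#' equivalence class are at distance 0.
#'
#' @param gold,learned Acyclic `bn_graph`s on the same node set.
#' @return Object of class `bn_shd`: `shd`, `add`, `delete`, `rev`,
#'   `mis`.
#' @export
shd <- function(gold, learned) {
  if (!setequal(gold$nodes, learned$nodes))
    stop("graphs must share the same node set")
  cg <- to_cpdag(gold)
  cl <- to_cpdag(learned)
  nodes <- gold$nodes
  n <- length(nodes)
  add <- del <- rev <- mis <- 0L
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    g <- pair_state_pdag(cg, nodes[i], nodes[j])
    l <- pair_state_pdag(cl, nodes[i], nodes[j])
    if (g == l) next
    if (g == 0L) add <- add + 1L
    else if (l == 0L) del <- del + 1L
    else if (g != 3L && l != 3L) rev <- rev + 1L
    else mis <- mis + 1L
  }
  structure(list(shd = add + del + rev + mis, add = add, delete = del,
                 rev = rev, mis = mis), class = "bn_shd")
}

#' @export
print.bn_shd <- function(x, ...) {
  cat("SHD", x$shd, "(add", x$add, "delete", x$delete, "rev", x$rev,
      "mis", x$mis, ")\n")
  invisible(x)
}
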