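# Shared fixtures and independent oracles.  The enumeration helpers are
# deliberately written from first principles (expand.grid over pair
# orientations, skeleton + v-structure keys) so they can serve as
# oracles for the package's learners and CPDAG conversion.

binary_specs <- function(n, prefix = "X") {
  stats::setNames(lapply(seq_len(n), function(i) c("a", "b")),
                  paste0(prefix, seq_len(n)))
}

rand_dataset <- function(n, N, seed, arity = 2) {
  set.seed(seed)
  specs <- stats::setNames(
    lapply(seq_len(n), function(i) paste0("s", seq_len(arity))),
    paste0("X", seq_len(n)))
  bn_dataset(specs, matrix(sample.int(arity, N * n, replace = TRUE),
                           N, n))
}

# a random dataset with real dependence structure (sampled from a random
# sharpened network), more discriminating than iid noise
dependent_dataset <- function(n, N, seed) {
  set.seed(seed)
  nodes <- paste0("X", seq_len(n))
  edges <- matrix(character(0), 0, 2)
  if (n >= 2) for (j in 2:n) for (i in 1:(j - 1)) {
    if (stats::runif(1) < 0.4) edges <- rbind(edges, c(nodes[i], nodes[j]))
  }
  g <- bn_graph(nodes, edges)
  specs <- binary_specs(n)
  cpts <- lapply(nodes, function(v) {
    q <- 2^length(g$parents[[v]])
    p1 <- stats::runif(q, 0.1, 0.9)
    cbind(p1, 1 - p1)
  })
  names(cpts) <- nodes
  bn <- bn_network(g, specs, cpts)
  logic_sample(bn, N, seed = seed + 1)
}

# every labeled DAG on n nodes: each unordered pair absent / forward /
# backward, cyclic assignments discarded
all_dags <- function(n, nodes = paste0("X", seq_len(n))) {
  pairs <- utils::combn(n, 2)
  grid <- do.call(expand.grid, rep(list(0:2), ncol(pairs)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    edges <- matrix(character(0), 0, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (st[p] == 1) edges <- rbind(edges, c(nodes[i], nodes[j]))
      if (st[p] == 2) edges <- rbind(edges, c(nodes[j], nodes[i]))
    }
    g <- bn_graph(nodes, edges, check_acyclic = FALSE)
    if (is_acyclic(g)) out[[length(out) + 1]] <- g
  }
  out
}

# Markov-equivalence oracle: same skeleton and same v-structures
equivalence_key <- function(graph) {
  nodes <- graph$nodes
  adj <- function(u, v) has_edge(graph, u, v) || has_edge(graph, v, u)
  skel <- character(0)
  n <- length(nodes)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (adj(nodes[i], nodes[j]))
      skel <- c(skel, paste(nodes[i], nodes[j]))
  vs <- character(0)
  for (c in nodes) {
    ps <- graph$parents[[c]]
    if (length(ps) >= 2) {
      cmb <- utils::combn(sort(match(ps, nodes)), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- nodes[cmb[1, k]]; b <- nodes[cmb[2, k]]
        if (!adj(a, b)) vs <- c(vs, paste(a, b, "->", c))
      }
    }
  }
  paste(c(sort(skel), "|", sort(vs)), collapse = ";")
}

# canonical string of a CPDAG (pair states over declaration order)
cpdag_key <- function(graph) {
  p <- to_cpdag(graph)
  nodes <- p$nodes
  n <- length(nodes)
  states <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    states <- c(states,
                bnrecover:::pair_state_pdag(p, nodes[i], nodes[j]))
  paste(states, collapse = "")
}

# brute-force multinomial regret: literal sum over all k^N sequences of
# the maximized likelihood of each sequence
regret_brute <- function(N, k) {
  if (N == 0 || k == 1) return(1)
  idx <- rep(1L, N)
  total <- 0
  repeat {
    cnt <- tabulate(idx, nbins = k)
    ml <- prod((cnt[cnt > 0] / N)^cnt[cnt > 0])
    total <- total + ml
    p <- 1L
    while (p <= N) {
      idx[p] <- idx[p] + 1L
      if (idx[p] <= k) break
      idx[p] <- 1L
      p <- p + 1L
    }
    if (p > N) break
  }
  total
}
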