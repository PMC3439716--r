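#' Profile for a synthetic gold-standard network
#'
#' Describes the shape of a generating network: variable count, average
#' in-degree, arity range, and CPT randomness.  Profiles emulate the
#' published summaries of benchmark networks learned from small
#' real-world categorical datasets (5-25 variables, average in-degree
#' roughly 1.3-2.7, small arities).
#'
#' @param n Number of variables (5 to 25).
#' @param avg_in_degree Target average in-degree (edges / n), in
#'   `[0, 3]`.
#' @param arity_range Two integers: inclusive range of variable arities
#'   (each >= 2).
#' @param concentration Symmetric Dirichlet parameter for CPT rows.
#' @param sharpen In `[0, 1)`: fraction of each CPT row's mass moved onto
#'   one randomly chosen dominant state.  0 leaves plain Dirichlet rows;
#'   values near 1 make near-deterministic dependencies whose structure
#'   is recoverable at moderate sample sizes.
#' @param seed Integer seed.
#' @return Object of class `bn_gold_profile`.
#' @export
gold_profile <- function(n, avg_in_degree = 1.5, arity_range = c(2, 3),
                         concentration = 1.0, sharpen = 0, seed = 1) {
  if (n < 5 || n > 25) stop("n must be in [5, 25]")
  if (avg_in_degree < 0 || avg_in_degree > 3)
    stop("avg_in_degree must be in [0, 3]")
  if (length(arity_range) != 2 || arity_range[1] < 2 ||
      arity_range[2] < arity_range[1])
    stop("invalid arity_range")
  if (sharpen < 0 || sharpen >= 1) stop("sharpen must be in [0, 1)")
  structure(list(n = n, avg_in_degree = avg_in_degree,
                 arity_range = as.integer(arity_range),
                 concentration = concentration, sharpen = sharpen,
                 seed = as.integer(seed)),
            class = "bn_gold_profile")
}

#' Sample a gold-standard network from a profile
#'
#' Draws a random DAG by visiting the variables in a random order and
#' making each predecessor a parent independently with probability
#' `2 * avg_in_degree / (n - 1)` (so the expected average in-degree
#' matches the target), then fills every CPT row from a symmetric
#' Dirichlet, optionally sharpened toward a dominant state.
#' Reproducible from `profile$seed`.
#'
#' @param profile A `bn_gold_profile`.
#' @return A `bn_network`.
#' @export
random_gold_network <- function(profile) {
  with_seed(profile$seed, {
    n <- profile$n
    nodes <- sprintf("V%02d", seq_len(n))
    p <- min(1, 2 * profile$avg_in_degree / (n - 1))
    ord <- sample(nodes)
    edges <- matrix(character(0), 0, 2)
    if (n >= 2) for (t in 2:n) {
      sel <- ord[seq_len(t - 1)][stats::runif(t - 1) < p]
      if (length(sel))
        edges <- rbind(edges, cbind(sel, rep(ord[t], length(sel))))
    }
    build_random_network(nodes, edges, profile)
  })
}

# DAG with an exact edge count: random order, `edges` distinct
# forward pairs chosen uniformly
random_network_exact_edges <- function(n, n_edges, profile) {
  nodes <- sprintf("V%02d", seq_len(n))
  ord <- sample(nodes)
  pairs <- utils::combn(n, 2)
  pick <- sample.int(ncol(pairs), n_edges)
  edges <- cbind(ord[pairs[1, pick]], ord[pairs[2, pick]])
  build_random_network(nodes, edges, profile)
}

build_random_network <- function(nodes, edges, profile) {
  graph <- bn_graph(nodes, edges)
  ar <- sample(seq(profile$arity_range[1], profile$arity_range[2]),
               length(nodes), replace = TRUE)
  specs <- stats::setNames(
    lapply(seq_along(nodes), function(i) paste0("s", seq_len(ar[i]))),
    nodes)
  cpts <- lapply(nodes, function(v) {
    r <- ar[match(v, nodes)]
    q <- prod(ar[match(graph$parents[[v]], nodes)])
    rows <- matrix(stats::rgamma(q * r, shape = profile$concentration),
                   q, r)
    rows <- rows / rowSums(rows)
    if (profile$sharpen > 0) {
      dom <- sample.int(r, q, replace = TRUE)
      rows <- (1 - profile$sharpen) * rows
      rows[cbind(seq_len(q), dom)] <-
        rows[cbind(seq_len(q), dom)] + profile$sharpen
    }
    rows
  })
  names(cpts) <- nodes
  bn_network(graph, specs, cpts)
}

#' Forward (logic) sampling from a Bayesian network
#'
#' Generates `N` i.i.d. complete rows.  Variables are visited in a
#' topological order so every parent is sampled before its children;
#' each value is drawn from the variable's conditional distribution
#' given the already-sampled parent configuration.
#'
#' @param bn A `bn_network`.
#' @param N Number of rows (>= 0).
#' @param seed Integer seed.
#' @return A `bn_dataset` with columns in the network's declaration
#'   order.
#' @export
logic_sample <- function(bn, N, seed = 1) {
  nodes <- bn$graph$nodes
  ar <- arities(bn$specs)
  mat <- matrix(NA_integer_, N, length(nodes),
                dimnames = list(NULL, nodes))
  with_seed(seed, {
    for (v in topological_order(bn$graph)) {
      ps <- bn$graph$parents[[v]]
      cpt <- bn$cpts[[v]]
      if (N == 0) next
      j <- config_index(mat[, ps, drop = FALSE], ar[ps])
      col <- integer(N)
      for (jj in unique(j)) {
        idx <- which(j == jj)
        col[idx] <- sample.int(ar[[v]], length(idx), replace = TRUE,
                               prob = cpt[jj, ])
      }
      mat[, v] <- col
    }
  })
  bn_dataset(bn$specs, mat)
}

#' The study's sample-size grid
#'
#' 200 to 1000 in steps of 200, then 2000 to 10000 in steps of 1000:
#' 14 distinct sizes.
#' @return Strictly increasing integer vector.
#' @export
paper_sample_grid <- function() {
  c(seq(200L, 1000L, by = 200L), seq(2000L, 10000L, by = 1000L))
}

# (name, nodes, edges, average in-degree) profiles of the 13 benchmark
# networks learned from small real-world categorical datasets
benchmark_profiles <- function() {
  data.frame(
    name = c("austra_like", "breast_like", "car_like", "cleve_like",
             "crx_like", "diabetes_like", "glass_like", "heart_like",
             "hepatitis_like", "iris_like", "nursery_like",
             "vehicle_like", "voting_like"),
    nodes = c(15L, 10L, 7L, 14L, 16L, 9L, 10L, 14L, 20L, 5L, 9L, 19L,
              17L),
    edges = c(33L, 20L, 9L, 22L, 35L, 13L, 17L, 21L, 36L, 8L, 14L, 40L,
              46L),
    stringsAsFactors = FALSE)
}

#' Synthetic benchmark suite of 13 gold networks
#'
#' Generates 13 networks whose (node count, edge count) pairs match the
#' published benchmark summary exactly (e.g. a 5-node/8-edge iris-like
#' and a 17-node/46-edge voting-like network); CPTs are random, so these
#' are synthetic stand-ins, not the original networks.
#'
#' @param seed Integer seed.
#' @param sharpen Passed to the CPT generator (see [gold_profile()]).
#' @return Named list of `bn_network`s.
#' @export
benchmark_suite <- function(seed = 1, sharpen = 0) {
  prof <- benchmark_profiles()
  out <- list()
  for (i in seq_len(nrow(prof))) {
    p <- gold_profile(prof$nodes[i],
                      avg_in_degree = prof$edges[i] / prof$nodes[i],
                      sharpen = sharpen, seed = seed + i)
    out[[prof$name[i]]] <- with_seed(
      seed + i, random_network_exact_edges(prof$nodes[i], prof$edges[i],
                                           p))
  }
  out
}

#' Six-network recovery suite
#'
#' The fixed study conditions for the structure-recovery experiments:
#' networks of 5 to 10 variables with average in-degree 1.5, binary or
#' ternary variables, and sharpened CPTs (dominant-state mass 0.85) so
#' the generating structure is identifiable at moderate sample sizes.
#'
#' @param seed Integer seed.
#' @return Named list of 6 `bn_network`s.
#' @export
recovery_suite <- function(seed = 1) {
  out <- list()
  for (n in 5:10) {
    p <- gold_profile(n, avg_in_degree = 1.5, arity_range = c(2, 3),
                      sharpen = 0.85, seed = seed * 131L + n)
    out[[sprintf("net%02d", n)]] <- random_gold_network(p)
  }
  out
}
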