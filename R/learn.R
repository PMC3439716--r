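# Structure learners.  Variable subsets are encoded as integer bitmasks
# over the declaration order of the dataset's variables (bit i-1 <->
# variable i), so the exact learner's tables are flat vectors indexed by
# mask + 1.

popcount <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + (mask %% 2L)
    mask <- mask %/% 2L
  }
  n
}

mask_bits <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)

#' Precompute local scores for all candidate parent sets
#'
#' Builds the per-variable map from parent set to local score consumed by
#' both learners.  Sufficient statistics are computed once per parent set
#' and scored under every requested specification, so scanning several
#' scoring functions over one dataset costs one counting pass.
#'
#' @param data A `bn_dataset`.
#' @param spec A `bn_score_spec`, or a list of them.
#' @param max_parents Optional bound on parent-set size (`NULL` = none).
#' @param limit Refuse datasets with more variables than this (the table
#'   holds `2^(n-1)` entries per variable).
#' @return For a single spec, a `bn_score_table`: list with `nodes`,
#'   `spec`, and `scores` (per variable, a numeric vector indexed by
#'   parent-set bitmask + 1; `NA` where the set is excluded).  For a list
#'   of specs, a list of `bn_score_table`s.
#' @export
enumerate_local_scores <- function(data, spec, max_parents = NULL,
                                   limit = 16) {
  single <- inherits(spec, "bn_score_spec")
  specs <- if (single) list(spec) else spec
  nodes <- names(data$specs)
  n <- length(nodes)
  if (n > limit)
    stop("dataset has ", n, " variables, above the exact-learning limit (",
         limit, "); use hill_climb()")
  if (is.null(max_parents)) max_parents <- n - 1L
  size <- bitwShiftL(1L, n)
  pc <- vapply(0:(size - 1), popcount, integer(1))
  tabs <- lapply(specs, function(s)
    list(nodes = nodes, spec = s,
         scores = lapply(seq_len(n), function(i) rep(NA_real_, size))))
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(size - 1)) {
      if (bitwAnd(mask, bit) != 0L || pc[mask + 1] > max_parents) next
      cts <- build_counts(data, nodes[i],
                          if (mask > 0L) nodes[mask_bits(mask, n)]
                          else character(0))
      for (t in seq_along(specs))
        tabs[[t]]$scores[[i]][mask + 1] <- local_score(specs[[t]], cts)
    }
  }
  tabs <- lapply(tabs, function(t) structure(t, class = "bn_score_table"))
  if (single) tabs[[1]] else tabs
}

# Deterministic parent-set tie-break: higher score wins; ties prefer the
# smaller set, then the lexicographically smaller sorted index sequence.
prefer_set <- function(score_a, mask_a, score_b, mask_b, n, tol = 0) {
  if (score_a > score_b + tol) return(TRUE)
  if (score_b > score_a + tol) return(FALSE)
  pa <- popcount(mask_a); pb <- popcount(mask_b)
  if (pa != pb) return(pa < pb)
  if (mask_a == mask_b) return(TRUE)
  a <- mask_bits(mask_a, n); b <- mask_bits(mask_b, n)
  d <- which(a != b)[1]
  a[d] < b[d]
}

#' Best parent set within every candidate subset
#'
#' Dynamic program over subsets: the best score attainable for variable
#' `i` using parents drawn from a candidate set `C` is the better of
#' `C`'s own local score and the best over `C` minus one candidate.
#'
#' @param table A `bn_score_table`.
#' @param i Variable index (position in `table$nodes`).
#' @param candidates Character vector of candidate parents (excluding
#'   variable `i`).
#' @return List with `score` and `set` vectors indexed by `mask + 1` over
#'   subsets of `candidates` (masks in the global bit encoding), and the
#'   convenience fields `best_set` / `best_score` for the full candidate
#'   set.
#' @export
best_parents_dp <- function(table, i, candidates) {
  n <- length(table$nodes)
  if (table$nodes[i] %in% candidates) stop("candidates must exclude i")
  cidx <- match(candidates, table$nodes)
  cmask <- sum(bitwShiftL(1L, cidx - 1L))
  loc <- table$scores[[i]]
  size <- bitwShiftL(1L, n)
  score <- rep(NA_real_, size)
  set <- rep(NA_integer_, size)
  # enumerate submasks of cmask in increasing order
  subs <- Filter(function(m) bitwAnd(m, cmask) == m, 0:(size - 1))
  for (m in subs) {
    s <- loc[m + 1]
    best_s <- if (is.na(s)) -Inf else s
    best_m <- if (is.na(s)) NA_integer_ else m
    if (m > 0L) for (c in mask_bits(m, n)) {
      sub <- bitwAnd(m, bitwNot(bitwShiftL(1L, c - 1L)))
      cs <- score[sub + 1]; cm <- set[sub + 1]
      if (is.na(cm)) next
      if (is.na(best_m) ||
          !prefer_set(best_s, best_m, cs, cm, n)) {
        best_s <- cs; best_m <- cm
      }
    }
    score[m + 1] <- best_s
    set[m + 1] <- best_m
  }
  list(score = score, set = set,
       best_score = score[cmask + 1], best_set = set[cmask + 1])
}

new_learn_result <- function(graph, score, learner, spec, seed = NA) {
  structure(list(graph = graph, score = score, learner = learner,
                 spec = spec, seed = seed), class = "bn_learn_result")
}

#' @export
print.bn_learn_result <- function(x, ...) {
  cat("bn_learn_result [", x$learner, ", ", score_label(x$spec), "]: ",
      "score ", format(x$score), ", ", n_edges(x$graph), " edges\n",
      sep = "")
  invisible(x)
}

#' Globally optimal structure learning by dynamic programming
#'
#' Sink-based subset dynamic programming: the best network over a variable
#' subset `W` is the best, over choices of a sink `s` in `W`, of the best
#' network over `W \\ {s}` plus the best parent set for `s` drawn from
#' `W \\ {s}`.  Returns a DAG attaining the global maximum of the
#' decomposable network score; any optimal learner returns a network in
#' the same equivalence class.
#'
#' @param data A `bn_dataset`.
#' @param spec A `bn_score_spec`.
#' @param max_parents Optional parent-set size bound (bounds the search
#'   space; the result is optimal within the bound).
#' @param limit Maximum number of variables (memory grows as `2^n`).
#' @param score_table Optional precomputed `bn_score_table` for this spec
#'   (skips the counting pass).
#' @return A `bn_learn_result`.
#' @export
exact_learn <- function(data, spec, max_parents = NULL, limit = 16,
                        score_table = NULL) {
  nodes <- names(data$specs)
  n <- length(nodes)
  if (n > limit)
    stop("dataset has ", n, " variables, above the exact-learning limit (",
         limit, "); use hill_climb()")
  table <- if (is.null(score_table))
    enumerate_local_scores(data, spec, max_parents, limit) else score_table
  full <- bitwShiftL(1L, n) - 1L
  bp <- lapply(seq_len(n), function(i)
    best_parents_dp(table, i, nodes[-i]))
  size <- full + 1L
  best <- rep(NA_real_, size)
  sink <- rep(NA_integer_, size)
  best[1] <- 0
  for (m in 1:full) {
    bs <- -Inf; bsink <- NA_integer_
    for (s in mask_bits(m, n)) {
      rest <- bitwAnd(m, bitwNot(bitwShiftL(1L, s - 1L)))
      cand <- best[rest + 1] + bp[[s]]$score[rest + 1]
      if (is.na(cand) || !is.finite(cand)) next
      if (cand > bs + 1e-12 ||
          (abs(cand - bs) <= 1e-12 && (is.na(bsink) || s < bsink))) {
        bs <- cand; bsink <- s
      }
    }
    best[m + 1] <- bs
    sink[m + 1] <- bsink
  }
  # reconstruct edges by peeling sinks off the full set
  edges <- matrix(character(0), 0, 2)
  W <- full
  while (W > 0L) {
    s <- sink[W + 1]
    rest <- bitwAnd(W, bitwNot(bitwShiftL(1L, s - 1L)))
    pm <- bp[[s]]$set[rest + 1]
    if (pm > 0L)
      edges <- rbind(edges, cbind(nodes[mask_bits(pm, n)], nodes[s]))
    W <- rest
  }
  graph <- bn_graph(nodes, edges)
  new_learn_result(graph, best[full + 1], "exact", spec)
}

#' Exhaustive structure learning over all labeled DAGs
#'
#' Test oracle: enumerates every DAG on at most 5 variables (each
#' unordered pair is absent, forward, or backward; cyclic assignments are
#' discarded) and returns a maximizer, breaking ties toward fewer edges
#' and then the lexicographically smallest edge set.
#'
#' @param data A `bn_dataset`.
#' @param spec A `bn_score_spec`.
#' @export
brute_force_learn <- function(data, spec) {
  nodes <- names(data$specs)
  n <- length(nodes)
  if (n > 5) stop("brute_force_learn supports at most 5 variables")
  table <- enumerate_local_scores(data, spec)
  best_score <- -Inf
  best_pm <- NULL
  best_key <- NULL
  for (pm in all_dag_parent_masks(n)) {
    sc <- sum(vapply(seq_len(n), function(i)
      table$scores[[i]][pm[i] + 1], numeric(1)))
    if (sc > best_score + 1e-12) {
      best_score <- sc; best_pm <- pm; best_key <- NULL
    } else if (abs(sc - best_score) <= 1e-12) {
      if (is.null(best_key)) best_key <- dag_key(best_pm)
      key <- dag_key(pm)
      if (key_less(key, best_key)) {
        best_score <- sc; best_pm <- pm; best_key <- key
      }
    }
  }
  graph <- graph_from_parent_masks(nodes, best_pm)
  new_learn_result(graph, best_score, "brute", spec)
}

# enumerate parent-mask vectors of all DAGs on n labeled nodes
all_dag_parent_masks <- function(n) {
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), 2, 0)
  P <- ncol(pairs)
  out <- vector("list", 0)
  states <- rep(0L, P)
  repeat {
    pm <- rep(0L, n)
    for (p in seq_len(P)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (states[p] == 1L) pm[j] <- bitwOr(pm[j], bitwShiftL(1L, i - 1L))
      if (states[p] == 2L) pm[i] <- bitwOr(pm[i], bitwShiftL(1L, j - 1L))
    }
    if (parent_masks_acyclic(pm)) out[[length(out) + 1]] <- pm
    # advance mixed-radix counter
    p <- 1L
    while (p <= P) {
      states[p] <- states[p] + 1L
      if (states[p] < 3L) break
      states[p] <- 0L
      p <- p + 1L
    }
    if (p > P) break
  }
  out
}

parent_masks_acyclic <- function(pm) {
  n <- length(pm)
  removed <- 0L
  alive <- rep(TRUE, n)
  repeat {
    found <- FALSE
    for (i in which(alive)) {
      if (bitwAnd(pm[i], bitwNot(removed)) == 0L) {
        removed <- bitwOr(removed, bitwShiftL(1L, i - 1L))
        alive[i] <- FALSE
        found <- TRUE
      }
    }
    if (!any(alive)) return(TRUE)
    if (!found) return(FALSE)
  }
}

dag_key <- function(pm) {
  n <- length(pm)
  e <- integer(0)
  for (i in seq_len(n)) if (pm[i] > 0L)
    e <- c(e, (mask_bits(pm[i], n) - 1L) * n + (i - 1L))
  sort(e)
}
key_less <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

graph_from_parent_masks <- function(nodes, pm) {
  n <- length(nodes)
  edges <- matrix(character(0), 0, 2)
  for (i in seq_len(n)) if (pm[i] > 0L)
    edges <- rbind(edges, cbind(nodes[mask_bits(pm[i], n)], nodes[i]))
  bn_graph(nodes, edges)
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Greedy hill climbing with random restarts and a tabu list
#'
#' Steepest-ascent search over the operators add / delete / reverse
#' (acyclicity-preserving), accepting only strictly improving moves.  The
#' inverse of each accepted move is pushed onto a fixed-length tabu list
#' so the search cannot immediately undo itself.  Restart 0 starts from
#' the empty graph; later restarts start from random DAGs with edge
#' probability `2/n`.  Fully reproducible given `seed`.
#'
#' @param data A `bn_dataset`.
#' @param spec A `bn_score_spec`.
#' @param restarts Number of restarts (>= 1).
#' @param tabu_length Tabu list capacity.
#' @param max_no_improve Stop a restart after this many consecutive
#'   iterations without an improving move (with strict ascent the first
#'   such iteration already terminates the restart).
#' @param seed Integer RNG seed.
#' @param max_parents Optional parent-set size bound.
#' @return A `bn_learn_result` for the best structure found.
#' @export
hill_climb <- function(data, spec, restarts = 10, tabu_length = 100,
                       max_no_improve = 50, seed = 1, max_parents = NULL) {
  nodes <- names(data$specs)
  n <- length(nodes)
  if (is.null(max_parents)) max_parents <- n - 1L
  cache <- new.env(parent = emptyenv())
  lsc <- function(i, mask) {
    key <- paste0(i, "|", mask)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- local_score(spec, build_counts(
        data, nodes[i],
        if (mask > 0L) nodes[mask_bits(mask, n)] else character(0)))
      cache[[key]] <- val
    }
    val
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      pm <- if (r == 1) rep(0L, n) else random_parent_masks(n, 2 / n,
                                                            max_parents)
      res <- climb_one(pm, n, lsc, tabu_length, max_no_improve,
                       max_parents)
      if (is.null(best) || res$score > best$score + 1e-12) best <- res
    }
  })
  graph <- graph_from_parent_masks(nodes, best$pm)
  new_learn_result(graph, best$score, "greedy", spec, seed = seed)
}

# random DAG: random topological order, each earlier->later edge with
# probability p
random_parent_masks <- function(n, p, max_parents) {
  ord <- sample.int(n)
  pm <- rep(0L, n)
  if (n >= 2) for (t in 2:n) {
    v <- ord[t]
    preds <- ord[seq_len(t - 1)]
    sel <- preds[stats::runif(t - 1) < p]
    if (length(sel) > max_parents) sel <- sel[seq_len(max_parents)]
    pm[v] <- sum(bitwShiftL(1L, sel - 1L))
  }
  pm
}

climb_one <- function(pm, n, lsc, tabu_length, max_no_improve,
                      max_parents) {
  loc <- vapply(seq_len(n), function(i) lsc(i, pm[i]), numeric(1))
  tabu <- character(0)
  stalled <- 0L
  repeat {
    mv <- best_move(pm, n, loc, lsc, tabu, max_parents)
    if (is.null(mv) || mv$delta <= 1e-12) {
      # strict ascent: with no improving move the state cannot change,
      # so the first stalled iteration already ends the restart
      stalled <- stalled + 1L
      if (stalled >= min(1L, max_no_improve)) break
    } else {
      stalled <- 0L
      pm <- mv$pm
      loc <- mv$loc
      tabu <- c(mv$inverse, tabu)
      if (length(tabu) > tabu_length) tabu <- tabu[seq_len(tabu_length)]
    }
  }
  list(pm = pm, score = sum(loc))
}

# directed reachability u ~> v on parent masks
pm_has_path <- function(pm, n, from, to) {
  stack <- from
  seen <- rep(FALSE, n)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    kids <- which(vapply(seq_len(n), function(c)
      bitwAnd(pm[c], bitwShiftL(1L, v - 1L)) != 0L, logical(1)))
    stack <- c(kids, stack)
  }
  FALSE
}

best_move <- function(pm, n, loc, lsc, tabu, max_parents) {
  best <- NULL
  consider <- function(key, delta, new_pm, new_loc) {
    if (key %in% tabu) return()
    if (is.null(best) || delta > best$delta + 1e-12)
      best <<- list(delta = delta, pm = new_pm, loc = new_loc,
                    inverse = inverse_key(key))
  }
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    ubit <- bitwShiftL(1L, u - 1L)
    if (bitwAnd(pm[v], ubit) != 0L) {
      # delete u -> v
      m2 <- bitwAnd(pm[v], bitwNot(ubit))
      s2 <- lsc(v, m2)
      consider(paste0("del:", u, ">", v), s2 - loc[v],
               replace_at(pm, v, m2), replace_at(loc, v, s2))
      # reverse u -> v (legal iff no other path u ~> v)
      pm_del <- replace_at(pm, v, m2)
      if (!pm_has_path(pm_del, n, u, v) &&
          popcount(pm[u]) < max_parents) {
        m3 <- bitwOr(pm[u], bitwShiftL(1L, v - 1L))
        s3 <- lsc(u, m3)
        new_pm <- replace_at(pm_del, u, m3)
        new_loc <- replace_at(replace_at(loc, v, lsc(v, m2)), u, s3)
        consider(paste0("rev:", u, ">", v),
                 (lsc(v, m2) - loc[v]) + (s3 - loc[u]), new_pm, new_loc)
      }
    } else if (bitwAnd(pm[u], bitwShiftL(1L, v - 1L)) == 0L) {
      # add u -> v (legal iff no path v ~> u)
      if (popcount(pm[v]) >= max_parents) next
      if (pm_has_path(pm, n, v, u)) next
      m2 <- bitwOr(pm[v], ubit)
      s2 <- lsc(v, m2)
      consider(paste0("add:", u, ">", v), s2 - loc[v],
               replace_at(pm, v, m2), replace_at(loc, v, s2))
    }
  }
  best
}

replace_at <- function(x, i, val) { x[i] <- val; x }

inverse_key <- function(key) {
  parts <- strsplit(sub("^[a-z]+:", "", key), ">")[[1]]
  op <- sub(":.*", "", key)
  switch(op,
    add = paste0("del:", parts[1], ">", parts[2]),
    del = paste0("add:", parts[1], ">", parts[2]),
    rev = paste0("rev:", parts[2], ">", parts[1]))
}
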