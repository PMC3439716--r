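test_that("local score tables cover exactly the allowed parent sets", {
  d <- rand_dataset(3, 20, 1)
  tab <- enumerate_local_scores(d, score_spec("MDL"))
  for (i in 1:3)
    expect_equal(sum(!is.na(tab$scores[[i]])), 4)  # 2^(n-1) sets
  d5 <- rand_dataset(5, 20, 2)
  tab5 <- enumerate_local_scores(d5, score_spec("MDL"), max_parents = 1)
  for (i in 1:5)
    expect_equal(sum(!is.na(tab5$scores[[i]])), 5)  # empty + 4 singletons
  expect_error(enumerate_local_scores(rand_dataset(4, 10, 3),
                                      score_spec("MDL"), limit = 3),
               "hill_climb")
})

test_that("table entries agree with direct network score evaluation", {
  d <- dependent_dataset(4, 80, 41)
  nodes <- names(d$specs)
  specs <- list(score_spec("MDL"), score_spec("fNML"),
                score_spec("BDeu", alpha = 10))
  tabs <- enumerate_local_scores(d, specs)
  set.seed(42)
  dags <- all_dags(4, nodes)
  for (g in dags[sample.int(length(dags), 10)]) {
    for (t in seq_along(specs)) {
      from_table <- sum(vapply(seq_along(nodes), function(i) {
        mask <- sum(bitwShiftL(1L, match(g$parents[[nodes[i]]],
                                         nodes) - 1L))
        tabs[[t]]$scores[[i]][mask + 1]
      }, numeric(1)))
      expect_equal(from_table, network_score(specs[[t]], g, d))
    }
  }
})

test_that("best-parents DP matches an exhaustive subset scan", {
  d <- dependent_dataset(5, 60, 17)
  nodes <- names(d$specs)
  tab <- enumerate_local_scores(d, score_spec("MDL"))
  for (i in c(1, 3, 5)) {
    cand <- nodes[-i]
    bp <- best_parents_dp(tab, i, cand)
    # empty candidate set -> empty parent set
    expect_equal(best_parents_dp(tab, i, character(0))$best_set, 0L)
    cmask <- sum(bitwShiftL(1L, match(cand, nodes) - 1L))
    subs <- Filter(function(m) bitwAnd(m, cmask) == m,
                   0:(2^length(nodes) - 1))
    prev <- -Inf
    for (m in sort(subs)) {
      # exhaustive: best local score over all parent sets within m
      inner <- Filter(function(p) bitwAnd(p, m) == p, subs)
      exh <- max(vapply(inner, function(p)
        tab$scores[[i]][p + 1], numeric(1)))
      expect_equal(bp$score[m + 1], exh)
      # monotone in the candidate set (along the enumeration of supersets)
      if (m == cmask) expect_gte(bp$score[m + 1], prev)
      prev <- max(prev, bp$score[m + 1])
    }
  }
})

test_that("exact learner returns the global optimum", {
  # iid uniform variables: the penalty dominates, empty graph is optimal
  d <- rand_dataset(4, 1000, 7)
  r <- exact_learn(d, score_spec("MDL"))
  expect_equal(n_edges(r$graph), 0)
  b <- brute_force_learn(d, score_spec("MDL"))
  expect_equal(r$score, b$score)
  # strong pairwise dependence: learned structure is in the gold class
  specs <- binary_specs(2)
  bn <- bn_network(
    bn_graph(c("X1", "X2"), rbind(c("X1", "X2"))), specs,
    list(X1 = matrix(c(0.5, 0.5), 1),
         X2 = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)))
  d2 <- logic_sample(bn, 1000, seed = 19)
  r2 <- exact_learn(d2, score_spec("MDL"))
  expect_equal(shd(bn$graph, r2$graph)$shd, 0)
  expect_equal(r2$score, brute_force_learn(d2, score_spec("MDL"))$score)
  # reported score always re-evaluates correctly
  expect_equal(r2$score, network_score(score_spec("MDL"), r2$graph, d2))
})

test_that("exact score is invariant to variable permutation", {
  for (s in 1:3) {
    d <- dependent_dataset(4, 150, s + 50)
    perm <- sample(names(d$specs))
    d_perm <- bn_dataset(d$specs[perm], d$data[, perm])
    for (spec in list(score_spec("MDL"), score_spec("fNML")))
      expect_equal(exact_learn(d, spec)$score,
                   exact_learn(d_perm, spec)$score, tolerance = 1e-9)
  }
})

test_that("brute force enumerates the labeled-DAG counts", {
  expect_equal(length(bnrecover:::all_dag_parent_masks(3)), 25)
  expect_equal(length(bnrecover:::all_dag_parent_masks(4)), 543)
  d1 <- rand_dataset(1, 10, 1)
  r1 <- brute_force_learn(d1, score_spec("MDL"))
  expect_equal(n_edges(r1$graph), 0)
  expect_equal(r1$score,
               local_score(score_spec("MDL"), build_counts(d1, "X1")))
  expect_error(brute_force_learn(rand_dataset(6, 10, 1),
                                 score_spec("MDL")), "at most 5")
})

test_that("hill climbing is deterministic, bounded by exact, and ascends", {
  # data from an independent generator: once the move-scan oracle
  # confirms no single-edge addition improves MDL, the climber must
  # return the empty graph from any seed
  spec <- score_spec("MDL")
  for (s in 1:10) {
    d <- rand_dataset(4, 500, s)
    nodes <- names(d$specs)
    empty_scores <- vapply(nodes, function(v)
      local_score(spec, build_counts(d, v)), numeric(1))
    improving <- FALSE
    for (u in nodes) for (v in nodes) {
      if (u == v) next
      if (local_score(spec, build_counts(d, v, u)) >
          empty_scores[[v]] + 1e-12) improving <- TRUE
    }
    if (improving) next
    for (seed in c(1, 5)) {
      h <- hill_climb(d, spec, seed = seed)
      expect_equal(n_edges(h$graph), 0)
    }
  }
  for (s in 1:4) {
    d <- dependent_dataset(5, 300, s + 60)
    spec <- score_spec("MDL")
    h1 <- hill_climb(d, spec, seed = s)
    h2 <- hill_climb(d, spec, seed = s)
    expect_identical(h1$graph, h2$graph)
    expect_equal(h1$score, h2$score)
    e <- exact_learn(d, spec)
    expect_lte(h1$score, e$score + 1e-9)
    expect_equal(h1$score, network_score(spec, h1$graph, d))
  }
})

test_that("greedy search attains the exact optimum on most small fixtures", {
  hits <- 0
  for (s in 1:8) {
    d <- dependent_dataset(5, 400, s + 200)
    spec <- score_spec("MDL")
    e <- exact_learn(d, spec)
    h <- hill_climb(d, spec, seed = s)
    expect_lte(h$score, e$score + 1e-9)
    if (abs(h$score - e$score) < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
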