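test_that("count tables tally rows in mixed-radix parent order", {
  specs <- binary_specs(1)
  d <- bn_dataset(specs, cbind(X1 = c(1, 1, 2, 1)))
  ct <- build_counts(d, "X1")
  expect_equal(ct$nij, 4)
  expect_equal(unname(ct$counts), matrix(c(3, 1), 1))
  # hand-checked 6-row parent/child fixture
  specs2 <- binary_specs(2)
  d2 <- bn_dataset(specs2, cbind(X1 = c(1, 1, 1, 2, 2, 2),
                                 X2 = c(1, 2, 1, 2, 2, 2)))
  ct2 <- build_counts(d2, "X2", "X1")
  expect_equal(unname(ct2$counts), rbind(c(2, 1), c(0, 3)))
  expect_equal(ct2$q, 2)
  expect_equal(ct2$r, 2)
  # unobserved parent configuration stays at zero
  specs3 <- list(X1 = c("a", "b"), X2 = c("a", "b"), X3 = c("a", "b"))
  d3 <- bn_dataset(specs3, cbind(X1 = c(1, 1), X2 = c(1, 2),
                                 X3 = c(1, 1)))
  ct3 <- build_counts(d3, "X3", c("X1", "X2"))
  expect_equal(ct3$nij, c(1, 1, 0, 0))
  expect_error(build_counts(d3, "X1", "X1"), "own parent")
})

test_that("local log-likelihood follows the frequency form", {
  specs <- binary_specs(1)
  d <- bn_dataset(specs, cbind(X1 = c(1, 1, 1, 2)))
  expect_equal(log_likelihood_local(build_counts(d, "X1")),
               3 * log(0.75) + log(0.25))
  d2 <- bn_dataset(specs, cbind(X1 = rep(1, 4)))
  expect_equal(log_likelihood_local(build_counts(d2, "X1")), 0)
  # empty slice contributes nothing
  d3 <- bn_dataset(specs, matrix(integer(0), 0, 1,
                                 dimnames = list(NULL, "X1")))
  expect_equal(log_likelihood_local(build_counts(d3, "X1")), 0)
})

test_that("parameter counts and penalties follow the free-parameter convention", {
  specs <- list(X1 = c("a", "b"), X2 = c("a", "b", "c"),
                X3 = c("a", "b"), X4 = c("a", "b", "c"))
  d <- bn_dataset(specs, matrix(1L, 2, 4,
                                dimnames = list(NULL, names(specs))))
  expect_equal(num_params(build_counts(d, "X1")), 1)
  expect_equal(num_params(build_counts(d, "X2", c("X1", "X3"))), 2 * 4)
  expect_equal(num_params(build_counts(d, "X1", c("X2", "X4"))), 1 * 9)
  expect_equal(penalty_mdl(1, 100), log(100) / 2)
  expect_equal(penalty_mdl(0, 50), 0)
  expect_equal(penalty_mdl(7, 1), 0)
  expect_equal(penalty_aic(8), 8)
  # above N = e^2 the MDL penalty exceeds the AIC penalty
  expect_gt(penalty_mdl(3, 9), penalty_aic(3))
})

test_that("BDeu local score matches the predictive-chain oracle", {
  specs <- binary_specs(1)
  d1 <- bn_dataset(specs, cbind(X1 = 1L))
  expect_equal(bdeu_local(build_counts(d1, "X1"), 1), log(0.5))
  # sequential predictive product for counts (1,1), alpha = 1:
  # P = 1/2 * (1/2)/(1+1) = 1/8
  d2 <- bn_dataset(specs, cbind(X1 = c(1L, 2L)))
  expect_equal(bdeu_local(build_counts(d2, "X1"), 1), log(1 / 8))
  # general oracle: random counts, alpha, arity
  set.seed(5)
  for (rep in 1:10) {
    r <- sample(2:4, 1)
    n <- sample(1:6, 1)
    alpha <- sample(c(0.5, 1, 5), 1)
    xs <- sample.int(r, n, replace = TRUE)
    sp <- list(X1 = paste0("s", 1:r))
    d <- bn_dataset(sp, cbind(X1 = xs))
    # predictive chain: prod over observations of
    # (alpha/r + #seen) / (alpha + t - 1)
    seen <- rep(0, r)
    logp <- 0
    for (t in seq_along(xs)) {
      logp <- logp + log((alpha / r + seen[xs[t]]) / (alpha + t - 1))
      seen[xs[t]] <- seen[xs[t]] + 1
    }
    expect_equal(bdeu_local(build_counts(d, "X1"), alpha), logp)
  }
  d0 <- bn_dataset(specs, matrix(integer(0), 0, 1,
                                 dimnames = list(NULL, "X1")))
  expect_equal(bdeu_local(build_counts(d0, "X1"), 1), 0)
  expect_error(bdeu_local(build_counts(d1, "X1"), 0), "positive")
})

test_that("multinomial regret matches enumeration and grows in N and k", {
  expect_equal(multinomial_regret(17, 1), 0)
  expect_equal(multinomial_regret(0, 5), 0)
  expect_equal(exp(multinomial_regret(1, 2)), 2)
  expect_equal(exp(multinomial_regret(2, 3)), 4.5)
  for (N in 1:5) for (k in 2:4)
    expect_equal(exp(multinomial_regret(N, k)), regret_brute(N, k))
  # nondecreasing in both arguments
  grid <- expand.grid(N = c(1, 5, 20, 100), k = 2:6)
  vals <- mapply(multinomial_regret, grid$N, grid$k)
  for (k in 2:6) {
    v <- vals[grid$k == k]
    expect_true(all(diff(v) >= -1e-12))
  }
  for (N in c(1, 5, 20, 100)) {
    v <- vals[grid$N == N]
    expect_true(all(diff(v) >= -1e-12))
  }
  # numerically stable at large N
  expect_true(is.finite(multinomial_regret(100000, 4)))
})

test_that("fNML equals slice-wise NML computed by brute force", {
  specs <- binary_specs(1)
  d <- bn_dataset(specs, cbind(X1 = 1L))
  expect_equal(fnml_local(build_counts(d, "X1")), -log(2))
  d0 <- bn_dataset(specs, matrix(integer(0), 0, 1,
                                 dimnames = list(NULL, "X1")))
  expect_equal(fnml_local(build_counts(d0, "X1")), 0)
  # slices of a parent-conditioned table, N_ij <= 4, r <= 3
  set.seed(13)
  for (rep in 1:8) {
    r <- sample(2:3, 1)
    sp <- list(P = c("a", "b"), X = paste0("s", 1:r))
    n <- sample(2:8, 1)
    rows <- cbind(P = sample.int(2, n, replace = TRUE),
                  X = sample.int(r, n, replace = TRUE))
    d <- bn_dataset(sp, rows)
    ct <- build_counts(d, "X", "P")
    expected <- 0
    for (j in 1:2) {
      nij <- ct$nij[j]
      if (nij == 0) next
      cnt <- ct$counts[j, ]
      ml <- prod((cnt[cnt > 0] / nij)^cnt[cnt > 0])
      expected <- expected + log(ml / regret_brute(nij, r))
    }
    expect_equal(fnml_local(ct), expected)
  }
})

test_that("network scores decompose and favour dependence-capturing arcs", {
  d <- dependent_dataset(3, 200, 31)
  spec <- score_spec("MDL")
  g0 <- bn_graph(names(d$specs))
  expect_equal(network_score(spec, g0, d),
               sum(vapply(names(d$specs), function(v)
                 local_score(spec, build_counts(d, v)), numeric(1))))
  # adding an arc never decreases the likelihood component
  set.seed(77)
  for (rep in 1:10) {
    d <- dependent_dataset(4, 100, rep)
    nodes <- names(d$specs)
    dags <- all_dags(4, nodes)
    g <- dags[[sample.int(length(dags), 1)]]
    ll <- function(gr) sum(vapply(nodes, function(v)
      log_likelihood_local(build_counts(d, v, gr$parents[[v]])),
      numeric(1)))
    # pick a random absent, acyclicity-safe arc
    for (u in nodes) for (v in nodes) {
      if (u != v && !has_edge(g, u, v) && !has_edge(g, v, u) &&
          !has_path(g, v, u)) {
        expect_gte(ll(bnrecover:::add_edge(g, u, v)), ll(g) - 1e-9)
      }
    }
  }
})

test_that("scores are invariant to row order and state relabelling", {
  for (s in 1:5) {
    d <- rand_dataset(3, 40, s, arity = 3)
    specs <- list(score_spec("MDL"), score_spec("AIC"),
                  score_spec("fNML"), score_spec("BDeu", alpha = 5))
    g <- bn_graph(names(d$specs),
                  rbind(c("X1", "X2"), c("X3", "X2")))
    set.seed(s)
    perm <- sample.int(nrow(d$data))
    d_shuf <- bn_dataset(d$specs, d$data[perm, ])
    # relabel X2's states by a permutation
    rel <- sample.int(3)
    d_rel <- d
    d_rel$data[, "X2"] <- rel[d$data[, "X2"]]
    d_rel <- bn_dataset(d$specs, d_rel$data)
    for (spec in specs) {
      base <- network_score(spec, g, d)
      expect_equal(network_score(spec, g, d_shuf), base)
      expect_equal(network_score(spec, g, d_rel), base)
    }
  }
})

test_that("MDL and BDeu assign equal scores to X->Y and X<-Y", {
  for (s in 1:5) {
    d <- dependent_dataset(2, 60, s + 100)
    nodes <- names(d$specs)
    fwd <- bn_graph(nodes, rbind(c(nodes[1], nodes[2])))
    rev <- bn_graph(nodes, rbind(c(nodes[2], nodes[1])))
    for (spec in list(score_spec("MDL"), score_spec("AIC"),
                      score_spec("BDeu", alpha = 1)))
      expect_equal(network_score(spec, fwd, d),
                   network_score(spec, rev, d), tolerance = 1e-10)
  }
})
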