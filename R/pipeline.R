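#' The full score grid of the study
#'
#' MDL, AIC, fNML, and BDeu at the nine equivalent sample sizes
#' 0.1, 0.5, 1, 5, 10, 20, 50, 80, 100 — twelve specifications in all,
#' matching "12 optimal networks per dataset and sample size".
#'
#' @return List of `bn_score_spec`s.
#' @export
full_score_grid <- function() {
  c(list(score_spec("MDL"), score_spec("AIC"), score_spec("fNML")),
    lapply(c(0.1, 0.5, 1, 5, 10, 20, 50, 80, 100),
           function(a) score_spec("BDeu", alpha = a)))
}

#' Experiment configuration
#'
#' Declares every moving part of a recovery experiment: which gold
#' networks, the sample-size grid, replicate count, score
#' specifications, learners, and a base seed from which every per-cell
#' seed is derived deterministically.  The configuration round-trips
#' losslessly through YAML.
#'
#' @param suite `"recovery"` (six networks, 5-10 variables, sharpened
#'   CPTs) or `"benchmark"` (13 networks matching the published
#'   node/edge profiles).
#' @param suite_seed Seed for the suite generator.
#' @param suite_sharpen CPT sharpening for the benchmark suite.
#' @param sizes Strictly increasing sample sizes.
#' @param replicates Independent datasets per (network, size).
#' @param base_seed Base RNG seed.
#' @param specs List of `bn_score_spec`s.
#' @param learners Character subset of `c("exact", "greedy")`.
#' @param max_parents Optional parent-set bound passed to the learners.
#' @param greedy Options list for the hill climber
#'   (`restarts`, `tabu_length`, `max_no_improve`).
#' @return Object of class `bn_experiment_config`.
#' @export
experiment_config <- function(suite = c("recovery", "benchmark"),
                              suite_seed = 1, suite_sharpen = 0.85,
                              sizes = paper_sample_grid(),
                              replicates = 1, base_seed = 1,
                              specs = full_score_grid(),
                              learners = "exact",
                              max_parents = NULL,
                              greedy = list(restarts = 10,
                                            tabu_length = 100,
                                            max_no_improve = 50)) {
  suite <- match.arg(suite)
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0) || any(sizes < 1))
    stop("sizes must be strictly increasing positive integers")
  if (!all(learners %in% c("exact", "greedy")))
    stop("learners must be a subset of c('exact', 'greedy')")
  structure(list(suite = suite, suite_seed = as.integer(suite_seed),
                 suite_sharpen = suite_sharpen, sizes = sizes,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), specs = specs,
                 learners = learners, max_parents = max_parents,
                 greedy = greedy),
            class = "bn_experiment_config")
}

#' Write / read an experiment configuration as YAML
#' @param config A `bn_experiment_config`.
#' @param path File path.
#' @export
write_experiment_config <- function(config, path) {
  obj <- unclass(config)
  obj$specs <- lapply(config$specs, function(s)
    if (is.null(s$alpha)) list(family = s$family)
    else list(family = s$family, alpha = s$alpha))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$specs <- lapply(obj$specs, function(s)
    score_spec(s$family, alpha = s$alpha))
  do.call(experiment_config,
          c(list(suite = obj$suite, suite_seed = obj$suite_seed,
                 suite_sharpen = obj$suite_sharpen, sizes = obj$sizes,
                 replicates = obj$replicates,
                 base_seed = obj$base_seed, specs = obj$specs,
                 learners = obj$learners,
                 max_parents = obj$max_parents),
            list(greedy = obj$greedy)))
}

config_networks <- function(config) {
  switch(config$suite,
         recovery = recovery_suite(config$suite_seed),
         benchmark = benchmark_suite(config$suite_seed,
                                     sharpen = config$suite_sharpen))
}

# deterministic per-cell seed, kept inside 32-bit integer range
cell_seed <- function(base, net_i, size_i, rep) {
  as.integer((as.double(base) * 2654435 + net_i * 40503 +
                size_i * 1327 + rep * 97) %% 2147483629)
}

#' Run a full recovery experiment
#'
#' For every gold network, sample size, and replicate: draw a dataset by
#' logic sampling, learn a structure under every (score, learner)
#' combination, and evaluate it against the gold network with accuracy,
#' sensitivity, AHD, and SHD (with its add/delete/rev/mis
#' decomposition).  Counting passes are shared across score
#' specifications for the exact learner.  Learner capability errors are
#' recorded in the `error` column of the affected rows, not raised.
#'
#' @param config A `bn_experiment_config`.
#' @param networks Optional named list of `bn_network`s overriding the
#'   configured suite.
#' @param quiet Suppress per-network progress messages.
#' @return Data frame of metric records, one row per
#'   (gold, size, replicate, learner, score).
#' @export
run_experiment <- function(config, networks = NULL, quiet = TRUE) {
  if (is.null(networks)) networks <- config_networks(config)
  rows <- list()
  for (net_i in seq_along(networks)) {
    gname <- names(networks)[net_i]
    bn <- networks[[net_i]]
    if (!quiet) message("network ", gname)
    for (size_i in seq_along(config$sizes)) {
      N <- config$sizes[size_i]
      for (rep in seq_len(config$replicates)) {
        seed <- cell_seed(config$base_seed, net_i, size_i, rep)
        data <- logic_sample(bn, N, seed = seed)
        tables <- NULL
        for (learner in config$learners) {
          if (learner == "exact") {
            tables <- tryCatch(
              enumerate_local_scores(data, config$specs,
                                     max_parents = config$max_parents),
              error = function(e) e)
          }
          for (spec_i in seq_along(config$specs)) {
            spec <- config$specs[[spec_i]]
            res <- tryCatch({
              if (learner == "exact") {
                if (inherits(tables, "error")) stop(tables$message)
                exact_learn(data, spec,
                            max_parents = config$max_parents,
                            score_table = tables[[spec_i]])
              } else {
                hill_climb(data, spec,
                           restarts = config$greedy$restarts,
                           tabu_length = config$greedy$tabu_length,
                           max_no_improve = config$greedy$max_no_improve,
                           seed = seed + spec_i,
                           max_parents = config$max_parents)
              }
            }, error = function(e) e)
            rows[[length(rows) + 1]] <-
              metric_record(gname, learner, spec, N, rep, seed,
                            bn$graph, res)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

metric_record <- function(gold, learner, spec, N, rep, seed, gold_graph,
                          res) {
  base <- data.frame(gold = gold, learner = learner,
                     family = spec$family,
                     alpha = if (is.null(spec$alpha)) NA_real_
                             else spec$alpha,
                     score_label = score_label(spec), size = N,
                     replicate = rep, seed = seed,
                     stringsAsFactors = FALSE)
  if (inherits(res, "error")) {
    return(cbind(base, data.frame(
      score = NA_real_, accuracy = NA_real_, sensitivity = NA_real_,
      ahd = NA_real_, shd = NA_integer_, add = NA_integer_,
      delete = NA_integer_, rev = NA_integer_, mis = NA_integer_,
      n_edges = NA_integer_, error = conditionMessage(res))))
  }
  conf <- edge_confusion(gold_graph, res$graph)
  d <- shd(gold_graph, res$graph)
  cbind(base, data.frame(
    score = res$score, accuracy = accuracy(conf),
    sensitivity = sensitivity(conf), ahd = ahd(conf), shd = d$shd,
    add = d$add, delete = d$delete, rev = d$rev, mis = d$mis,
    n_edges = n_edges(res$graph), error = NA_character_))
}

#' Summarize SHD across the sample-size grid
#'
#' Per (gold network, learner, score specification): replicates are
#' averaged within each sample size first, then the Min, Mean, Max, and
#' population standard deviation are taken across the grid — the layout
#' of the study's summary tables.
#'
#' @param records Output of [run_experiment()].
#' @return Data frame with columns `gold`, `learner`, `score_label`,
#'   `min`, `mean`, `max`, `std`.
#' @export
summarize_shd <- function(records) {
  records <- records[is.na(records$error), , drop = FALSE]
  if (nrow(records) == 0) stop("no successful records to summarize")
  by_size <- stats::aggregate(
    shd ~ gold + learner + score_label + size, records, mean)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- do.call(rbind, by(by_size, list(
    by_size$gold, by_size$learner, by_size$score_label), function(d) {
      data.frame(gold = d$gold[1], learner = d$learner[1],
                 score_label = d$score_label[1],
                 min = min(d$shd), mean = mean(d$shd),
                 max = max(d$shd), std = pop_sd(d$shd),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$gold, out$learner, out$score_label), , drop = FALSE]
}

#' Convergence of a metric series over increasing sample sizes
#'
#' A series has converged when adding more data no longer changes the
#' value: the call reports the smallest grid position from which the
#' series is constant to the end.  A series whose last two entries
#' differ has not converged.
#'
#' @param values Metric values aligned to the size grid.
#' @param sizes Optional sizes; when given, `at` is reported as a size
#'   rather than a position.
#' @return `list(converged =, at =)`; `at` is `NA` when not converged.
#' @export
detect_convergence <- function(values, sizes = NULL) {
  m <- length(values)
  if (m == 0) stop("empty series")
  i <- m
  while (i > 1 && values[i - 1] == values[m]) i <- i - 1
  converged <- i < m || m == 1
  if (m > 1 && values[m] != values[m - 1]) converged <- FALSE
  if (m == 1) converged <- TRUE
  at <- if (!converged) NA else if (is.null(sizes)) i else sizes[i]
  list(converged = converged, at = at)
}
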