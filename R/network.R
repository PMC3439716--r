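#' Categorical dataset
#'
#' Complete discrete data table: an `N x n` integer matrix of 1-based state
#' indices plus per-variable state labels.  Columns follow the declaration
#' order of `specs`.
#'
#' @param specs Named list: variable name -> character vector of state
#'   labels (each variable needs at least 2 unique labels to carry signal,
#'   but arity 1 is tolerated for intermediate products).
#' @param rows Integer matrix (or data frame) of 1-based state indices,
#'   one column per variable in `specs` order.
#' @return Object of class `bn_dataset` with elements `specs` and `data`.
#' @export
bn_dataset <- function(specs, rows) {
  if (is.null(names(specs)) || anyDuplicated(names(specs)))
    stop("specs must be a uniquely named list")
  for (v in names(specs)) {
    st <- specs[[v]]
    if (anyDuplicated(st)) stop("duplicate state labels for ", v)
  }
  rows <- as.matrix(rows)
  storage.mode(rows) <- "integer"
  if (ncol(rows) != length(specs))
    stop("row width does not match number of variables")
  colnames(rows) <- names(specs)
  ar <- arities(specs)
  if (nrow(rows) > 0) {
    if (anyNA(rows)) stop("missing entries not allowed")
    for (i in seq_along(specs)) {
      if (any(rows[, i] < 1L | rows[, i] > ar[i]))
        stop("state index out of range for ", names(specs)[i])
    }
  }
  structure(list(specs = specs, data = rows), class = "bn_dataset")
}

arities <- function(specs) vapply(specs, length, integer(1))

#' @export
print.bn_dataset <- function(x, ...) {
  cat("bn_dataset:", nrow(x$data), "rows,", length(x$specs), "variables (",
      paste(names(x$specs), collapse = ", "), ")\n")
  invisible(x)
}

#' Discrete Bayesian network
#'
#' A pair of a DAG and conditional probability tables.  The CPT of a
#' variable with arity `r` and parent arities `a1..am` is a `q x r` matrix
#' with `q = prod(a)` rows, one per parent configuration in mixed-radix
#' order (first-declared parent most significant), each row a distribution
#' over the variable's states.
#'
#' @param graph A `bn_graph`.
#' @param specs Named list of state-label vectors (declaration order must
#'   match `graph$nodes`).
#' @param cpts Named list of CPT matrices.
#' @return Object of class `bn_network`.
#' @export
bn_network <- function(graph, specs, cpts) {
  if (!identical(graph$nodes, names(specs)))
    stop("specs must be named by graph nodes, in the same order")
  ar <- arities(specs)
  for (v in graph$nodes) {
    cpt <- as.matrix(cpts[[v]])
    q <- prod(ar[graph$parents[[v]]])
    if (nrow(cpt) != q || ncol(cpt) != ar[[v]])
      stop("CPT for ", v, " must be ", q, " x ", ar[[v]])
    if (any(cpt < 0 | cpt > 1)) stop("CPT entries outside [0,1] for ", v)
    if (any(abs(rowSums(cpt) - 1) > 1e-9))
      stop("CPT rows for ", v, " must sum to 1")
    dimnames(cpt) <- list(NULL, specs[[v]])
    cpts[[v]] <- cpt
  }
  structure(list(graph = graph, specs = specs, cpts = cpts[graph$nodes]),
            class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  cat("bn_network:", length(x$graph$nodes), "variables,",
      n_edges(x$graph), "edges\n")
  invisible(x)
}

# Mixed-radix parent-configuration index, 1-based; first parent most
# significant.  `state_cols`: matrix of 1-based state indices, one column
# per parent; `ar`: parent arities.  Zero parents -> all rows map to 1.
config_index <- function(state_cols, ar) {
  n <- if (is.matrix(state_cols)) nrow(state_cols) else length(state_cols)
  if (length(ar) == 0) return(rep(1L, n))
  state_cols <- as.matrix(state_cols)
  w <- rev(cumprod(rev(c(ar[-1], 1))))
  as.integer((state_cols - 1L) %*% w) + 1L
}

#' Joint log-probability of a complete instantiation
#'
#' The log of the factored joint \eqn{\prod_i P(x_i | pa_i)}, in nats.
#'
#' @param bn A `bn_network`.
#' @param instance Named vector covering every variable: either 1-based
#'   integer state indices or character state labels.
#' @return Sum of log CPT factors; `-Inf` if any factor is exactly zero.
#' @export
joint_log_probability <- function(bn, instance) {
  nodes <- bn$graph$nodes
  if (is.character(instance)) {
    idx <- mapply(function(v, val) match(val, bn$specs[[v]]),
                  nodes, instance[nodes])
  } else {
    idx <- as.integer(instance[nodes])
  }
  names(idx) <- nodes
  ar <- arities(bn$specs)
  if (anyNA(idx) || any(idx < 1L | idx > ar[nodes]))
    stop("instance assigns an invalid state")
  total <- 0
  for (v in nodes) {
    ps <- bn$graph$parents[[v]]
    j <- config_index(matrix(idx[ps], nrow = 1), ar[ps])
    p <- unname(bn$cpts[[v]][j, idx[[v]]])
    if (p == 0) return(-Inf)
    total <- total + log(p)
  }
  total
}

#' Maximum-likelihood CPT estimation
#'
#' Fills each CPT row with observed frequencies `N_ijk / N_ij`.  Parent
#' configurations never observed in the data get the uniform distribution,
#' which keeps downstream sampling well-defined.
#'
#' @param graph A `bn_graph` over the dataset's variables.
#' @param data A `bn_dataset`.
#' @return A `bn_network` on `graph` with fitted CPTs.
#' @export
fit_mle <- function(graph, data) {
  if (!setequal(graph$nodes, names(data$specs)))
    stop("graph nodes must match dataset variables")
  specs <- data$specs[graph$nodes]
  ar <- arities(specs)
  cpts <- list()
  for (v in graph$nodes) {
    ps <- graph$parents[[v]]
    counts <- count_matrix(data$data, v, ps, ar)
    tot <- rowSums(counts)
    cpt <- counts / ifelse(tot == 0, 1, tot)
    cpt[tot == 0, ] <- 1 / ar[[v]]
    cpts[[v]] <- cpt
  }
  bn_network(graph, specs, cpts)
}

# q x r count matrix for variable v under parent set ps
count_matrix <- function(mat, v, ps, ar) {
  q <- prod(ar[ps])
  r <- ar[[v]]
  if (nrow(mat) == 0) return(matrix(0, q, r))
  j <- config_index(mat[, ps, drop = FALSE], ar[ps])
  cell <- (j - 1L) * r + mat[, v]
  matrix(tabulate(cell, nbins = q * r), nrow = q, ncol = r, byrow = TRUE)
}

#' Read / write networks as JSON
#'
#' Format: `{"variables":[{"name","states":[...]}], "edges":[[p,c],...],
#' "cpts":{"var":[[row],...]}}` with CPT rows in mixed-radix parent order.
#' Probabilities are written at full precision so a write/read round-trip
#' is bit-exact.
#'
#' @param bn A `bn_network`.
#' @param path File path.
#' @return `read_network_json` returns a `bn_network`.
#' @export
write_network_json <- function(bn, path) {
  e <- graph_edges(bn$graph)
  obj <- list(
    variables = lapply(bn$graph$nodes, function(v)
      list(name = v, states = as.list(bn$specs[[v]]))),
    edges = if (nrow(e)) lapply(seq_len(nrow(e)), function(r)
      list(e[r, 1], e[r, 2])) else list(),
    cpts = lapply(bn$cpts, function(cpt)
      lapply(seq_len(nrow(cpt)), function(j) as.vector(cpt[j, ])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  specs <- stats::setNames(
    lapply(obj$variables, function(v) unlist(v$states)),
    vapply(obj$variables, function(v) v$name, character(1)))
  edges <- if (length(obj$edges))
    do.call(rbind, lapply(obj$edges, function(e) c(e[[1]], e[[2]])))
  graph <- bn_graph(names(specs), edges)
  cpts <- lapply(obj$cpts, function(rows)
    do.call(rbind, lapply(rows, unlist)))
  bn_network(graph, specs, cpts)
}

#' Read / write datasets as CSV of state labels
#'
#' Header row of variable names; cells are state labels, mapped to indices
#' through `specs`.  When `specs` is `NULL` the reader infers each
#' variable's states as the sorted unique labels observed.
#'
#' @param data A `bn_dataset`.
#' @param path File path.
#' @param specs Optional named list of state-label vectors.
#' @export
write_dataset_csv <- function(data, path) {
  lab <- vapply(seq_along(data$specs), function(i)
    data$specs[[i]][data$data[, i]], character(nrow(data$data)))
  if (nrow(data$data) == 1) lab <- matrix(lab, nrow = 1)
  colnames(lab) <- names(data$specs)
  utils::write.csv(as.data.frame(lab), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, specs = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  if (is.null(specs))
    specs <- lapply(df, function(col) sort(unique(col)))
  rows <- vapply(names(specs), function(v) {
    idx <- match(df[[v]], specs[[v]])
    if (anyNA(idx)) stop("label not in spec for ", v)
    idx
  }, integer(nrow(df)))
  if (nrow(df) == 1) rows <- matrix(rows, nrow = 1,
                                    dimnames = list(NULL, names(specs)))
  bn_dataset(specs, rows)
}
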