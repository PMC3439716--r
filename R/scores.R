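#' Score specification
#'
#' Selects one of the four decomposable penalized log-likelihood scoring
#' families.  All scores are "larger is better" and in nats; MDL is the
#' negated description length, which makes it identical to BIC.
#'
#' @param family One of `"MDL"`, `"AIC"`, `"BDeu"`, `"fNML"`.
#' @param alpha Equivalent sample size, required (and only allowed) for
#'   BDeu; must be positive.
#' @return Object of class `bn_score_spec`.
#' @examples
#' score_spec("MDL")
#' score_spec("BDeu", alpha = 1)
#' @export
score_spec <- function(family = c("MDL", "AIC", "BDeu", "fNML"),
                       alpha = NULL) {
  family <- match.arg(family)
  if (family == "BDeu") {
    if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0)
      stop("BDeu requires a positive equivalent sample size alpha")
  } else if (!is.null(alpha)) {
    stop("alpha is only meaningful for BDeu")
  }
  structure(list(family = family, alpha = alpha), class = "bn_score_spec")
}

#' @export
print.bn_score_spec <- function(x, ...) {
  cat(score_label(x), "\n")
  invisible(x)
}

#' Short label for a score specification
#' @param spec A `bn_score_spec`.
#' @export
score_label <- function(spec) {
  if (spec$family == "BDeu") paste0("BDeu(alpha=", spec$alpha, ")")
  else spec$family
}

#' Sufficient statistics for one variable under one parent set
#'
#' Tallies, in a single pass, the number of rows with each (parent
#' configuration, state) combination.  Parent configurations are indexed
#' in mixed-radix order with the first-declared parent most significant.
#'
#' @param data A `bn_dataset`.
#' @param variable Variable name.
#' @param parents Character vector of parent names (may be empty).
#' @return Object of class `bn_counts`: `variable`, `parents`, `q`
#'   (number of parent configurations), `r` (variable arity), `counts`
#'   (`q x r` integer matrix, `N_ijk`), `nij` (row sums, `N_ij`), `N`.
#' @export
build_counts <- function(data, variable, parents = character(0)) {
  if (variable %in% parents) stop("variable cannot be its own parent")
  ar <- arities(data$specs)
  parents <- sort_by_declaration(parents, names(data$specs))
  counts <- count_matrix(data$data, variable, parents, ar)
  structure(list(variable = variable, parents = parents,
                 q = nrow(counts), r = ncol(counts),
                 counts = counts, nij = rowSums(counts),
                 N = nrow(data$data)),
            class = "bn_counts")
}

#' Local multinomial log-likelihood
#'
#' \eqn{\sum_j \sum_k N_{ijk} \log(N_{ijk}/N_{ij})} in nats, with
#' \eqn{0 \log 0 = 0}; never positive.
#'
#' @param counts A `bn_counts`.
#' @export
log_likelihood_local <- function(counts) {
  cm <- counts$counts
  nz <- cm > 0
  if (!any(nz)) return(0)
  nij <- counts$nij[row(cm)[nz]]
  sum(cm[nz] * (log(cm[nz]) - log(nij)))
}

#' Free-parameter count of a local multinomial family
#'
#' `(r - 1) * q` free parameters: each of the `q` parent configurations
#' holds a distribution over `r` states.
#'
#' @param counts A `bn_counts`.
#' @export
num_params <- function(counts) (counts$r - 1L) * counts$q

#' MDL / BIC penalty for one variable
#'
#' `log(N)/2` nats per free parameter; the local MDL score is the local
#' log-likelihood minus this penalty.
#'
#' @param p Free-parameter count.
#' @param N Dataset size (>= 1).
#' @export
penalty_mdl <- function(p, N) {
  if (N < 1) stop("N must be >= 1")
  log(N) / 2 * p
}

#' AIC penalty for one variable
#'
#' One nat per free parameter.
#' @param p Free-parameter count.
#' @export
penalty_aic <- function(p) p

#' BDeu local score
#'
#' Log marginal likelihood of the variable's data slice under symmetric
#' Dirichlet priors distributing an equivalent sample size `alpha` evenly:
#' configuration pseudo-count `alpha/q` and cell pseudo-count
#' `alpha/(r*q)`.
#'
#' @param counts A `bn_counts`.
#' @param alpha Positive equivalent sample size.
#' @export
bdeu_local <- function(counts, alpha) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  aj <- alpha / counts$q
  ajk <- alpha / (counts$r * counts$q)
  sum(lgamma(aj) - lgamma(aj + counts$nij)) +
    sum(lgamma(ajk + counts$counts) - lgamma(ajk))
}

# package-local cache: key = as.character(N), value = numeric vector of
# log C_N^k for k = 1..len
.regret_cache <- new.env(parent = emptyenv())

#' Multinomial regret (parametric complexity), in log-space
#'
#' Natural log of the normalized-maximum-likelihood normalizer
#' \eqn{C_N^k}: the sum over all `k`-ary datasets of size `N` of their
#' maximized likelihoods.  `C_N^1 = 1` and `C_0^k = 1`; the binary case is
#' the exact binomial sum (evaluated by log-sum-exp), and larger `k` use
#' the linear recurrence \eqn{C_N^{k+2} = C_N^{k+1} + (N/k) C_N^k}.
#' Stable for `N` up to at least `1e5`.
#'
#' @param N Number of observations (>= 0).
#' @param k Number of states (>= 1).
#' @return `log(C_N^k)`.
#' @examples
#' exp(multinomial_regret(1, 2))  # 2
#' @export
multinomial_regret <- function(N, k) {
  if (N < 0 || k < 1) stop("require N >= 0, k >= 1")
  if (N == 0 || k == 1) return(0)
  key <- as.character(N)
  row <- if (!is.null(.regret_cache[[key]])) .regret_cache[[key]] else
    numeric(0)
  if (length(row) >= k) return(row[k])
  if (length(row) < 2) {
    h <- 0:N
    terms <- lchoose(N, h) +
      ifelse(h == 0, 0, h * log(h / N)) +
      ifelse(h == N, 0, (N - h) * log((N - h) / N))
    row <- c(0, logsumexp(terms))
  }
  while (length(row) < k) {
    j <- length(row)  # computing entry j+1 = (j-1)+2
    row <- c(row, logaddexp(row[j], log(N) - log(j - 1) + row[j - 1]))
  }
  .regret_cache[[key]] <- row
  row[k]
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

#' fNML local score
#'
#' Factorized normalized maximum likelihood: the local log-likelihood
#' minus one multinomial regret term per parent configuration,
#' \eqn{\sum_j \log C_{N_{ij}}^{r}}.
#'
#' @param counts A `bn_counts`.
#' @export
fnml_local <- function(counts) {
  pen <- sum(vapply(counts$nij, multinomial_regret, numeric(1),
                    k = counts$r))
  log_likelihood_local(counts) - pen
}

#' Local score under a score specification
#'
#' @param spec A `bn_score_spec`.
#' @param counts A `bn_counts`.
#' @return Local score in nats (larger is better).
#' @export
local_score <- function(spec, counts) {
  switch(spec$family,
    MDL = log_likelihood_local(counts) -
      penalty_mdl(num_params(counts), counts$N),
    AIC = log_likelihood_local(counts) - penalty_aic(num_params(counts)),
    BDeu = bdeu_local(counts, spec$alpha),
    fNML = fnml_local(counts))
}

#' Decomposable network score
#'
#' Sum of local scores of each variable given its parents in `graph`.
#'
#' @param spec A `bn_score_spec`.
#' @param graph An acyclic `bn_graph` over the dataset's variables.
#' @param data A `bn_dataset`.
#' @export
network_score <- function(spec, graph, data) {
  sum(vapply(graph$nodes, function(v)
    local_score(spec, build_counts(data, v, graph$parents[[v]])),
    numeric(1)))
}
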