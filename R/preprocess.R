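#' Raw mixed-type table
#'
#' Pre-discretization container: a data frame whose columns are declared
#' continuous or categorical, with missing cells as `NA` and a designated
#' categorical class column (the supervision signal for discretization).
#'
#' @param df Data frame; continuous columns numeric, categorical columns
#'   character.
#' @param kinds Named character vector mapping every column to
#'   `"continuous"` or `"categorical"`.
#' @param class_column Name of the class column (must be categorical).
#' @return Object of class `bn_raw_table`.
#' @export
raw_table <- function(df, kinds, class_column) {
  if (!setequal(names(df), names(kinds)))
    stop("kinds must name every column")
  if (!all(kinds %in% c("continuous", "categorical")))
    stop("kinds must be 'continuous' or 'categorical'")
  if (!(class_column %in% names(df)) ||
      kinds[[class_column]] != "categorical")
    stop("class_column must exist and be categorical")
  for (cn in names(df)) {
    if (kinds[[cn]] == "continuous") {
      df[[cn]] <- as.numeric(df[[cn]])
      if (any(!is.finite(df[[cn]]) & !is.na(df[[cn]])))
        stop("non-finite continuous value in ", cn)
    } else {
      df[[cn]] <- as.character(df[[cn]])
    }
  }
  structure(list(df = df, kinds = kinds[names(df)],
                 class_column = class_column),
            class = "bn_raw_table")
}

#' Read a raw table from CSV plus a YAML sidecar
#'
#' The CSV uses `?` as the missing-value sentinel.  The sidecar declares
#' column kinds and the class column:
#' `columns: {age: continuous, ...}` and `class_column: outcome`.
#'
#' @param csv_path CSV file path.
#' @param yaml_path YAML sidecar path.
#' @export
read_raw_table <- function(csv_path, yaml_path) {
  meta <- yaml::read_yaml(yaml_path)
  df <- utils::read.csv(csv_path, colClasses = "character",
                        check.names = FALSE, na.strings = "?")
  raw_table(df, unlist(meta$columns), meta$class_column)
}

#' Shannon entropy of a label multiset, in bits
#'
#' \eqn{-\sum_c p_c \log_2 p_c} with \eqn{0 \log 0 = 0}.
#'
#' @param labels Non-empty vector of class labels.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) stop("entropy of an empty set is undefined")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Best binary cut of a numeric column under class supervision
#'
#' Scans the midpoints between consecutive distinct sorted values and
#' returns the boundary `T` minimizing the size-weighted entropy
#' `E = (|S1|/|S|) Ent(S1) + (|S2|/|S|) Ent(S2)`, ties broken toward the
#' smaller `T`.
#'
#' @param values Numeric column (>= 2 rows for a cut to exist).
#' @param labels Class labels aligned with `values`.
#' @return `list(T =, E =)` or `NULL` when all values are identical.
#' @export
best_cut <- function(values, labels) {
  o <- order(values)
  v <- values[o]
  l <- labels[o]
  dv <- sort(unique(v))
  if (length(dv) < 2) return(NULL)
  cuts <- (dv[-length(dv)] + dv[-1]) / 2
  n <- length(v)
  best <- NULL
  for (T in cuts) {
    left <- v <= T
    E <- sum(left) / n * entropy(l[left]) +
      sum(!left) / n * entropy(l[!left])
    if (is.null(best) || E < best$E - 1e-12) best <- list(T = T, E = E)
  }
  best
}

#' MDL stopping rule for recursive discretization
#'
#' Accepts a binary split when the information gain
#' `Ent(S) - E(S1, S2)` strictly exceeds the encoding cost
#' `log2(|S|-1)/|S| + Delta/|S|` with
#' `Delta = log2(3^k - 2) - [k Ent(S) - k1 Ent(S1) - k2 Ent(S2)]`,
#' where `k`, `k1`, `k2` count the distinct class labels in each set.
#'
#' @param s,s1,s2 Class-label vectors; `s` is the concatenation of the
#'   two parts.
#' @return `TRUE` to accept the split.
#' @export
mdlp_accept <- function(s, s1, s2) {
  n <- length(s)
  if (n < 2) return(FALSE)
  ent <- entropy(s)
  e1 <- entropy(s1)
  e2 <- entropy(s2)
  gain <- ent - (length(s1) / n * e1 + length(s2) / n * e2)
  k <- length(unique(s))
  k1 <- length(unique(s1))
  k2 <- length(unique(s2))
  delta <- log2(3^k - 2) - (k * ent - k1 * e1 - k2 * e2)
  gain > log2(n - 1) / n + delta / n
}

#' Supervised MDLP discretization of a numeric column
#'
#' Recursively applies [best_cut()] and keeps each split only while
#' [mdlp_accept()] holds; segments then recurse independently.  Returns
#' the strictly increasing cut points; a column that earns no cut (for
#' example a constant column, or one uninformative about the class)
#' returns an empty vector.
#'
#' @param values Numeric column.
#' @param labels Class labels aligned with `values`.
#' @return Numeric vector of cut points (possibly empty).
#' @export
discretize_mdlp <- function(values, labels) {
  if (length(values) < 2) return(numeric(0))
  cut <- best_cut(values, labels)
  if (is.null(cut)) return(numeric(0))
  left <- values <= cut$T
  if (!mdlp_accept(labels, labels[left], labels[!left]))
    return(numeric(0))
  sort(c(discretize_mdlp(values[left], labels[left]),
         cut$T,
         discretize_mdlp(values[!left], labels[!left])))
}

#' Bin a numeric column by cut points
#'
#' @param values Numeric vector.
#' @param cuts Strictly increasing cut points (value <= cut goes left).
#' @return Integer bin indices in `1..(length(cuts) + 1)`.
#' @export
apply_cuts <- function(values, cuts) {
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' k-nearest-neighbour imputation of missing cells
#'
#' For each record with missing cells, finds the `k` closest fully
#' observed records by Euclidean distance over min-max-scaled continuous
#' columns plus 0/1 mismatch on categorical columns, computed over the
#' columns the record has observed and excluding the column being
#' imputed.  Continuous targets receive the neighbour mean, categorical
#' targets the neighbour majority vote with ties broken toward the
#' smallest state index (states in sorted label order).
#'
#' @param table A `bn_raw_table`.
#' @param k Neighbour count (default 5).
#' @return A `bn_raw_table` with no missing cells; observed cells are
#'   never altered.
#' @export
knn_impute <- function(table, k = 5) {
  df <- table$df
  complete <- stats::complete.cases(df)
  if (!any(!complete)) return(table)
  if (sum(complete) < k)
    stop("need at least k = ", k, " complete records, have ",
         sum(complete))
  cont <- names(df)[table$kinds == "continuous"]
  rng <- lapply(df[cont], function(x) {
    r <- range(x, na.rm = TRUE)
    if (r[1] == r[2]) r[2] <- r[1] + 1  # constant column: zero spread
    r
  })
  scaled <- df
  for (cn in cont)
    scaled[[cn]] <- (df[[cn]] - rng[[cn]][1]) /
      (rng[[cn]][2] - rng[[cn]][1])
  donors <- which(complete)
  for (i in which(!complete)) {
    missing_cols <- names(df)[is.na(df[i, ])]
    for (target in missing_cols) {
      feat <- setdiff(names(df)[!is.na(df[i, ])], target)
      d2 <- numeric(length(donors))
      for (cn in feat) {
        if (table$kinds[[cn]] == "continuous") {
          d2 <- d2 + (scaled[[cn]][donors] - scaled[[cn]][i])^2
        } else {
          d2 <- d2 + (scaled[[cn]][donors] != scaled[[cn]][i])
        }
      }
      nb <- donors[order(d2)[seq_len(k)]]
      if (table$kinds[[target]] == "continuous") {
        df[i, target] <- mean(df[[target]][nb])
      } else {
        states <- sort(unique(df[[target]][complete]))
        votes <- tabulate(match(df[[target]][nb], states),
                          nbins = length(states))
        df[i, target] <- states[which.max(votes)]
      }
    }
  }
  raw_table(df, table$kinds, table$class_column)
}

#' Turn a raw table into a complete categorical dataset
#'
#' Imputes missing cells first (so distances are computed on raw
#' values), then discretizes every continuous column against the class
#' column with MDLP.  Continuous columns that earn no cut are
#' single-state and dropped from modelling with a warning; surviving
#' bins are labelled `bin0..binK` left to right.  Categorical columns
#' keep their labels (states in sorted order).
#'
#' @param table A `bn_raw_table`.
#' @param k Imputation neighbour count.
#' @return List with `data` (a `bn_dataset`), `cuts` (named list of cut
#'   vectors per continuous column), and `dropped` (names of discarded
#'   columns).
#' @export
preprocess_table <- function(table, k = 5) {
  table <- knn_impute(table, k = k)
  df <- table$df
  cls <- df[[table$class_column]]
  specs <- list()
  cols <- list()
  cuts <- list()
  dropped <- character(0)
  for (cn in names(df)) {
    if (table$kinds[[cn]] == "continuous") {
      cp <- discretize_mdlp(df[[cn]], cls)
      cuts[[cn]] <- cp
      if (length(cp) == 0) {
        dropped <- c(dropped, cn)
        warning("column ", cn,
                " earned no MDLP cut; dropped from modelling")
        next
      }
      specs[[cn]] <- paste0("bin", seq_len(length(cp) + 1) - 1)
      cols[[cn]] <- apply_cuts(df[[cn]], cp)
    } else {
      st <- sort(unique(df[[cn]]))
      specs[[cn]] <- st
      cols[[cn]] <- match(df[[cn]], st)
    }
  }
  rows <- do.call(cbind, cols)
  list(data = bn_dataset(specs, rows), cuts = cuts, dropped = dropped)
}

#' Persist discretization cut points as JSON
#' @param cuts Named list of numeric cut vectors.
#' @param path Output path.
#' @export
write_cutpoints_json <- function(cuts, path) {
  jsonlite::write_json(lapply(cuts, as.vector), path, digits = NA)
  invisible(path)
}
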