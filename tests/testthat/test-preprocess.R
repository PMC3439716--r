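test_that("entropy matches the closed form in bits", {
  expect_equal(entropy(c("A", "A", "B", "B")), 1.0)
  expect_equal(entropy(c("A", "A", "A")), 0.0)
  expect_equal(entropy(c("A", "A", "A", "B")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(entropy(character(0)), "empty")
})

test_that("best_cut minimizes weighted entropy with smallest-T ties", {
  r <- best_cut(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(r$T, 2.5)
  expect_equal(r$E, 0)
  expect_null(best_cut(c(3, 3, 3), c("A", "B", "A")))
  # all candidate cuts tie at E = 0 on a pure set: smallest T wins
  r2 <- best_cut(c(1, 2), c("A", "A"))
  expect_equal(r2$T, 1.5)
  expect_equal(r2$E, 0)
})

test_that("the MDL stopping rule accepts informative splits only", {
  s <- c("A", "A", "B", "B")
  expect_true(mdlp_accept(s, c("A", "A"), c("B", "B")))
  # pure parent set: zero gain can never exceed the threshold
  expect_false(mdlp_accept(c("A", "A", "A", "A"), c("A", "A"),
                           c("A", "A")))
  # two-point split: Gain = 1 exceeds threshold (log2(1) + log2(7) - 2)/2
  expect_true(mdlp_accept(c("A", "B"), "A", "B"))
})

test_that("recursive discretization stops on pure or constant segments", {
  expect_equal(discretize_mdlp(c(1, 2, 3, 4), c("A", "A", "B", "B")),
               2.5)
  expect_equal(discretize_mdlp(rep(2, 6), c("A", "B", "A", "B", "A", "B")),
               numeric(0))
  expect_equal(discretize_mdlp(1:6, rep("A", 6)), numeric(0))
})

test_that("discretization is invariant to monotone transformations", {
  set.seed(21)
  for (rep in 1:5) {
    v <- stats::rnorm(60)
    lab <- ifelse(v + stats::rnorm(60, sd = 0.3) > 0, "hi", "lo")
    cuts <- discretize_mdlp(v, lab)
    cuts_t <- discretize_mdlp(exp(v), lab)
    expect_equal(length(cuts), length(cuts_t))
    expect_identical(apply_cuts(v, cuts), apply_cuts(exp(v), cuts_t))
    # every bin non-empty on the training column
    if (length(cuts))
      expect_true(all(tabulate(apply_cuts(v, cuts),
                               length(cuts) + 1) > 0))
  }
})

test_that("information gain of any binary split is nonnegative", {
  set.seed(4)
  for (rep in 1:10) {
    lab <- sample(c("A", "B", "C"), 20, replace = TRUE)
    cut <- sample(2:18, 1)
    e <- entropy(lab)
    ew <- cut / 20 * entropy(lab[1:cut]) +
      (20 - cut) / 20 * entropy(lab[(cut + 1):20])
    expect_gte(e, ew - 1e-12)
  }
})

make_raw <- function(df) {
  kinds <- vapply(df, function(col)
    if (is.numeric(col)) "continuous" else "categorical", character(1))
  raw_table(df, kinds, class_column = names(df)[length(df)])
}

test_that("kNN imputation votes, averages, and preserves observed cells", {
  df <- data.frame(
    x = c(1, 2, 3, 4, 5, NA),
    g = c("b", "b", "b", "b", "b", "b"),
    cls = c("p", "p", "p", "q", "q", "q"),
    stringsAsFactors = FALSE)
  out <- knn_impute(make_raw(df), k = 5)
  expect_equal(out$df$x[6], mean(1:5))  # neighbour mean
  df2 <- data.frame(
    x = c(1, 1.1, 0.9, 1.05, 0.95, 1),
    g = c("b", "b", "b", "b", "b", NA),
    cls = c("p", "p", "p", "p", "p", "p"),
    stringsAsFactors = FALSE)
  out2 <- knn_impute(make_raw(df2), k = 5)
  expect_equal(out2$df$g[6], "b")  # unanimous vote
  # complete table returned unchanged; observed cells never altered
  expect_identical(knn_impute(out2, k = 5)$df, out2$df)
  expect_identical(out$df$x[1:5], df$x[1:5])
  short <- df[c(1, 2, 3, 6), ]  # one missing cell, three complete donors
  expect_error(knn_impute(make_raw(short), k = 5), "complete")
})

test_that("preprocessing imputes, discretizes, and drops inert columns", {
  set.seed(8)
  n <- 80
  sig <- c(stats::rnorm(n / 2, -2), stats::rnorm(n / 2, 2))
  noise <- rep(1.5, n)  # constant: earns no cut
  cls <- rep(c("neg", "pos"), each = n / 2)
  df <- data.frame(sig = sig, noise = noise, cls = cls,
                   stringsAsFactors = FALSE)
  df$sig[3] <- NA
  expect_warning(res <- preprocess_table(make_raw(df)), "no MDLP cut")
  expect_identical(res$dropped, "noise")
  expect_true(length(res$cuts$sig) >= 1)
  expect_identical(names(res$data$specs), c("sig", "cls"))
  expect_true(all(startsWith(res$data$specs$sig, "bin")))
  expect_equal(nrow(res$data$data), n)
})

test_that("raw tables load from CSV with ? sentinel and YAML sidecar", {
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("age,outcome", "1.5,p", "?,q", "2.5,p"), csv)
  writeLines(c("columns:", "  age: continuous",
               "  outcome: categorical", "class_column: outcome"), yml)
  tab <- read_raw_table(csv, yml)
  expect_true(is.na(tab$df$age[2]))
  expect_identical(tab$kinds[["age"]], "continuous")
  expect_identical(tab$class_column, "outcome")
  # cut points persist as JSON
  p <- tempfile(fileext = ".json")
  write_cutpoints_json(list(age = c(1.25, 2)), p)
  expect_equal(jsonlite::read_json(p, simplifyVector = TRUE)$age,
               c(1.25, 2))
})
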