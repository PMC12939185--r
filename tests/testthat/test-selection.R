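test_that("Z-score normalization centers training data and never refits", {
  set.seed(1)
  train <- matrix(rnorm(200, 5, 3), 20, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
  z <- zscore_fit_apply(train, train + 10)
  expect_lt(max(abs(colMeans(z$train))), 1e-12)
  expect_lt(max(abs(apply(z$train, 2, sd) - 1)), 1e-12)
  # the shifted table is transformed with training parameters: means land at
  # +10 / sd, not at 0
  expect_equal(colMeans(z$others[[1]]), 10 / z$state$sd, tolerance = 1e-10)
})

test_that("constant features are flagged and excluded from selection", {
  set.seed(2)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("f", 1:10)))
  x[, 4] <- 2
  z <- zscore_fit_apply(x)
  expect_true(z$state$constant[4])
  expect_false(any(z$state$constant[-4]))
  y <- rep(c(0L, 1L), 15)
  sel <- lasso_select(x, y, seed = 1)
  expect_identical(sel$constant_features, "f4")
  expect_false("f4" %in% sel$retained_after_lasso)
})

test_that("LASSO retains an informative feature and shrinks everything at huge penalty", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 200
    y <- rep(c(0L, 1L), n / 2)
    x <- cbind(signal = y + rnorm(n, 0, 0.1),
               matrix(rnorm(n * 20), n, 20,
                      dimnames = list(NULL, paste0("noise", 1:20))))
    x <- scale(x)
    sel <- lasso_select(x, y, seed = s)
    if ("signal" %in% sel$retained_after_lasso) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  # penalty forced to the top of the grid: empty retention
  set.seed(3)
  x <- scale(matrix(rnorm(400), 40, 10, dimnames = list(NULL, paste0("f", 1:10))))
  sel0 <- lasso_select(x, rep(c(0L, 1L), 20), seed = 1, lambda = c(10, 9.9))
  expect_length(sel0$retained_after_lasso, 0L)
  expect_length(sel0$final_features, 0L)
})

test_that("a duplicated informative feature keeps at least one copy", {
  kept <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    y <- rep(c(0L, 1L), n / 2)
    base <- y + rnorm(n, 0, 0.1)
    x <- scale(cbind(dup1 = base, dup2 = base + rnorm(n, 0, 0.01),
                     matrix(rnorm(n * 10), n, 10,
                            dimnames = list(NULL, paste0("noise", 1:10)))))
    sel <- lasso_select(x, y, seed = s)
    if (any(c("dup1", "dup2") %in% sel$retained_after_lasso)) kept <- kept + 1L
  }
  expect_identical(kept, 20L)
})

test_that("selection errors on degenerate labels", {
  x <- matrix(rnorm(100), 10, 10)
  expect_error(lasso_select(x, rep(1L, 10)), "both classes")
  expect_error(lasso_select(x, c(1L, rep(0L, 9))), "2 subjects per class")
})

test_that("Spearman matrix honors rank invariance", {
  set.seed(4)
  x <- runif(50)
  m <- spearman_matrix(cbind(a = x, b = exp(3 * x), c = rev(sort(x))[rank(x)]))
  expect_equal(m["a", "b"], 1)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
  # reversing order flips the sign
  m2 <- spearman_matrix(cbind(a = x, rev_a = -x))
  expect_equal(m2["a", "rev_a"], -1)
  # independent columns have small correlations at n = 1000
  set.seed(5)
  m3 <- spearman_matrix(matrix(runif(4000), 1000, 4))
  expect_lt(max(abs(m3[upper.tri(m3)])), 0.1)
  expect_warning(spearman_matrix(cbind(a = x, const = rep(1, 50))), "constant")
  expect_error(spearman_matrix(matrix(1:4, 2, 2)), "3 rows")
})

test_that("correlation pruning removes the smaller-range member above 0.8", {
  mk_rho <- function(ab) {
    rho <- diag(2)
    dimnames(rho) <- list(c("a", "b"), c("a", "b"))
    rho["a", "b"] <- rho["b", "a"] <- ab
    rho
  }
  x_raw <- cbind(a = c(0, 5), b = c(0, 2))  # ranges 5 vs 2
  out <- correlation_prune(c("a", "b"), mk_rho(0.9), x_raw)
  expect_identical(out$final_features, "a")
  expect_identical(out$pruned$feature, "b")
  # strict threshold: 0.79 keeps both
  out2 <- correlation_prune(c("a", "b"), mk_rho(0.79), x_raw)
  expect_identical(out2$final_features, c("a", "b"))
  expect_identical(nrow(out2$pruned), 0L)
})

test_that("a mutually correlated triple collapses to its largest-range member", {
  rho <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(rho) <- 1
  rho["a", "b"] <- rho["b", "a"] <- 0.95
  rho["a", "c"] <- rho["c", "a"] <- 0.9
  rho["b", "c"] <- rho["c", "b"] <- 0.85
  x_raw <- cbind(a = c(0, 3), b = c(0, 2), c = c(0, 1))
  out <- correlation_prune(c("a", "b", "c"), rho, x_raw)
  expect_identical(out$final_features, "a")
  # idempotence
  again <- correlation_prune(out$final_features, rho, x_raw)
  expect_identical(again$final_features, out$final_features)
  # empty input gives empty output, no error
  expect_identical(correlation_prune(character(0), rho, x_raw)$final_features,
                   character(0))
})

test_that("retention probabilities are counts over cycles", {
  feats <- scx_feature_names()
  records <- c(rep(list(feats[1]), 150),
               rep(list(feats[1:2]), 0))
  records <- lapply(1:150, function(i) {
    out <- feats[1]
    if (i <= 75) out <- c(out, feats[2])
    out
  })
  rp <- retention_probabilities(records)
  expect_equal(rp[[feats[1]]], 1.0)
  expect_equal(rp[[feats[2]]], 0.5)
  expect_equal(rp[[feats[10]]], 0.0)
  expect_true(all(diff(rp) <= 0))  # sorted descending
  expect_error(retention_probabilities(list()), "at least one")
})

test_that("selection state is a pure function of the training fold", {
  set.seed(6)
  x <- matrix(rnorm(600), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(0L, 1L), 15)
  other1 <- matrix(rnorm(200), 10, 20)
  other2 <- matrix(runif(200, -50, 50), 10, 20)
  z1 <- zscore_fit_apply(x, other1)
  z2 <- zscore_fit_apply(x, other2)
  expect_identical(z1$state, z2$state)
  expect_identical(z1$train, z2$train)
  s1 <- lasso_select(z1$train, y, seed = 5)
  s2 <- lasso_select(z2$train, y, seed = 5)
  expect_identical(s1, s2)
})
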