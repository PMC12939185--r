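test_that("stratified folds preserve class proportions and partition subjects", {
  y <- c(rep(0L, 60), rep(1L, 40))
  f <- stratified_kfold(y, 5, seed = 1)
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f == k), 20L)
    expect_identical(sum(f == k & y == 0), 12L)
    expect_identical(sum(f == k & y == 1), 8L)
  }
  # partition: union is everyone, folds disjoint by construction of a vector
  expect_identical(length(f), length(y))
  expect_identical(stratified_kfold(y, 5, seed = 1), f)  # deterministic
  expect_false(identical(stratified_kfold(y, 5, seed = 2), f))
  expect_error(stratified_kfold(rep(1L, 20), 5), "single class")
  expect_error(stratified_kfold(c(rep(0L, 3), rep(1L, 17)), 5), "fewer members")
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  out <- youden_threshold(c(0.2, 0.6, 0.9), c(0, 1, 1))
  expect_equal(out$threshold, 0.4)
  expect_equal(out$j, 1)
  expect_false(out$degenerate)
  # identical scores are degenerate with J = 0
  deg <- youden_threshold(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(deg$j, 0)
  expect_true(deg$degenerate)
  # random scores: optimal J stays within the Kolmogorov-Smirnov noise scale
  set.seed(1)
  y <- rep(c(0L, 1L), 500)
  j <- youden_threshold(runif(1000), y)$j
  expect_lt(j, 3 * sqrt(1 / 500 + 1 / 500))
  expect_error(youden_threshold(runif(5), rep(1, 5)), "single class")
})

test_that("all three classifier kinds separate a separable toy exactly", {
  set.seed(2)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = rnorm(n, ifelse(y == 1, 4, -4), 0.5),
             f2 = rnorm(n, ifelse(y == 1, -4, 4), 0.5))
  cfg <- fast_config()
  for (kind in c("svm", "rf", "lda")) {
    model <- train_classifier(kind, x, y, cfg, seed = 1)
    p <- scatteromics:::model_probabilities(model, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(as.integer(p >= 0.5), y)
  }
})

test_that("hyperparameter choice is deterministic and drawn from the grids", {
  set.seed(3)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[y == 1, 1] <- x[y == 1, 1] + 1.5
  cfg <- cv_config(svm_costs = c(0.1, 1, 10), rf_trees = c(100L, 250L),
                   rf_min_leaf = c(1L, 5L))
  m1 <- train_classifier("svm", x, y, cfg, seed = 7)
  m2 <- train_classifier("svm", x, y, cfg, seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_true(m1$hyperparameters$kernel %in% cfg$svm_kernels)
  expect_true(m1$hyperparameters$cost %in% cfg$svm_costs)
  r1 <- train_classifier("rf", x, y, cfg, seed = 7)
  r2 <- train_classifier("rf", x, y, cfg, seed = 7)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_identical(predict(r1$fit, x, type = "prob"),
                   predict(r2$fit, x, type = "prob"))
  expect_error(train_classifier("boost", x, y, cfg), "arg")
})

test_that("an empty feature set degrades to the prevalence model", {
  y <- rep(c(0L, 1L), 10)
  m <- train_classifier("svm", matrix(numeric(0), 20, 0), y, fast_config(), 1)
  expect_length(m$features, 0L)
  p <- scatteromics:::model_probabilities(m, matrix(numeric(0), 5, 0))
  expect_identical(p, rep(0.5, 5))
})

test_that("the repeated-CV driver records every cycle and reproduces bit-identically", {
  tab <- demo_feature_table(n = 40, effect = 2, seed = 1)
  cfg <- fast_config(n_repeats = 2L)
  fit1 <- scatteromics(tab, cfg, seed = 5)
  fit2 <- scatteromics(tab, cfg, seed = 5)
  expect_identical(fit1$cycles, fit2$cycles)
  expect_identical(fit1$oof, fit2$oof)
  expect_identical(fit1$retention, fit2$retention)
  expect_identical(fit1$n_cycles, 10L)
  expect_identical(nrow(fit1$cycles), 10L * 3L)  # three kinds per cycle
  # constructed separation: median validation AUROC is high for every kind
  med <- tapply(fit1$cycles$auroc, fit1$cycles$kind, median)
  expect_true(all(med > 0.9))
  # every cycle's validation subjects are disjoint from training by fold
  # construction; the out-of-fold table covers each subject once per repeat
  per_repeat <- table(fit1$oof$subject[fit1$oof$kind == "lda"],
                      fit1$oof$repeat_idx[fit1$oof$kind == "lda"])
  expect_true(all(per_repeat == 1L))
})

test_that("a label-free cohort yields chance-level validation AUROC", {
  tab <- demo_feature_table(n = 60, effect = 0, seed = 2)
  fit <- scatteromics(tab, fast_config(n_repeats = 2L), seed = 3)
  med <- median(fit$cycles$auroc)
  expect_gt(med, 0.3)
  expect_lt(med, 0.7)
})

test_that("stored best models apply to new tables without refitting", {
  tab <- demo_feature_table(n = 40, effect = 2, seed = 4)
  fit <- scatteromics(tab, fast_config(n_repeats = 1L), seed = 1)
  test_tab <- demo_feature_table(n = 20, effect = 2, seed = 99)
  for (kind in c("svm", "rf", "lda")) {
    out <- apply_model(fit$models[[kind]], test_tab)
    expect_length(out$prob, 20L)
    expect_true(all(out$prob >= 0 & out$prob <= 1))
    expect_true(all(out$class %in% 0:1))
    # single-row table gives one probability
    one <- apply_model(fit$models[[kind]], test_tab[3, ])
    expect_length(one$prob, 1L)
    expect_equal(one$prob, out$prob[3], tolerance = 1e-12)
  }
  expect_gt(auroc(predict(fit, test_tab, kind = "lda"), test_tab$label)$auroc,
            0.85)
  # missing feature columns are named
  broken <- test_tab[, setdiff(names(test_tab), fit$models$lda$features[1])]
  expect_error(apply_model(fit$models$lda, broken), "lacks feature")
  expect_identical(predict(fit, test_tab, kind = "lda", type = "class"),
                   apply_model(fit$models$lda, test_tab)$class)
})

test_that("cv_config validates grids and counts", {
  expect_error(cv_config(n_folds = 1), "n_folds")
  expect_error(cv_config(svm_costs = numeric(0)), "non-empty")
  cfg <- cv_config()
  expect_identical(cfg$n_folds * cfg$n_repeats, 150L)
})
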