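#' Cross-validation and hyperparameter-search configuration
#'
#' Defaults follow the repeated stratified design: 5 folds x 30 repeats =
#' 150 training-validation cycles, per-cycle feature selection, SVM box
#' constraints spanning 0.1-10 over linear/RBF/polynomial(3) kernels, random
#' forests with 100-1000 trees and minimum leaf sizes 1-20, and LDA.
#'
#' @param n_folds Outer folds (>= 2).
#' @param n_repeats Outer repetitions of the fold split.
#' @param kinds Classifier kinds to train each cycle.
#' @param svm_kernels,svm_costs SVM hyperparameter grid.
#' @param rf_trees,rf_min_leaf Random-forest hyperparameter grid.
#' @param inner_folds Folds of the internal model-selection CV
#'   (misclassification loss).
#' @param lasso_lambda Penalty grid handed to [lasso_select()].
#' @param prune_threshold Spearman threshold for [correlation_prune()].
#' @return A list of class `"cv_config"`.
#' @export
cv_config <- function(n_folds = 5L,
                      n_repeats = 30L,
                      kinds = c("svm", "rf", "lda"),
                      svm_kernels = c("linear", "radial", "polynomial"),
                      svm_costs = 10^seq(-1, 1, length.out = 5),
                      rf_trees = c(100L, 250L, 500L, 1000L),
                      rf_min_leaf = c(1L, 5L, 10L, 20L),
                      inner_folds = 5L,
                      lasso_lambda = NULL,
                      prune_threshold = 0.8) {
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  if (n_repeats < 1L) stop("`n_repeats` must be at least 1", call. = FALSE)
  kinds <- match.arg(kinds, c("svm", "rf", "lda"), several.ok = TRUE)
  if (length(svm_kernels) * length(svm_costs) == 0L ||
      length(rf_trees) * length(rf_min_leaf) == 0L) {
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  }
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 kinds = kinds,
                 svm_kernels = svm_kernels, svm_costs = svm_costs,
                 rf_trees = as.integer(rf_trees),
                 rf_min_leaf = as.integer(rf_min_leaf),
                 inner_folds = as.integer(inner_folds),
                 lasso_lambda = lasso_lambda,
                 prune_threshold = prune_threshold),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Partitions subjects into `k` folds preserving class proportions: within
#' each class, shuffled subjects are dealt round-robin, so per-fold class
#' counts differ by at most one subject. Deterministic for a given seed.
#'
#' @param labels Class labels (any type; each class needs >= k members).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L) stop("labels contain a single class", call. = FALSE)
  if (min(tab) < k) stop("smallest class has fewer members than folds", call. = FALSE)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Youden-index operating threshold
#'
#' Scans the midpoints between sorted unique scores and returns the threshold
#' maximizing J = sensitivity + specificity - 1 (predict positive when score
#' >= threshold). Ties resolve to the lowest threshold. Identical scores for
#' all subjects give J = 0 and a degenerate flag.
#'
#' @param scores Numeric classifier scores or probabilities.
#' @param labels Binary 0/1 labels (both classes required).
#' @return List with `threshold`, `j` (the Youden index at the optimum) and
#'   `degenerate`.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    return(list(threshold = u, j = 0, degenerate = TRUE))
  }
  cand <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  j <- vapply(cand, function(t) {
    sum(scores >= t & y == 1) / n1 + sum(scores < t & y == 0) / n0 - 1
  }, numeric(1))
  best <- which(j == max(j))[1]  # lowest threshold among ties (cand is sorted)
  list(threshold = cand[best], j = j[best], degenerate = FALSE)
}

## ---- classifier kinds ----------------------------------------------------

svm_grid <- function(config) {
  expand.grid(kernel = config$svm_kernels, cost = config$svm_costs,
              stringsAsFactors = FALSE)
}

rf_grid <- function(config) {
  expand.grid(ntree = config$rf_trees, nodesize = config$rf_min_leaf)
}

fit_svm_once <- function(x, yf, kernel, cost, seed) {
  set.seed(seed)
  e1071::svm(x, yf, kernel = kernel, cost = cost, degree = 3,
             scale = FALSE, probability = FALSE)
}

svm_decision <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  as.numeric(dv[, 1])
}

#' Train one classifier with inner-CV hyperparameter selection
#'
#' Fits an SVM, random forest or LDA model on (already normalized and
#' selected) training features. SVM and RF hyperparameters are chosen by
#' stratified inner cross-validated misclassification rate over the
#' configured grids (ties resolve to the earlier grid entry). All kinds emit
#' class-1 probabilities: the SVM through a monotone logistic (Platt) map
#' fitted on inner out-of-fold decision values, the forest through its vote
#' fraction, LDA through its posterior. An empty feature set yields a
#' prevalence model predicting the training class-1 rate.
#'
#' @param kind One of `"svm"`, `"rf"`, `"lda"`.
#' @param x Numeric feature matrix (may have zero columns).
#' @param y Binary 0/1 labels (>= 2 per class).
#' @param config A [cv_config()] supplying the grids.
#' @param seed Integer seed (fold assignment, forest randomness).
#' @return Object of class `"scx_model"`: `kind`, `hyperparameters`, `fit`,
#'   `features`, `prob_map`, and slots `threshold` / `norm` /
#'   `selection` filled by the cross-validation driver.
#' @export
train_classifier <- function(kind, x, y, config = cv_config(), seed = 1L) {
  kind <- match.arg(kind, c("svm", "rf", "lda"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  if (ncol(x) == 0L) {
    return(structure(list(kind = kind, hyperparameters = list(),
                          fit = NULL, prob_map = NULL,
                          features = character(0),
                          prevalence = mean(y),
                          threshold = NA_real_, norm = NULL, selection = NULL),
                     class = "scx_model"))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0, 1))
  inner_k <- min(config$inner_folds, min(table(y)))
  foldid <- if (inner_k >= 2L) stratified_kfold(y, inner_k, derive_seed(seed, 11L)) else NULL

  if (kind == "lda") {
    fit <- tryCatch(MASS::lda(x, grouping = yf), error = function(e) NULL)
    if (is.null(fit)) {
      return(train_classifier(kind, x[, 0, drop = FALSE], y, config, seed))
    }
    return(structure(list(kind = "lda", hyperparameters = list(),
                          fit = fit, prob_map = NULL,
                          features = colnames(x),
                          weights = fit$scaling,
                          threshold = NA_real_, norm = NULL, selection = NULL),
                     class = "scx_model"))
  }

  if (kind == "svm") {
    grid <- svm_grid(config)
    loss <- rep(NA_real_, nrow(grid))
    for (g in seq_len(nrow(grid))) {
      if (is.null(foldid)) { loss[g] <- 0; next }
      err <- 0L
      ok <- TRUE
      for (f in seq_len(inner_k)) {
        tr <- foldid != f
        fit <- tryCatch(fit_svm_once(x[tr, , drop = FALSE], yf[tr],
                                     grid$kernel[g], grid$cost[g],
                                     derive_seed(seed, g, f)),
                        error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        pred <- predict(fit, x[!tr, , drop = FALSE])
        err <- err + sum(pred != yf[!tr])
      }
      loss[g] <- if (ok) err / length(y) else Inf
    }
    best <- which(loss == min(loss))[1]
    fit <- fit_svm_once(x, yf, grid$kernel[best], grid$cost[best],
                        derive_seed(seed, 999L))
    # Platt map from inner out-of-fold decision values of the chosen combo
    dv_oof <- rep(NA_real_, length(y))
    if (!is.null(foldid)) {
      for (f in seq_len(inner_k)) {
        tr <- foldid != f
        ft <- fit_svm_once(x[tr, , drop = FALSE], yf[tr],
                           grid$kernel[best], grid$cost[best],
                           derive_seed(seed, best, f))
        dv_oof[!tr] <- svm_decision(ft, x[!tr, , drop = FALSE])
      }
    } else {
      dv_oof <- svm_decision(fit, x)
    }
    platt <- suppressWarnings(glm(y ~ dv, family = binomial(),
                                  data = data.frame(y = y, dv = dv_oof)))
    return(structure(list(kind = "svm",
                          hyperparameters = list(kernel = grid$kernel[best],
                                                 cost = grid$cost[best]),
                          fit = fit,
                          prob_map = coef(platt),
                          features = colnames(x),
                          threshold = NA_real_, norm = NULL, selection = NULL),
                     class = "scx_model"))
  }

  ## random forest
  grid <- rf_grid(config)
  loss <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    if (is.null(foldid)) { loss[g] <- 0; next }
    err <- 0L
    for (f in seq_len(inner_k)) {
      tr <- foldid != f
      set.seed(derive_seed(seed, g, f))
      fit <- randomForest::randomForest(x[tr, , drop = FALSE], yf[tr],
                                        ntree = grid$ntree[g],
                                        nodesize = grid$nodesize[g])
      pred <- predict(fit, x[!tr, , drop = FALSE])
      err <- err + sum(pred != yf[!tr])
    }
    loss[g] <- err / length(y)
  }
  best <- which(loss == min(loss))[1]
  set.seed(derive_seed(seed, 999L))
  fit <- randomForest::randomForest(x, yf, ntree = grid$ntree[best],
                                    nodesize = grid$nodesize[best])
  structure(list(kind = "rf",
                 hyperparameters = list(ntree = grid$ntree[best],
                                        nodesize = grid$nodesize[best]),
                 fit = fit, prob_map = NULL,
                 features = colnames(x),
                 threshold = NA_real_, norm = NULL, selection = NULL),
            class = "scx_model")
}

# Class-1 probabilities of a fitted scx_model on a (normalized) matrix.
model_probabilities <- function(model, x) {
  if (length(model$features) == 0L) {
    return(rep(model$prevalence, nrow(x)))
  }
  x <- x[, model$features, drop = FALSE]
  switch(model$kind,
         svm = {
           dv <- svm_decision(model$fit, x)
           plogis(model$prob_map[1] + model$prob_map[2] * dv)
         },
         rf = predict(model$fit, x, type = "prob")[, "1"],
         lda = predict(model$fit, x)$posterior[, "1"])
}

#' @export
print.scx_model <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<scx_model:%s> %d features | hyperparameters: %s | threshold %s\n",
              x$kind, length(x$features), hp,
              ifelse(is.na(x$threshold), "unset", format(x$threshold, digits = 3))))
  invisible(x)
}
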