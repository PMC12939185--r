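#' Fit scatteromics classifiers by repeated stratified cross-validation
#'
#' The central fitting routine: given a per-subject feature table (52
#' first-order features over the four envelope-statistics parametric maps,
#' plus a binary label), runs `n_repeats` repetitions of stratified
#' `n_folds`-fold cross-validation. Inside every one of the
#' `n_repeats * n_folds` training-validation cycles, and using the training
#' folds only: features are Z-score normalized, retained by cross-validated
#' LASSO logistic regression, pruned by the Spearman |rho| > 0.8 /
#' smaller-dynamic-range rule, and the configured classifier kinds (SVM,
#' random forest, LDA) are trained with inner-CV hyperparameter search. Each
#' cycle's validation fold supplies out-of-fold probabilities, a Youden
#' operating threshold, and AUROC/accuracy estimates. All data splitting is
#' at the subject level and the validation fold never influences selection
#' or training, so there is no leakage.
#'
#' The returned object keeps, per classifier kind, the model from its
#' highest-validation-accuracy cycle (ties resolve to the earlier cycle)
#' complete with its normalization parameters, selection state and
#' threshold, ready for [predict.scatteromics()] on an independent test
#' table. Feature retention probabilities across all cycles are in
#' `$retention`.
#'
#' @param table A `feature_table` (see [build_feature_table()]) or
#'   data.frame with a 0/1 `label` column and feature columns.
#' @param config A [cv_config()].
#' @param seed Integer master seed; the full run is bit-reproducible given
#'   the same table, config and seed.
#' @param verbose Print one line per repeat.
#' @return An object of class `"scatteromics"` with components `cycles`
#'   (one row per cycle x kind), `oof` (pooled out-of-fold probabilities),
#'   `retention`, `models`, `config`, `seed`, `n_cycles`.
#' @seealso [summary.scatteromics()], [predict.scatteromics()],
#'   [plot.scatteromics()]
#' @examples
#' \donttest{
#' tab <- demo_feature_table(n = 40, seed = 1)
#' fit <- scatteromics(tab, cv_config(n_repeats = 2), seed = 1)
#' summary(fit)
#' }
#' @export
scatteromics <- function(table, config = cv_config(), seed = 1L,
                         verbose = FALSE) {
  y <- as.integer(table$label)
  if (!is_binary01(y) || length(unique(y)) < 2L) {
    stop("`table$label` must contain both classes coded 0/1", call. = FALSE)
  }
  if (length(y) < 10L) stop("need at least 10 subjects", call. = FALSE)
  x_raw <- feature_matrix_any(table)
  feat_names <- colnames(x_raw)
  kinds <- config$kinds

  cycle_rows <- list()
  oof_rows <- list()
  final_feature_records <- vector("list", config$n_repeats * config$n_folds)
  best <- setNames(vector("list", length(kinds)), kinds)
  best_acc <- setNames(rep(-Inf, length(kinds)), kinds)

  cyc <- 0L
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_kfold(y, config$n_folds, derive_seed(seed, 5000L, r))
    for (f in seq_len(config$n_folds)) {
      cyc <- cyc + 1L
      val <- folds == f
      stopifnot(sum(val) > 0L, !any(val & !val))  # partition sanity
      y_tr <- y[!val]
      y_va <- y[val]

      z <- zscore_fit_apply(x_raw[!val, , drop = FALSE],
                            x_raw[val, , drop = FALSE])
      usable <- !z$state$constant
      sel <- lasso_select(z$train[, usable, drop = FALSE], y_tr,
                          seed = derive_seed(seed, r, f),
                          lambda = config$lasso_lambda)
      retained <- sel$retained_after_lasso
      if (length(retained) >= 2L) {
        rho <- spearman_matrix(z$train[, retained, drop = FALSE])
        pr <- correlation_prune(retained, rho, x_raw[!val, , drop = FALSE],
                                threshold = config$prune_threshold)
        sel$pruned <- pr$pruned
        sel$final_features <- pr$final_features
      } else {
        sel$final_features <- retained
      }
      fin <- sel$final_features
      final_feature_records[[cyc]] <- fin

      # validation features flagged invalid for a subject (NA) are imputed at
      # the training-fold mean, i.e. 0 after Z-scoring; no refitting involved
      x_va <- z$others[[1]][, fin, drop = FALSE]
      x_va[!is.finite(x_va)] <- 0
      for (ki in seq_along(kinds)) {
        kind <- kinds[ki]
        model <- train_classifier(kind, z$train[, fin, drop = FALSE], y_tr,
                                  config,
                                  seed = derive_seed(seed, r, f, ki))
        p_va <- model_probabilities(model, x_va)
        thr <- youden_threshold(p_va, y_va)
        acc <- mean(as.integer(p_va >= thr$threshold) == y_va)
        auc <- auroc(p_va, y_va)$auroc
        cycle_rows[[length(cycle_rows) + 1L]] <- data.frame(
          repeat_idx = r, fold = f, cycle = cyc, kind = kind,
          n_features = length(fin), lambda = sel$lasso_lambda,
          auroc = auc, accuracy = acc, threshold = thr$threshold,
          youden_j = thr$j, stringsAsFactors = FALSE)
        oof_rows[[length(oof_rows) + 1L]] <- data.frame(
          repeat_idx = r, fold = f, kind = kind,
          subject = which(val), prob = p_va, label = y_va,
          stringsAsFactors = FALSE)
        if (acc > best_acc[kind]) {
          best_acc[kind] <- acc
          model$threshold <- thr$threshold
          model$norm <- list(mean = z$state$mean, sd = z$state$sd,
                             constant = z$state$constant)
          model$selection <- sel
          model$cycle <- c(repeat_idx = r, fold = f)
          best[[kind]] <- model
        }
      }
    }
    if (verbose) message(sprintf("repeat %d/%d done", r, config$n_repeats))
  }

  structure(list(
    cycles = do.call(rbind, cycle_rows),
    oof = do.call(rbind, oof_rows),
    retention = retention_probabilities(final_feature_records,
                                        all_features = feat_names),
    models = best,
    config = config,
    seed = seed,
    n_cycles = cyc,
    n_subjects = length(y),
    labels = y,
    feature_names = feat_names,
    call = match.call()),
    class = "scatteromics")
}

#' Apply a trained scatteromics model to new subjects
#'
#' Transforms the test table with the normalization parameters stored in the
#' model (fitted on its training fold; nothing is refit), restricts to the
#' model's selected features, and returns class-1 probabilities and classes
#' at the stored Youden threshold.
#'
#' @param model An `scx_model` taken from a fitted [scatteromics()] object.
#' @param table Feature table containing at least the model's features.
#' @return List with `prob` and `class` vectors.
#' @export
apply_model <- function(model, table) {
  if (!inherits(model, "scx_model")) stop("`model` must be an scx_model", call. = FALSE)
  x <- feature_matrix_any(table)
  missing_feats <- setdiff(model$features, colnames(x))
  if (length(missing_feats)) {
    stop(sprintf("test table lacks feature columns: %s",
                 paste(missing_feats, collapse = ", ")), call. = FALSE)
  }
  if (length(model$features) > 0L) {
    mu <- model$norm$mean[model$features]
    sdv <- model$norm$sd[model$features]
    xs <- sweep(x[, model$features, drop = FALSE], 2, mu, `-`)
    xs <- sweep(xs, 2, sdv, `/`)
    # flagged-invalid (NA) entries impute at the training mean (0 after
    # Z-scoring)
    xs[!is.finite(xs)] <- 0
  } else {
    xs <- x[, 0, drop = FALSE]
  }
  p <- model_probabilities(model, xs)
  list(prob = as.numeric(p),
       class = as.integer(p >= model$threshold))
}

#' @export
print.scatteromics <- function(x, ...) {
  cat(sprintf("Scatteromics fit: %d subjects, %d cycles (%d repeats x %d folds)\n",
              x$n_subjects, x$n_cycles, x$config$n_repeats, x$config$n_folds))
  agg <- stats::aggregate(cbind(auroc, accuracy) ~ kind, data = x$cycles, median)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-4s median validation AUROC %.3f, accuracy %.3f\n",
                agg$kind[i], agg$auroc[i], agg$accuracy[i]))
  }
  invisible(x)
}

#' Summary of a scatteromics fit
#'
#' Per-kind median and interquartile range of the cycle validation AUROCs
#' and accuracies, pooled out-of-fold Brier scores, and the most frequently
#' retained features.
#'
#' @param object A fitted [scatteromics()] object.
#' @param top Number of top-retention features to display.
#' @param ... Unused.
#' @return Invisibly, a list with `performance`, `brier` and `retention`.
#' @export
summary.scatteromics <- function(object, top = 10L, ...) {
  perf <- do.call(rbind, lapply(split(object$cycles, object$cycles$kind),
                                function(d) {
    data.frame(kind = d$kind[1],
               auroc_median = median(d$auroc),
               auroc_q1 = quantile(d$auroc, 0.25, names = FALSE),
               auroc_q3 = quantile(d$auroc, 0.75, names = FALSE),
               accuracy_median = median(d$accuracy))
  }))
  brier <- vapply(split(object$oof, object$oof$kind),
                  function(d) brier_score(d$prob, d$label), numeric(1))
  print(object)
  cat("\nPooled out-of-fold Brier scores:\n")
  for (k in names(brier)) cat(sprintf("  %-4s %.4f\n", k, brier[k]))
  cat(sprintf("\nTop retained features (of %d cycles):\n", object$n_cycles))
  rp <- head(object$retention[object$retention > 0], top)
  for (i in seq_along(rp)) {
    cat(sprintf("  %-16s %5.1f%%\n", names(rp)[i], 100 * rp[i]))
  }
  invisible(list(performance = perf, brier = brier,
                 retention = object$retention))
}

#' Predict method for scatteromics fits
#'
#' @param object A fitted [scatteromics()] object.
#' @param newdata Feature table of new subjects.
#' @param kind Which stored best model to use (default the first configured
#'   kind).
#' @param type `"prob"` for class-1 probabilities, `"class"` for thresholded
#'   classes.
#' @param ... Unused.
#' @return Numeric (probabilities) or integer (classes) vector.
#' @export
predict.scatteromics <- function(object, newdata,
                                 kind = object$config$kinds[1],
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  kind <- match.arg(kind, object$config$kinds)
  out <- apply_model(object$models[[kind]], newdata)
  if (type == "prob") out$prob else out$class
}

#' Retention probabilities as model coefficients
#'
#' For a scatteromics fit the natural "coefficients" are the per-feature
#' retention probabilities across cross-validation cycles.
#'
#' @param object A fitted [scatteromics()] object.
#' @param ... Unused.
#' @return Named numeric vector (descending retention probability).
#' @export
coef.scatteromics <- function(object, ...) object$retention

#' Diagnostic plots for a scatteromics fit
#'
#' Left: distribution of cycle validation AUROCs per classifier kind.
#' Right: pooled out-of-fold calibration curve (10 equally spaced bins)
#' against the perfect-calibration diagonal.
#'
#' @param x A fitted [scatteromics()] object.
#' @param kind Kind shown in the calibration panel.
#' @param ... Unused.
#' @export
plot.scatteromics <- function(x, kind = x$config$kinds[1], ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  boxplot(auroc ~ kind, data = x$cycles, ylab = "validation AUROC",
          xlab = "", main = sprintf("%d CV cycles", x$n_cycles))
  abline(h = 0.5, lty = 3)
  d <- x$oof[x$oof$kind == kind, ]
  cal <- calibration_curve(d$prob, d$label)
  plot(cal$mean_pred, cal$frac_pos, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "mean predicted probability", ylab = "observed fraction",
       main = sprintf("calibration (%s), Brier %.3f", kind,
                      brier_score(d$prob, d$label)))
  abline(0, 1, lty = 2)
  lines(cal$mean_pred[!is.na(cal$frac_pos)], cal$frac_pos[!is.na(cal$frac_pos)])
  invisible(x)
}

#' Small synthetic feature table for examples and tests
#'
#' Draws a feature table directly in feature space (bypassing the RF
#' simulator): class-1 subjects shift a subset of features by `effect`
#' standard deviations; all other features are noise. Useful for exercising
#' the selection and cross-validation machinery quickly.
#'
#' @param n Number of subjects.
#' @param effect Shift (in SD) of the informative features for class 1.
#' @param n_informative Number of informative features.
#' @param seed Integer seed.
#' @return A `feature_table` with the 52 standard feature names.
#' @export
demo_feature_table <- function(n = 40L, effect = 1.5, n_informative = 6L,
                               seed = 1L) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  feats <- scx_feature_names()
  x <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, feats))
  informative <- seq_len(n_informative)
  x[y == 1, informative] <- x[y == 1, informative] + effect
  out <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                          label = y, stringsAsFactors = FALSE),
               as.data.frame(x))
  class(out) <- c("feature_table", "data.frame")
  out
}
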