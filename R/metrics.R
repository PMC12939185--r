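#' AUROC with Hanley-McNeil confidence interval
#'
#' Area under the ROC curve computed as the pairwise concordance probability
#' (rank / Mann-Whitney formulation; tied scores count one half), with an
#' asymptotic 95 percent confidence interval by the Hanley-McNeil variance.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary 0/1 labels, both classes present.
#' @return List with `auroc`, `ci` (length-2, clipped to `[0, 1]`) and `se`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("labels contain a single class", call. = FALSE)
  r <- rank(scores)
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  list(auroc = a,
       ci = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se)),
       se = se)
}

#' Diagnostic metric panel from a confusion matrix
#'
#' Computes the full panel from predicted and true binary classes:
#' sensitivity, specificity, accuracy, F1, positive/negative diagnostic
#' likelihood ratios, predictive values and balanced accuracy, plus the raw
#' confusion counts. Zero denominators yield `Inf` (flagged likelihood
#' ratios) or `NA` rather than errors.
#'
#' @param predicted Predicted 0/1 classes.
#' @param labels True 0/1 labels.
#' @return List of class `"metric_panel"`; rates are proportions in
#'   `[0, 1]`.
#' @export
confusion_metrics <- function(predicted, labels) {
  p <- as.integer(predicted)
  y <- as.integer(labels)
  if (length(p) != length(y) || length(y) < 1L) {
    stop("inputs must be equal-length and non-empty", call. = FALSE)
  }
  tp <- sum(p == 1 & y == 1)
  tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  out <- metric_panel(sens, spec, ppv = ppv,
                      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  out$accuracy <- (tp + tn) / length(y)
  out$counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}

#' Diagnostic metric panel from printed rates
#'
#' Derives the likelihood ratios, F1 score and balanced accuracy implied by
#' reported sensitivity, specificity and (for F1) positive predictive value:
#' LR+ = sens / (1 - spec), LR- = (1 - sens) / spec,
#' F1 = 2 PPV sens / (PPV + sens), balanced accuracy = (sens + spec) / 2.
#' Accepts proportions or percentages (values > 1 are divided by 100).
#'
#' @param sensitivity,specificity Rates (proportion or percent).
#' @param ppv,npv Optional predictive values.
#' @return List of class `"metric_panel"` with `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `lr_plus`, `lr_minus`, `f1`, `balanced_accuracy`
#'   (proportions; likelihood ratios unitless, `Inf` flagged when
#'   specificity is 1).
#' @export
metric_panel <- function(sensitivity, specificity, ppv = NULL, npv = NULL) {
  as_prop <- function(x) if (!is.null(x) && is.finite(x) && x > 1) x / 100 else x
  sens <- as_prop(sensitivity)
  spec <- as_prop(specificity)
  ppv <- as_prop(ppv)
  npv <- as_prop(npv)
  lr_plus <- if (is.na(spec)) NA_real_ else if (spec == 1) Inf else sens / (1 - spec)
  lr_minus <- if (is.na(spec)) NA_real_ else if (spec == 0) Inf else (1 - sens) / spec
  f1 <- if (is.null(ppv) || is.na(ppv) || is.na(sens) || ppv + sens == 0) {
    NA_real_
  } else {
    2 * ppv * sens / (ppv + sens)
  }
  structure(list(sensitivity = sens, specificity = spec,
                 ppv = ppv %||% NA_real_, npv = npv %||% NA_real_,
                 lr_plus = lr_plus, lr_minus = lr_minus, f1 = f1,
                 balanced_accuracy = (sens + spec) / 2),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("sens %s spec %s PPV %s NPV %s | LR+ %.2f LR- %.2f F1 %.2f balacc %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
              x$lr_plus, x$lr_minus, x$f1, pct(x$balanced_accuracy)))
  invisible(x)
}

#' Brier score
#'
#' Mean squared difference between predicted class-1 probabilities and the
#' observed binary outcomes; lower is better, 0.25 is the score of a
#' constant 0.5 forecast.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param labels Binary 0/1 outcomes.
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(probabilities, labels) {
  p <- as.numeric(probabilities)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  mean((p - as.numeric(labels))^2)
}

#' Calibration curve over equally spaced probability bins
#'
#' Groups predicted probabilities into `bins` equal-width bins on `[0, 1]`
#' and reports, per bin, the subject count, mean predicted probability and
#' observed fraction of positive outcomes. Empty bins are kept in the table
#' with `NA` summaries so they are visibly flagged rather than silently
#' dropped.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param labels Binary 0/1 outcomes.
#' @param bins Number of bins (default 10).
#' @return data.frame with columns `bin`, `lower`, `upper`, `n`,
#'   `mean_pred`, `frac_pos`.
#' @export
calibration_curve <- function(probabilities, labels, bins = 10L) {
  p <- as.numeric(probabilities)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  y <- as.numeric(labels)
  bins <- as.integer(bins)
  breaks <- (0:bins) / bins
  idx <- findInterval(p, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(bin = seq_len(bins),
                    lower = breaks[-length(breaks)],
                    upper = breaks[-1],
                    n = tabulate(idx, nbins = bins),
                    mean_pred = NA_real_,
                    frac_pos = NA_real_)
  for (b in seq_len(bins)) {
    if (out$n[b] > 0L) {
      out$mean_pred[b] <- mean(p[idx == b])
      out$frac_pos[b] <- mean(y[idx == b])
    }
  }
  out
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F test across two or more groups
#' (equal-variance assumption), as used to compare per-subject parametric-map
#' means across fibrosis stages.
#'
#' @param groups List of numeric vectors, each with at least 2 values.
#' @return List with `f`, `p`, and the degrees of freedom `df_between`,
#'   `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  n <- length(x)
  kg <- length(groups)
  gm <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ss_b <- sum(vapply(groups, length, integer(1)) * (means - gm)^2)
  ss_w <- sum((x - means[as.integer(g)])^2)
  df_b <- kg - 1L
  df_w <- n - kg
  if (ss_w == 0) {
    f <- if (ss_b == 0) 0 else Inf
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df_b, df_w, lower.tail = FALSE)
  list(f = f, p = p, df_between = df_b, df_within = df_w)
}

#' Evaluate stored models on an independent test cohort and write a report
#'
#' For every stored best-cycle model of a [scatteromics()] fit: applies it to
#' the test table (normalization and features from the model's training
#' fold; nothing refit), and assembles AUROC with 95 percent CI, the full
#' confusion-derived metric panel at the stored Youden threshold, the Brier
#' score and the 10-bin calibration table. Optionally serializes the report
#' as JSON plus CSV side tables (cycle AUROC distribution, retention
#' probabilities, per-kind calibration bins). Output is deterministic: the
#' same fit and table always produce byte-identical files.
#'
#' @param fit A fitted [scatteromics()] object.
#' @param test_table Feature table of independent test subjects (0/1
#'   `label`).
#' @param dir Output directory, or `NULL` to skip writing.
#' @return The report list (per-kind `testing` metrics plus
#'   `validation_summary`), invisibly when writing.
#' @export
scx_report <- function(fit, test_table, dir = NULL) {
  if (!inherits(fit, "scatteromics")) stop("`fit` must be a scatteromics object", call. = FALSE)
  y <- as.integer(test_table$label)
  report <- list(metadata = list(
    package_version = as.character(utils::packageVersion("scatteromics")),
    n_test = length(y),
    n_cycles = fit$n_cycles,
    seed = fit$seed,
    auroc_ci_method = "hanley-mcneil",
    notes = "threshold = Youden on validation fold of the best cycle"))
  for (kind in fit$config$kinds) {
    pred <- apply_model(fit$models[[kind]], test_table)
    roc <- auroc(pred$prob, y)
    cm <- confusion_metrics(pred$class, y)
    report[[kind]] <- list(
      auroc = roc$auroc, auroc_ci = roc$ci,
      threshold = fit$models[[kind]]$threshold,
      accuracy = cm$accuracy,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      ppv = cm$ppv, npv = cm$npv, f1 = cm$f1,
      lr_plus = cm$lr_plus, lr_minus = cm$lr_minus,
      balanced_accuracy = cm$balanced_accuracy,
      confusion = as.list(cm$counts),
      brier = brier_score(pred$prob, y),
      calibration = calibration_curve(pred$prob, y),
      n_features = length(fit$models[[kind]]$features),
      features = fit$models[[kind]]$features)
  }
  agg <- stats::aggregate(auroc ~ kind, data = fit$cycles, median)
  report$validation_summary <- setNames(as.list(agg$auroc), agg$kind)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    write.csv(fit$cycles, file.path(dir, "cycle_metrics.csv"),
              row.names = FALSE)
    write.csv(data.frame(feature = names(fit$retention),
                         retention_probability = as.numeric(fit$retention)),
              file.path(dir, "retention.csv"), row.names = FALSE)
    for (kind in fit$config$kinds) {
      write.csv(report[[kind]]$calibration,
                file.path(dir, sprintf("calibration_%s.csv", kind)),
                row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
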