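#' Z-score normalization fitted on training data
#'
#' Centers and scales every feature column to zero mean and unit standard
#' deviation using parameters estimated on the training table only; any
#' further tables (validation, test) are transformed with the training
#' parameters, never refit, so no information leaks out of the training fold.
#' Constant training columns cannot be scaled: they are flagged and left
#' untransformed, and downstream selection excludes them.
#'
#' @param train Feature table or numeric matrix/data.frame (training rows).
#' @param ... Further tables to transform with the training parameters.
#' @return List with `train`, `others` (list), and `state` (per-feature
#'   `mean`, `sd`, logical `constant`).
#' @export
zscore_fit_apply <- function(train, ...) {
  xt <- feature_matrix_any(train)
  if (nrow(xt) < 2L) stop("need at least 2 training rows", call. = FALSE)
  mu <- colMeans(xt)
  sdv <- apply(xt, 2, sd)
  constant <- !is.finite(sdv) | sdv <= 0
  scale_one <- function(x) {
    out <- sweep(x, 2, mu, `-`)
    out[, !constant] <- sweep(out[, !constant, drop = FALSE], 2,
                              sdv[!constant], `/`)
    out[, constant] <- x[, constant, drop = FALSE]
    out
  }
  others <- lapply(list(...), function(tab) scale_one(feature_matrix_any(tab)))
  list(train = scale_one(xt), others = others,
       state = list(mean = mu, sd = sdv, constant = constant))
}

feature_matrix_any <- function(x) {
  if (inherits(x, "feature_table")) return(feature_matrix(x))
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), c("subject_id", "label")), drop = FALSE]
  }
  as.matrix(x)
}

#' LASSO feature retention
#'
#' L1-penalized logistic regression over a log-spaced penalty grid, with the
#' penalty chosen by internal stratified cross-validated binomial deviance
#' (minimum rule). Features with nonzero coefficients at the chosen penalty
#' are retained. Constant columns are excluded before fitting.
#'
#' @param x Numeric matrix of normalized features (rows = subjects).
#' @param y Binary 0/1 labels (at least 2 subjects per class).
#' @param seed Integer seed controlling the internal fold assignment.
#' @param lambda Penalty grid (default 50 values log-spaced on
#'   `[1e-4, 10]`).
#' @param nfolds Internal stratified folds (default 5, reduced if a class is
#'   smaller).
#' @return List of class `"selection_state"` with `lasso_lambda`,
#'   `lasso_coefficients`, `retained_after_lasso`, `constant_features`;
#'   `pruned` and `final_features` are filled by [correlation_prune()].
#' @export
lasso_select <- function(x, y, seed = 1L, lambda = NULL, nfolds = 5L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!is_binary01(y) || length(unique(y)) < 2L) {
    stop("`y` must contain both classes", call. = FALSE)
  }
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  constant <- apply(x, 2, function(col) !is.finite(sd(col)) || sd(col) <= 0)
  xa <- x[, !constant, drop = FALSE]
  if (is.null(lambda)) lambda <- exp(seq(log(10), log(1e-4), length.out = 50))
  lambda <- sort(lambda, decreasing = TRUE)
  nfolds <- min(nfolds, min(table(y)))
  foldid <- stratified_kfold(y, nfolds, seed)
  fit <- glmnet::cv.glmnet(xa, y, family = "binomial", lambda = lambda,
                           foldid = foldid, standardize = FALSE,
                           type.measure = "deviance")
  beta <- as.numeric(coef(fit, s = "lambda.min"))[-1]
  names(beta) <- colnames(xa)
  retained <- names(beta)[beta != 0]
  structure(list(lasso_lambda = fit$lambda.min,
                 lasso_coefficients = beta,
                 retained_after_lasso = retained,
                 constant_features = colnames(x)[constant],
                 pruned = NULL,
                 final_features = retained),
            class = "selection_state")
}

#' Pairwise Spearman rank-correlation matrix
#'
#' Symmetric matrix of Spearman correlations between feature columns; also
#' usable to correlate features against external covariates. Constant columns
#' produce `NA` entries (flagged with a warning).
#'
#' @param x Numeric matrix or data.frame with at least 3 rows.
#' @return Correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- feature_matrix_any(x)
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  constant <- apply(x, 2, function(col) sd(col) == 0 || !is.finite(sd(col)))
  rho <- suppressWarnings(cor(x, method = "spearman"))
  diag(rho) <- 1
  if (any(constant)) {
    warning("constant columns give undefined correlations (NA)")
  }
  rho
}

#' Correlation-based redundancy pruning
#'
#' Processes feature pairs in descending absolute Spearman correlation; for
#' every pair still surviving whose |rho| exceeds the threshold, the member
#' with the smaller dynamic range (max minus min over the raw, pre-normalized
#' training values) is removed. Deterministic given its inputs, and
#' idempotent.
#'
#' @param retained Character vector of candidate feature names.
#' @param rho Correlation matrix covering at least `retained`.
#' @param x_raw Raw (pre-Z-score) training feature matrix for dynamic ranges.
#' @param threshold Pruning threshold on |rho| (default 0.8, strict
#'   inequality).
#' @return List with `final_features` and `pruned` (data.frame: feature,
#'   partner, rho).
#' @export
correlation_prune <- function(retained, rho, x_raw, threshold = 0.8) {
  if (length(retained) == 0L) {
    return(list(final_features = character(0),
                pruned = data.frame(feature = character(0),
                                    partner = character(0),
                                    rho = numeric(0))))
  }
  x_raw <- feature_matrix_any(x_raw)
  rng <- apply(x_raw[, retained, drop = FALSE], 2,
               function(col) diff(range(col)))
  alive <- setNames(rep(TRUE, length(retained)), retained)
  pruned <- list()
  if (length(retained) >= 2L) {
    pairs <- which(upper.tri(rho[retained, retained, drop = FALSE]),
                   arr.ind = TRUE)
    pr <- abs(rho[retained, retained, drop = FALSE][pairs])
    ord <- order(pr, decreasing = TRUE)
    for (p in ord) {
      i <- retained[pairs[p, 1]]
      j <- retained[pairs[p, 2]]
      if (!alive[i] || !alive[j] || is.na(pr[p]) || pr[p] <= threshold) next
      drop_name <- if (rng[i] < rng[j]) i else j
      alive[drop_name] <- FALSE
      pruned[[length(pruned) + 1L]] <- data.frame(
        feature = drop_name, partner = if (drop_name == i) j else i,
        rho = rho[i, j], stringsAsFactors = FALSE)
    }
  }
  list(final_features = retained[alive[retained]],
       pruned = if (length(pruned)) do.call(rbind, pruned) else
         data.frame(feature = character(0), partner = character(0),
                    rho = numeric(0)))
}

#' Feature retention probabilities across cross-validation cycles
#'
#' Fraction of cycles in which each feature survived LASSO selection plus
#' correlation pruning, reported for all features in descending order.
#'
#' @param records List of character vectors, one per cycle, naming the final
#'   features of that cycle.
#' @param all_features Character vector of the full feature set (default the
#'   52 names of [scx_feature_names()]).
#' @return Named numeric vector of probabilities in `[0, 1]`, sorted
#'   decreasingly.
#' @export
retention_probabilities <- function(records, all_features = scx_feature_names()) {
  if (length(records) == 0L) stop("need at least one cycle", call. = FALSE)
  counts <- setNames(numeric(length(all_features)), all_features)
  for (r in records) {
    r <- intersect(r, all_features)
    counts[r] <- counts[r] + 1
  }
  sort(counts / length(records), decreasing = TRUE)
}
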