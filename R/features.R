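#' Names of the 13 first-order statistics and the 52-feature set
#'
#' The simplified feature set comprises 13 first-order statistics computed on
#' each of the four parametric maps (Nakagami m, homodyned-K alpha and k,
#' entropy H), giving 52 named features `<param>_<stat>` in parameter-major
#' order.
#'
#' @return `first_order_stat_names()`: character vector of 13 statistic
#'   names; `scx_feature_names()`: character vector of 52 feature names.
#' @export
first_order_stat_names <- function() {
  c("mean", "median", "mode", "variance", "std", "kurtosis", "skewness",
    "min", "max", "q3", "q1", "iqr", "range")
}

#' @rdname first_order_stat_names
#' @export
scx_feature_names <- function() {
  as.vector(t(outer(c("m", "alpha", "k", "H"), first_order_stat_names(),
                    paste, sep = "_")))
}

#' In-ROI values of a parametric map
#'
#' Resamples a binary ROI mask (defined on the envelope/B-mode pixel grid)
#' onto the parametric map grid: a map cell belongs to the ROI if and only if
#' its window center falls on a masked pixel. Flagged-invalid (non-finite)
#' cells are dropped.
#'
#' @param map A `parametric_map`.
#' @param mask Logical matrix on the envelope grid (or a list with elements
#'   `mask`/`values`).
#' @return Numeric vector of finite in-ROI map values (at least 5 required).
#' @export
roi_values <- function(map, mask) {
  m <- if (is.list(mask)) (mask$mask %||% mask$values) else mask
  if (!is.matrix(m) || !is.logical(m)) stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(m)) stop("mask has no selected pixels", call. = FALSE)
  ctr <- map_cell_centers(map)
  ri <- pmin(pmax(round(ctr$axial), 1L), nrow(m))
  ci <- pmin(pmax(round(ctr$lateral), 1L), ncol(m))
  inroi <- m[ri, ci, drop = FALSE]
  vals <- map$values[inroi]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 5L) {
    stop("fewer than 5 valid map cells inside the ROI", call. = FALSE)
  }
  vals
}

#' The 13 first-order statistics of a value vector
#'
#' Computes the simplified feature set: mean, median, mode, variance,
#' standard deviation, kurtosis, skewness, minimum, maximum, 75th percentile
#' (Q3), 25th percentile (Q1), interquartile range and range. Moment
#' statistics use the 1/n normalization; kurtosis is excess kurtosis (the
#' normal distribution scores 0); quantiles use linear interpolation between
#' order statistics; the mode of continuous data is the center of the
#' maximal-count bin of a 50-bin equal-width histogram over
#' \[min, max\] (ties resolved to the lowest bin). A zero-variance input
#' yields `NA` skewness and kurtosis (flagged, not an error).
#'
#' @param values Numeric vector with at least 2 finite values (ROI
#'   extraction upstream enforces the stricter minimum of 5 valid cells).
#' @return Named numeric vector of length 13 (names from
#'   [first_order_stat_names()]).
#' @export
first_order_features <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  if (s > 0) {
    skew <- sum((x - mu)^3) / n / s^3
    kurt <- sum((x - mu)^4) / n / s^4 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lo <- min(x)
  hi <- max(x)
  if (hi > lo) {
    breaks <- lo + (hi - lo) * (0:50) / 50
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = 50L)
    b <- which.max(counts)  # which.max takes the lowest maximal bin
    mode_val <- (breaks[b] + breaks[b + 1]) / 2
  } else {
    mode_val <- lo
  }
  setNames(c(mu, q[2], mode_val, v, s, kurt, skew, lo, hi, q[3], q[1],
             q[3] - q[1], hi - lo),
           first_order_stat_names())
}

#' Assemble the per-subject feature table
#'
#' Applies the subject's ROI mask to its four parametric maps and computes
#' the 13 first-order statistics on each, yielding one row of 52 features per
#' subject plus `subject_id` and the binary `label`.
#'
#' @param maps List (one element per subject) of named lists with
#'   `parametric_map`s `m`, `alpha`, `k`, `H`.
#' @param masks List of logical ROI matrices, one per subject.
#' @param labels Binary (0/1) vector, one per subject.
#' @param subject_ids Optional character vector of unique subject ids.
#' @return A data.frame of class `"feature_table"`: `subject_id`, `label`,
#'   then the 52 feature columns of [scx_feature_names()].
#' @export
build_feature_table <- function(maps, masks, labels, subject_ids = NULL) {
  n <- length(maps)
  if (length(masks) != n || length(labels) != n) {
    stop("`maps`, `masks` and `labels` must have equal length", call. = FALSE)
  }
  if (!is_binary01(labels)) stop("`labels` must be 0/1", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  if (anyDuplicated(subject_ids)) stop("duplicated subject_id", call. = FALSE)
  params <- c("m", "alpha", "k", "H")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!all(params %in% names(maps[[i]]))) {
      stop(sprintf("subject %s is missing a parametric map", subject_ids[i]),
           call. = FALSE)
    }
    feats <- lapply(params, function(p) {
      vals <- tryCatch(roi_values(maps[[i]][[p]], masks[[i]]),
                       error = function(e) {
                         stop(sprintf("subject %s: %s", subject_ids[i],
                                      conditionMessage(e)), call. = FALSE)
                       })
      first_order_features(vals)
    })
    rows[[i]] <- unlist(feats)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- scx_feature_names()
  out <- cbind(data.frame(subject_id = subject_ids, label = as.integer(labels),
                          stringsAsFactors = FALSE), out)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_matrix <- function(table) {
  as.matrix(table[, scx_feature_names()[scx_feature_names() %in% names(table)],
                  drop = FALSE])
}

#' Parametric maps and feature table for a simulated cohort
#'
#' Convenience pipeline: for every cohort subject, computes the envelope
#' image, the four parametric maps (Nakagami window 3 pulse lengths,
#' homodyned-K 5, entropy 1, all at 50 percent overlap), applies the ROI
#' mask and assembles the 52-column feature table.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config An [estimator_config()].
#' @param verbose Print a progress line per subject.
#' @return A `feature_table` (see [build_feature_table()]).
#' @export
cohort_feature_table <- function(cohort, config = estimator_config(),
                                 verbose = FALSE) {
  n <- length(cohort$frames)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- cohort$frames[[i]]
    env <- envelope_from_rf(fr)
    w_m <- window_spec_from_pulse(fr$pulse_length, 3L, fr)
    w_hk <- window_spec_from_pulse(fr$pulse_length, 5L, fr)
    w_h <- window_spec_from_pulse(fr$pulse_length, 1L, fr)
    hk <- hk_parametric_maps(env, w_hk, config)
    maps[[i]] <- list(m = sliding_window_map(env, "m", w_m, config),
                      alpha = hk$alpha, k = hk$k,
                      H = sliding_window_map(env, "H", w_h, config))
    if (verbose) message(sprintf("subject %d/%d", i, n))
  }
  build_feature_table(maps, cohort$masks, cohort$labels,
                      cohort$truth$subject_id)
}
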