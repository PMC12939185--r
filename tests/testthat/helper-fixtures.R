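# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env()

# Frame whose tone frequency divides fs exactly (integer cycles, so the
# FFT-based analytic signal has no leakage).
tone_frame <- function(n_ax = 960L, n_lat = 8L, f0 = 3e6, fs = 12e6,
                       amplitude = 1) {
  t <- (seq_len(n_ax) - 1) / fs
  col <- amplitude * cos(2 * pi * f0 * t)
  rf_frame(matrix(col, n_ax, n_lat), fs = fs, f0 = f0, pulse_length = 0.6,
           lateral_pitch = 0.15)
}

# Independent-oracle recomputation of the 13 first-order statistics, written
# directly from their defining formulas (explicit sums, no shared code).
naive_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  xs <- sort(x)
  q_lin <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  lo <- xs[1]
  hi <- xs[n]
  if (hi > lo) {
    counts <- integer(50)
    for (xi in x) {
      b <- floor((xi - lo) / (hi - lo) * 50) + 1
      if (b > 50) b <- 50
      counts[b] <- counts[b] + 1
    }
    b <- which(counts == max(counts))[1]
    mode_val <- lo + (hi - lo) * (b - 0.5) / 50
  } else {
    mode_val <- lo
  }
  c(mean = mu, median = q_lin(0.5), mode = mode_val, variance = v, std = s,
    kurtosis = sum(((x - mu) / s)^4) / n - 3,
    skewness = sum(((x - mu) / s)^3) / n,
    min = lo, max = hi, q3 = q_lin(0.75), q1 = q_lin(0.25),
    iqr = q_lin(0.75) - q_lin(0.25), range = hi - lo)
}

# Tiny labeled cohort (shared across tests; ~8 s to build once).
tiny_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    spec <- phantom_spec(n_per_class = 4L, geometry = c(512L, 48L), seed = 42L)
    .fixtures$cohort <- generate_cohort(spec)
  }
  .fixtures$cohort
}

tiny_cohort_table <- function() {
  if (is.null(.fixtures$cohort_table)) {
    .fixtures$cohort_table <- cohort_feature_table(tiny_cohort())
  }
  .fixtures$cohort_table
}

# Reduced hyperparameter grids keep unit-test cross-validation fast; the
# outer-CV defaults (5 folds x N repeats) are untouched.
fast_config <- function(n_repeats = 2L, ...) {
  cv_config(n_repeats = n_repeats,
            svm_kernels = "linear", svm_costs = c(0.1, 1),
            rf_trees = 100L, rf_min_leaf = c(5L, 10L), ...)
}
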