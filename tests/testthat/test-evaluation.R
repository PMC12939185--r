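test_that("AUROC equals hand-counted concordance", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auroc, 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auroc, 1.0)
  # ties count one half
  expect_equal(auroc(c(1, 1), c(0, 1))$auroc, 0.5)
  expect_error(auroc(runif(5), rep(1, 5)), "single class")
})

test_that("AUROC equals the exhaustive pair-counting oracle on random instances", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    conc <- 0
    for (i in which(y == 1)) {
      for (j in which(y == 0)) {
        conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
      }
    }
    expect_equal(auroc(s, y)$auroc, conc / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
})

test_that("AUROC and its CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(200, 1, 0.4)
  s <- runif(200) + 0.5 * y
  ours <- auroc(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours$auroc, theirs, tolerance = 1e-12)
  expect_true(ours$ci[1] < ours$auroc && ours$auroc < ours$ci[2])
})

test_that("permuted labels give chance AUROC within 3 SE", {
  set.seed(3)
  n <- 2000
  y <- rep(c(0L, 1L), n / 2)
  out <- auroc(runif(n), y)
  se_null <- sqrt((n + 1) / (12 * (n / 2)^2))
  expect_lt(abs(out$auroc - 0.5), 3 * se_null)
})

test_that("the metric panel reproduces printed diagnostic ratios", {
  # likelihood ratios and scores implied by published sens/spec/PPV pairs
  lda <- metric_panel(80.00, 65.52, ppv = 51.61)
  expect_equal(round(lda$lr_plus, 2), 2.32)
  expect_equal(round(lda$lr_minus, 2), 0.31)
  expect_equal(round(lda$f1, 2), 0.63)
  svm <- metric_panel(95.00, 48.28)
  expect_equal(round(svm$lr_plus, 2), 1.84)
  rf <- metric_panel(90.00, 52.87)
  expect_lt(abs(100 * rf$balanced_accuracy - 71.43), 0.006)  # 2 d.p. agreement
  # perfect specificity flags an infinite LR+
  expect_identical(metric_panel(0.8, 1)$lr_plus, Inf)
})

test_that("confusion-derived metrics are internally consistent", {
  set.seed(4)
  for (rep in 1:10) {
    y <- rbinom(60, 1, 0.5)
    p <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    cm <- confusion_metrics(p, y)
    ct <- cm$counts
    expect_identical(sum(ct), 60L)
    expect_equal(cm$sensitivity, ct["tp"] / (ct["tp"] + ct["fn"]),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(cm$balanced_accuracy, (cm$sensitivity + cm$specificity) / 2,
                 tolerance = 1e-12)
    expect_equal(cm$lr_plus, cm$sensitivity / (1 - cm$specificity),
                 tolerance = 1e-12)
    expect_equal(cm$f1, 2 * cm$ppv * cm$sensitivity / (cm$ppv + cm$sensitivity),
                 tolerance = 1e-12)
    expect_equal(cm$accuracy, (ct["tp"] + ct["tn"]) / 60,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("perfect separation means a threshold with sens = spec = 1 exists", {
  set.seed(5)
  y <- rep(c(0L, 1L), 25)
  s <- y + runif(50, -0.4, 0.4)
  expect_equal(auroc(s, y)$auroc, 1.0)
  thr <- youden_threshold(s, y)
  cm <- confusion_metrics(as.integer(s >= thr$threshold), y)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 1.0)
})

test_that("Brier score matches closed forms and the uniform-calibration integral", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 20), rbinom(20, 1, 0.7)), 0.25)
  set.seed(6)
  n <- 1e5
  p <- runif(n)
  y <- rbinom(n, 1, p)
  b <- brier_score(p, y)
  se <- sd((p - y)^2) / sqrt(n)
  expect_lt(abs(b - 1 / 6), 3 * se)   # E[(p - y)^2] = E[p(1 - p)] = 1/6
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("calibration bins are equally spaced, flagged when empty", {
  set.seed(7)
  n <- 1e5
  p <- runif(n)
  y <- rbinom(n, 1, p)
  cal <- calibration_curve(p, y)
  expect_identical(nrow(cal), 10L)
  expect_equal(cal$upper - cal$lower, rep(0.1, 10))
  expect_lt(max(abs(cal$frac_pos - cal$mean_pred)), 0.02)
  expect_identical(sum(cal$n), as.integer(n))
  # a single populated bin, the rest flagged NA
  cal2 <- calibration_curve(rep(0.95, 40), rbinom(40, 1, 0.9))
  expect_identical(sum(cal2$n > 0), 1L)
  expect_identical(which(cal2$n > 0), 10L)
  expect_true(all(is.na(cal2$mean_pred[1:9])))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # SSB = 54 on 2 df, SSW = 6 on 6 df, hence F = (54/2) / (6/6) = 27
  out <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(out$f, 27)
  expect_equal(out$p, pf(27, 2, 6, lower.tail = FALSE))
  expect_identical(c(out$df_between, out$df_within), c(2L, 6L))
  ident <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$f, 0)
  expect_equal(ident$p, 1)
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(c(1, 2), 3)), "at least 2 values")
  # cross-check against the classical equal-variance test in stats
  set.seed(8)
  g <- list(rnorm(10), rnorm(12, 0.5), rnorm(9, 1))
  ours <- anova_oneway(g)
  ref <- oneway.test(x ~ grp, data = data.frame(
    x = unlist(g), grp = factor(rep(1:3, sapply(g, length)))),
    var.equal = TRUE)
  expect_equal(ours$f, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(9)
  rej <- 0L
  n_rep <- 1e4
  for (i in seq_len(n_rep)) {
    if (anova_oneway(list(rnorm(5), rnorm(5), rnorm(5)))$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.04)
  expect_lt(rej / n_rep, 0.06)
})

test_that("reports carry the full metric panel and serialize deterministically", {
  tab <- demo_feature_table(n = 40, effect = 2, seed = 10)
  fit <- scatteromics(tab, fast_config(n_repeats = 1L), seed = 2)
  test_tab <- demo_feature_table(n = 30, effect = 2, seed = 77)
  rep1 <- scx_report(fit, test_tab)
  for (kind in c("svm", "rf", "lda")) {
    for (field in c("auroc", "auroc_ci", "accuracy", "sensitivity",
                    "specificity", "f1", "lr_plus", "lr_minus", "ppv", "npv",
                    "balanced_accuracy", "confusion", "brier", "calibration")) {
      expect_true(field %in% names(rep1[[kind]]),
                  info = paste(kind, field))
    }
    expect_identical(nrow(rep1[[kind]]$calibration), 10L)
    expect_identical(sum(unlist(rep1[[kind]]$confusion)), 30L)
  }
  d1 <- file.path(tempdir(), "scx_rep1")
  d2 <- file.path(tempdir(), "scx_rep2")
  scx_report(fit, test_tab, d1)
  scx_report(fit, test_tab, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(file.exists(file.path(d1, "report.json")))
  expect_true(file.exists(file.path(d1, "retention.csv")))
})
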