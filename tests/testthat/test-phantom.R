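test_that("samplers are deterministic given a seed", {
  expect_identical(sample_nakagami(0.7, 1, 1000, seed = 7),
                   sample_nakagami(0.7, 1, 1000, seed = 7))
  expect_identical(sample_hk(4, 0.4, 1, 1000, seed = 7),
                   sample_hk(4, 0.4, 1, 1000, seed = 7))
  f1 <- simulate_rf_frame(density = 5, geometry = c(256L, 16L), seed = 3)
  f2 <- simulate_rf_frame(density = 5, geometry = c(256L, 16L), seed = 3)
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(
    f1$samples,
    simulate_rf_frame(density = 5, geometry = c(256L, 16L), seed = 4)$samples))
})

test_that("Nakagami sampler conserves the intensity moments", {
  # omega recovery within 3 SE at n = 1e5
  a <- sample_nakagami(0.6, 2, 1e5, seed = 1)
  i <- a^2
  se <- sd(i) / sqrt(length(i))
  expect_lt(abs(mean(i) - 2), 3 * se)
  # m = 1 is Rayleigh: intensity is exponential, so mean = sd
  a1 <- sample_nakagami(1, 1, 1e6, seed = 2)
  expect_equal(mean(a1^2), 1, tolerance = 0.01)
  expect_equal(sd(a1^2) / mean(a1^2), 1, tolerance = 0.01)
  # large-sample mean of A^2 within 1 percent of omega
  expect_equal(mean(sample_nakagami(0.6, 2, 1e6, seed = 3)^2), 2,
               tolerance = 0.01)
})

test_that("homodyned-K sampler matches its closed-form limits", {
  # k = 0 gives a K envelope: Nakagami m = alpha / (alpha + 2)
  m_of <- function(a) {
    i <- a^2
    mean(i)^2 / mean((i - mean(i))^2)
  }
  expect_lt(abs(m_of(sample_hk(100, 0, 1, 1e6, seed = 5)) - 100 / 102), 0.03)
  expect_lt(m_of(sample_hk(0.5, 0, 1, 1e6, seed = 6)), 1)
  # intensity SNR of the K case matches the gamma-mixture closed form
  # sqrt(alpha / (alpha + 2)), within 3 block-resampled SEs
  for (alpha in c(1, 4)) {
    i <- sample_hk(alpha, 0, 1, 2e5, seed = alpha)^2
    blocks <- matrix(i, ncol = 20)
    snr_b <- apply(blocks, 2, function(b) mean(b) / sd(b))
    se <- sd(snr_b) / sqrt(20)
    expect_lt(abs(mean(i) / sd(i) - sqrt(alpha / (alpha + 2))), 3 * se)
  }
  # mean intensity = 2 sigma^2 alpha (1 + k^2) under the shared convention
  i <- sample_hk(4, 0.5, 1.5, 1e6, seed = 9)^2
  expect_equal(mean(i), 2 * 1.5^2 * 4 * (1 + 0.25), tolerance = 0.01)
})

test_that("sampler inputs are validated", {
  expect_error(sample_nakagami(-1, 1, 10, 1), "m")
  expect_error(sample_nakagami(1, 0, 10, 1), "omega")
  expect_error(sample_nakagami(1, 1, 0, 1), "n")
  expect_error(sample_hk(0, 0.4, 1, 10, 1), "alpha")
  expect_error(sample_hk(1, -0.1, 1, 10, 1), "k")
})

test_that("simulated frames reproduce the acquisition constants and density physics", {
  fr <- simulate_rf_frame(density = 20, geometry = c(1024L, 64L), seed = 1)
  expect_equal(fr$fs, 12e6)
  expect_equal(fr$f0, 3.5e6)
  expect_gt(fr$fs, 2 * fr$f0)
  env <- envelope_from_rf(fr)
  w <- window_spec_from_pulse(fr$pulse_length, 3, fr)
  m_dense <- mean(sliding_window_map(env, "m", w)$values, na.rm = TRUE)
  expect_gt(m_dense, 0.9)   # fully developed speckle is Rayleigh-like
  expect_lt(m_dense, 1.1)
  fr_sparse <- simulate_rf_frame(density = 0.5, geometry = c(1024L, 64L), seed = 1)
  m_sparse <- mean(sliding_window_map(envelope_from_rf(fr_sparse), "m", w)$values,
                   na.rm = TRUE)
  expect_lt(m_sparse, 0.9)  # sparse scatterers are pre-Rayleigh
})

test_that("windowed m is monotone in scatterer density", {
  mean_m <- function(density, seed) {
    fr <- simulate_rf_frame(density = density, geometry = c(512L, 32L),
                            seed = seed)
    w <- window_spec_from_pulse(fr$pulse_length, 3, fr)
    mean(sliding_window_map(envelope_from_rf(fr), "m", w)$values, na.rm = TRUE)
  }
  ms <- sapply(c(0.5, 2, 20), function(d) {
    mean(sapply(1:10, function(s) mean_m(d, s)))
  })
  expect_true(all(diff(ms) > 0))
})

test_that("frame simulation rejects invalid geometry and bandwidth", {
  expect_error(simulate_rf_frame(density = 5, geometry = c(4L, 8L), seed = 1),
               "pulse length")
  expect_error(simulate_rf_frame(density = 5, geometry = c(256L, 8L),
                                 pulse = list(f0 = 3.5e6, fs = 12e6,
                                              bandwidth = 2.5), seed = 1),
               "bandwidth")
  expect_error(simulate_rf_frame(density = 5, geometry = c(256L, 8L),
                                 pulse = list(f0 = 7e6, fs = 12e6,
                                              bandwidth = 0.6), seed = 1),
               "fs")
})

test_that("cohorts are reproducible given the same spec and seed", {
  coh <- tiny_cohort()
  spec <- phantom_spec(n_per_class = 4L, geometry = c(512L, 48L), seed = 42L)
  coh2 <- generate_cohort(spec)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$frames[[3]]$samples, coh2$frames[[3]]$samples)
  expect_identical(coh$labels, c(rep(0L, 4), rep(1L, 4)))
})

test_that("preset classes separate in the fibrosis direction", {
  spec <- phantom_spec(n_per_class = 10L, geometry = c(768L, 48L), seed = 42L)
  tab <- cohort_feature_table(generate_cohort(spec))
  # fibrosis-like class: fewer effective scatterers, more pre-Rayleigh
  expect_gt(mean(tab$m_mean[tab$label == 0]),
            mean(tab$m_mean[tab$label == 1]))
  expect_gt(mean(tab$alpha_mean[tab$label == 0]),
            mean(tab$alpha_mean[tab$label == 1]))
})

test_that("steatosis-flagged subjects shift toward Rayleigh statistics", {
  cls <- phantom_class_presets()$F1
  spec <- phantom_spec(classes = list(cls), n_per_class = 12L,
                       geometry = c(512L, 48L), steatosis_fraction = 0.5,
                       seed = 9L)
  coh <- generate_cohort(spec)
  expect_true(any(coh$truth$steatosis) && any(!coh$truth$steatosis))
  # elevated density is recorded in the ground truth ...
  expect_gt(mean(coh$truth$density[coh$truth$steatosis]),
            mean(coh$truth$density[!coh$truth$steatosis]))
  # ... and visible as higher within-class mean m
  tab <- cohort_feature_table(coh)
  expect_gt(mean(tab$m_mean[coh$truth$steatosis]),
            mean(tab$m_mean[!coh$truth$steatosis]))
})

test_that("phantom spec validation catches bad inputs", {
  expect_error(phantom_spec(classes = list()), "non-empty")
  expect_error(phantom_spec(steatosis_fraction = 1.2), "steatosis_fraction")
  expect_error(phantom_class("X", density = -1), "density")
})
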