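# Internal helpers shared across modules.

# Deterministic sub-seed derivation: keeps every stochastic step independently
# seeded from one user seed while staying inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (i in idx) {
    x <- (x * 69069 + as.double(i) * 1234567 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Gauss-Legendre nodes/weights on (0, 1) via the Golub-Welsch eigenproblem.
gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

is_binary01 <- function(y) {
  all(y %in% c(0, 1)) && length(unique(y)) >= 1L
}
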