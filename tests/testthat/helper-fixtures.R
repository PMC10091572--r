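# Shared fixtures and independent oracles, built in code at test time.

# Independent linear solver: Gaussian elimination with partial pivoting,
# used as the normal-equations oracle for every least-squares check.
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n)) {
    p <- which.max(abs(M[k:n, k])) + k - 1L
    if (p != k) M[c(k, p), ] <- M[c(p, k), ]
    M[k, ] <- M[k, ] / M[k, k]
    for (i in setdiff(seq_len(n), k)) {
      M[i, ] <- M[i, ] - M[i, k] * M[k, ]
    }
  }
  M[, n + 1L]
}

ols_oracle <- function(X, y) {
  as.numeric(gauss_solve(crossprod(X), crossprod(X, y)))
}

# Small deterministic regression fixture (6 rows, 2 predictors).
toy_regression <- function() {
  data.frame(
    y = c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2),
    x1 = c(1, 2, 3, 4, 5, 6),
    x2 = c(0.5, -0.3, 0.8, -0.1, 0.4, -0.6)
  )
}

# Mediation-shaped fixture with nonzero paths, fixed numbers.
toy_mediation <- function() {
  data.frame(
    x = c(1.2, -0.4, 0.3, 2.1, -1.5, 0.9, -0.2, 1.7),
    m = c(0.8, -0.9, 0.1, 1.6, -1.2, 0.5, -0.6, 1.1),
    y = c(1.1, -0.7, 0.4, 2.0, -1.8, 0.9, -0.1, 1.5)
  )
}

# Larger smooth fixture for moderated fits (12 rows, 5 columns).
toy_moderated <- function() {
  set.seed(424242)
  d <- data.frame(
    x = rnorm(12), w = rnorm(12), age = rnorm(12), sex = rep(0:1, 6)
  )
  d$m <- 0.5 * d$x - 0.2 * d$x * d$w + rnorm(12, sd = 0.3)
  d$y <- 0.3 * d$x - 0.4 * d$m + 0.1 * d$m * d$w + rnorm(12, sd = 0.3)
  d
}

table1_spec <- function(include_age = TRUE) adult_survey_moments(include_age)

expect_tol <- function(actual, expected, tol) {
  expect_true(
    abs(actual - expected) < tol,
    label = sprintf("|%g - %g| < %g", actual, expected, tol)
  )
}
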