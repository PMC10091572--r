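#' Repair an indefinite correlation matrix
#'
#' Printed correlation tables are rounded, and augmenting them with extra
#' rows (e.g. an age column with a few known correlations and zeros
#' elsewhere) can make the assembled matrix indefinite. This routine
#' restores positive definiteness by eigenvalue clipping: eigenvalues below
#' `floor` are raised to `floor`, the matrix is reassembled and rescaled to
#' a unit diagonal, and the two steps are iterated until the smallest
#' eigenvalue of the rescaled matrix is at least `floor`.
#'
#' The repair is a no-op (zero change, single pass) on matrices that are
#' already positive definite, and is idempotent.
#'
#' @param corr Symmetric matrix with unit diagonal, off-diagonals in
#'   \[-1, 1\].
#' @param floor Eigenvalue floor; the smallest perturbation target that
#'   still yields a usable covariance. Default `1e-6`.
#' @param max_iter Maximum clip-rescale iterations.
#' @return The repaired correlation matrix, with attributes
#'   `repair_delta` (max absolute elementwise change from the input),
#'   `iterations` (clip-rescale passes used), and `min_eigenvalue`.
#' @export
#' @examples
#' bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
#' fixed <- repair_correlation_matrix(bad)
#' attr(fixed, "repair_delta")
repair_correlation_matrix <- function(corr, floor = 1e-6, max_iter = 200L) {
  corr <- as.matrix(corr)
  check_corr_matrix(corr)
  if (floor <= 0) abort("`floor` must be strictly positive.")
  out <- (corr + t(corr)) / 2
  iterations <- 0L
  repeat {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= floor || iterations >= max_iter) break
    vals <- pmax(e$values, floor)
    out <- e$vectors %*% (vals * t(e$vectors))
    # rescale to a unit diagonal (clipping inflates the diagonal slightly)
    d <- 1 / sqrt(diag(out))
    out <- out * tcrossprod(d)
    out <- (out + t(out)) / 2
    diag(out) <- 1
    iterations <- iterations + 1L
  }
  min_eig <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig < floor * (1 - 1e-6)) {
    abort("Correlation repair failed to reach the eigenvalue floor.")
  }
  dimnames(out) <- dimnames(corr)
  structure(
    out,
    repair_delta = max(abs(out - corr)),
    iterations = iterations,
    min_eigenvalue = min_eig
  )
}
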