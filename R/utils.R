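# Internal helpers shared across modules.

# Run `code` with the RNG seeded at `seed` (if non-NULL), restoring the
# caller's RNG state afterwards so generators never perturb user streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically fork a master seed into named substreams. The pool is
# drawn once in a fixed order, so appending stage names never changes the
# seeds of earlier stages.
fork_seeds <- function(master, names) {
  pool <- with_seed(master, sample.int(.Machine$integer.max - 1L, length(names)))
  setNames(as.list(pool), names)
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds.
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

# Empirical quantile convention used for all bootstrap bounds: order
# statistics with linear interpolation (type 7). Bounds at two decimals are
# sensitive to this choice, so it is fixed here and documented.
boot_quantile <- function(x, probs) {
  quantile(x, probs = probs, type = 7, names = FALSE)
}

# Column-wise z-scoring with the n-1 standard deviation, consistent with
# the sample descriptives.
standardize_columns <- function(data, cols) {
  for (cl in cols) {
    v <- data[[cl]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(paste0("Cannot standardize constant column '", cl, "'."))
    }
    data[[cl]] <- (v - mean(v)) / s
  }
  data
}

check_columns <- function(data, cols, what = "column") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Unknown ", what, "(s): ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

check_complete <- function(data, cols) {
  bad <- !complete.cases(data[cols])
  if (any(bad)) {
    abort(paste0(
      "Missing values in analysis columns (rows ",
      paste(head(which(bad), 5L), collapse = ", "),
      if (sum(bad) > 5) ", ..." else "",
      "); filter with validate_input() first."
    ))
  }
  invisible(TRUE)
}
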