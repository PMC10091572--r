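#' Descriptive statistics per variable
#'
#' Mean, standard deviation (n-1 denominator), median and interquartile
#' range for each numeric column.
#'
#' @param data A data frame.
#' @param variables Columns to describe; default all numeric columns.
#' @return A tibble with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `median`, `q25`, `q75`.
#' @export
#' @examples
#' describe(generate_scale_level(adult_survey_moments(), 200, seed = 1))
describe <- function(data, variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  check_columns(data, variables)
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 2) abort(paste0("Need at least 2 values in '", v, "'."))
    tibble(
      variable = v, n = length(x), mean = mean(x), sd = sd(x),
      median = median(x),
      q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75))
    )
  })
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations with two-sided p-values from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param data A data frame with `n >= 3` complete rows on `variables`.
#' @param variables Columns to correlate; default all numeric columns.
#' @return An object of class `pearson_matrix`: list with matrices `r` and
#'   `p`, and `n`. Use [tidy()] for a long tibble.
#' @export
#' @examples
#' pm <- pearson_matrix(generate_scale_level(adult_survey_moments(), 200, seed = 1),
#'                      c("ct", "se", "phq9"))
#' tidy(pm)
pearson_matrix <- function(data, variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  check_columns(data, variables)
  x <- as.matrix(data[variables])
  check_complete(data, variables)
  n <- nrow(x)
  if (n < 3) abort("Need at least 3 rows.")
  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    abort(paste0(
      "Constant column(s): ", paste(variables[const], collapse = ", ")
    ))
  }
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat("<pearson_matrix> n =", x$n, "\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Mann-Whitney U test for a two-group comparison
#'
#' Rank-sum comparison of `values` between the two levels of `groups`,
#' through [stats::wilcox.test()] (normal approximation with tie
#' correction for large samples). `U` counts pairs in which the
#' first-group value exceeds the second-group value, ties counting one
#' half.
#'
#' @param data A data frame.
#' @param values Name of the numeric column.
#' @param groups Name of the binary grouping column (2 distinct values;
#'   the first group is the smaller level after sorting).
#' @return A tibble with `u`, `p.value`, `n1`, `n2`, `group1`, `group2`.
#' @export
mann_whitney_u <- function(data, values, groups) {
  check_columns(data, c(values, groups))
  x <- data[[values]]
  g <- data[[groups]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- g[keep]
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`groups` must take exactly two values.")
  x1 <- x[g == lev[1]]
  x2 <- x[g == lev[2]]
  if (length(x1) == 0 || length(x2) == 0) abort("Both groups must be non-empty.")
  wt <- suppressWarnings(wilcox.test(x1, x2))
  tibble(
    u = unname(wt$statistic), p.value = wt$p.value,
    n1 = length(x1), n2 = length(x2),
    group1 = as.character(lev[1]), group2 = as.character(lev[2])
  )
}

# Expand terms like "a:b" into component columns and build the working data
# frame: optionally z-score the base variables first, then form interaction
# products from the (standardized) components. Products themselves are not
# re-standardized, so +/-1 on a standardized moderator is exactly one SD.
build_design <- function(data, outcome, terms, standardized) {
  comps <- strsplit(terms, ":", fixed = TRUE)
  base_vars <- unique(c(outcome, unlist(comps)))
  check_columns(data, base_vars)
  d <- as.data.frame(data)[base_vars]
  check_complete(d, base_vars)
  if (standardized) d <- standardize_columns(d, base_vars)
  work <- d[outcome]
  safe <- make.names(gsub(":", "_x_", terms), unique = TRUE)
  for (i in seq_along(terms)) {
    work[[safe[i]]] <- Reduce(`*`, d[comps[[i]]])
  }
  list(work = work, safe = safe, terms = terms, data = d)
}

#' Ordinary least-squares fit with standardized coefficients
#'
#' Fits `outcome ~ terms` by least squares through [stats::lm()]. Terms may
#' include interactions written `"a:b"`; when `standardized = TRUE` all
#' base variables are z-scored (n-1 SD) first and products are formed from
#' the standardized components. For unstandardized fits the standardized
#' coefficient of a non-interaction term is reported as
#' `B * sd(x) / sd(y)`.
#'
#' @param data A data frame (complete cases on the used columns).
#' @param outcome Name of the outcome column.
#' @param terms Character vector of predictor terms (column names, or
#'   `"a:b"` products).
#' @param standardized Fit on z-scored variables?
#' @return An object of class `ols_fit`; see [tidy()] / [glance()].
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 500, seed = 1)
#' fit <- ols_fit(d, "se", "ct")
#' tidy(fit)
ols_fit <- function(data, outcome, terms, standardized = FALSE) {
  des <- build_design(data, outcome, terms, standardized)
  work <- des$work
  n <- nrow(work)
  p <- length(terms)
  if (n < p + 2) abort("Too few rows for the number of terms.")
  names(work)[1] <- ".outcome"
  fit <- lm(reformulate(des$safe, response = ".outcome"), data = work)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- des$terms[match(names(cf)[is.na(cf)], des$safe)]
    abort(paste0(
      "Rank-deficient design; offending term(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  sdy <- sd(work$.outcome)
  is_int <- grepl(":", des$terms, fixed = TRUE)
  std <- vapply(seq_along(des$terms), function(i) {
    if (standardized) {
      unname(cf[des$safe[i]])
    } else if (is_int[i]) {
      NA_real_
    } else {
      unname(cf[des$safe[i]]) * sd(work[[des$safe[i]]]) / sdy
    }
  }, numeric(1))
  coefs <- tibble(
    term = c("(Intercept)", des$terms),
    estimate = unname(cf[c("(Intercept)", des$safe)]),
    std_estimate = c(NA_real_, std),
    se = unname(ct[c("(Intercept)", des$safe), "Std. Error"]),
    statistic = unname(ct[c("(Intercept)", des$safe), "t value"]),
    p.value = unname(ct[c("(Intercept)", des$safe), "Pr(>|t|)"])
  )
  coefs$stars <- signif_stars(coefs$p.value)
  fstat <- unname(sm$fstatistic)
  structure(
    list(
      coefficients = coefs,
      r.squared = sm$r.squared,
      fstatistic = fstat[1], df1 = fstat[2], df2 = fstat[3],
      p.value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      sigma = sm$sigma, n = n, outcome = outcome, terms = terms,
      standardized = standardized
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(
    "<ols_fit> ", x$outcome, " ~ ", paste(x$terms, collapse = " + "),
    if (x$standardized) "  (standardized)", "\n",
    sep = ""
  )
  print(x$coefficients)
  cat(sprintf(
    "R^2 = %.4f, F(%d, %d) = %.2f, n = %d\n",
    x$r.squared, x$df1, x$df2, x$fstatistic, x$n
  ))
  invisible(x)
}

#' Hierarchical (blockwise) least-squares regression
#'
#' Fits a sequence of nested models by entering predictor blocks in order,
#' reporting each step's coefficients plus the R-squared increment and the
#' incremental F test
#' `F = (delta R^2 / q) / ((1 - R^2_step) / (n - p_step - 1))`
#' with `q` terms added at the step.
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param blocks List of character vectors of terms, entered in order;
#'   blocks must be disjoint. Interactions as `"a:b"`.
#' @param standardized Fit on z-scored variables (default `TRUE`, the
#'   convention for moderated regression with interaction terms).
#' @return An object of class `hier_fit`: list with `steps` (one
#'   [ols_fit()] per block) and `increments` (a tibble with `step`,
#'   `terms_added`, `r.squared`, `delta_r2`, `inc_f`, `df1`, `df2`,
#'   `p.value`, `stars`).
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 500, seed = 1)
#' hf <- hierarchical_fit(d, "se",
#'   blocks = list(c("age", "sex"), c("ct", "cr"), "ct:cr"))
#' hf$increments
hierarchical_fit <- function(data, outcome, blocks, standardized = TRUE) {
  if (!is.list(blocks) || length(blocks) == 0) {
    abort("`blocks` must be a non-empty list of term vectors.")
  }
  all_terms <- unlist(blocks)
  if (anyDuplicated(all_terms)) abort("Blocks must be disjoint.")
  steps <- vector("list", length(blocks))
  cum <- character()
  rows <- vector("list", length(blocks))
  r2_prev <- 0
  for (i in seq_along(blocks)) {
    cum <- c(cum, blocks[[i]])
    steps[[i]] <- ols_fit(data, outcome, cum, standardized = standardized)
    q <- length(blocks[[i]])
    r2 <- steps[[i]]$r.squared
    df2 <- steps[[i]]$n - length(cum) - 1
    inc_f <- ((r2 - r2_prev) / q) / ((1 - r2) / df2)
    pv <- pf(inc_f, q, df2, lower.tail = FALSE)
    rows[[i]] <- tibble(
      step = i, terms_added = paste(blocks[[i]], collapse = " + "),
      r.squared = r2, delta_r2 = r2 - r2_prev,
      inc_f = inc_f, df1 = q, df2 = df2, p.value = pv,
      stars = signif_stars(pv)
    )
    r2_prev <- r2
  }
  structure(
    list(
      steps = steps, increments = dplyr::bind_rows(rows),
      outcome = outcome, blocks = blocks, standardized = standardized
    ),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit> outcome:", x$outcome, "-", length(x$blocks), "blocks\n")
  print(x$increments)
  cat("Final step coefficients:\n")
  print(x$steps[[length(x$steps)]]$coefficients)
  invisible(x)
}
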