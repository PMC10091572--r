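#' Moment specification for the scale-level generator
#'
#' A moment specification bundles the per-variable means and standard
#' deviations with a Pearson correlation matrix. It is the contract the
#' synthetic scale-level generator draws from: a multivariate-normal sample
#' whose population moments equal the specification (after positive-definite
#' repair of the correlation matrix, if needed).
#'
#' @param variables Character vector of variable names (column order).
#' @param means Numeric vector of means, one per variable.
#' @param sds Numeric vector of strictly positive standard deviations.
#' @param corr Symmetric correlation matrix with unit diagonal and
#'   off-diagonal entries in \[-1, 1\]. Dimnames, if present, must agree
#'   with `variables`.
#'
#' @return An object of class `moment_spec`.
#' @seealso [generate_scale_level()], [repair_correlation_matrix()],
#'   [adult_survey_moments()]
#' @export
#' @examples
#' moment_spec(c("x", "y"), means = c(0, 10), sds = c(1, 2),
#'             corr = matrix(c(1, 0.5, 0.5, 1), 2))
moment_spec <- function(variables, means, sds, corr) {
  variables <- as.character(variables)
  k <- length(variables)
  if (k < 1) abort("`variables` must be non-empty.")
  if (anyDuplicated(variables)) abort("`variables` must be unique.")
  if (length(means) != k || length(sds) != k) {
    abort("`means` and `sds` must have one entry per variable.")
  }
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    abort("`sds` must be strictly positive and finite.")
  }
  corr <- as.matrix(corr)
  check_corr_matrix(corr, k)
  if (!is.null(dimnames(corr)[[1]]) &&
      !identical(dimnames(corr)[[1]], variables)) {
    abort("Dimnames of `corr` disagree with `variables`.")
  }
  dimnames(corr) <- list(variables, variables)
  structure(
    list(
      variables = variables,
      means = setNames(as.numeric(means), variables),
      sds = setNames(as.numeric(sds), variables),
      corr = corr
    ),
    class = "moment_spec"
  )
}

check_corr_matrix <- function(corr, k = nrow(corr), tol = 1e-8) {
  if (!is.matrix(corr) || nrow(corr) != k || ncol(corr) != k) {
    abort("`corr` must be a square matrix matching the number of variables.")
  }
  if (any(!is.finite(corr))) abort("`corr` must be finite.")
  if (max(abs(corr - t(corr))) > tol) abort("`corr` must be symmetric.")
  if (max(abs(diag(corr) - 1)) > tol) abort("`corr` must have a unit diagonal.")
  off <- corr[row(corr) != col(corr)]
  if (any(off < -1 - tol | off > 1 + tol)) {
    abort("Off-diagonal correlations must lie in [-1, 1].")
  }
  invisible(TRUE)
}

#' @export
print.moment_spec <- function(x, ...) {
  cat("<moment_spec> ", length(x$variables), " variables: ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  print(tibble(variable = x$variables, mean = unname(x$means),
               sd = unname(x$sds)))
  invisible(x)
}

#' Covariance matrix implied by a moment specification
#'
#' @param spec A [moment_spec()].
#' @return The covariance matrix `diag(sds) %*% corr %*% diag(sds)`.
#' @export
moment_covariance <- function(spec) {
  stopifnot(inherits(spec, "moment_spec"))
  s <- diag(spec$sds, nrow = length(spec$sds))
  out <- s %*% spec$corr %*% s
  dimnames(out) <- dimnames(spec$corr)
  out
}

#' Reference moment structure: adult mental-health survey
#'
#' Scale-level means, standard deviations and Pearson correlations of the
#' six analysis variables observed in a large cross-sectional online survey
#' of Chinese adults (n = 6057): GAD-7 anxiety symptoms, PHQ-9 depression
#' symptoms, childhood trauma (CTQ total), self-esteem (Rosenberg SES
#' total), cognitive reappraisal and expressive suppression (the two ERQ
#' subscales). This is the default input of the package's worked examples
#' and of the synthetic-data generator.
#'
#' @param include_age If `TRUE` (default), append a standardized `age`
#'   column correlated -0.13 with depression and -0.10 with anxiety (its
#'   marginal distribution is supplied by [demographic_spec()] at draw
#'   time); all other age correlations are 0.
#' @return A [moment_spec()] with variables `gad7`, `phq9`, `ct`, `se`,
#'   `cr`, `es` (and optionally `age`).
#' @export
#' @examples
#' adult_survey_moments()
adult_survey_moments <- function(include_age = TRUE) {
  vars <- c("gad7", "phq9", "ct", "se", "cr", "es")
  means <- c(3.12, 4.194, 38.46, 31.09, 26.77, 14.31)
  sds <- c(4.05, 4.90, 11.67, 5.49, 7.53, 4.82)
  r <- diag(6)
  dimnames(r) <- list(vars, vars)
  fill <- function(i, j, v) {
    r[i, j] <<- v
    r[j, i] <<- v
  }
  fill("gad7", "phq9", 0.80)
  fill("gad7", "ct", 0.28)
  fill("gad7", "se", -0.30)
  fill("gad7", "cr", -0.05)
  fill("gad7", "es", 0.09)
  fill("phq9", "ct", 0.31)
  fill("phq9", "se", -0.35)
  fill("phq9", "cr", -0.05)
  fill("phq9", "es", 0.13)
  fill("ct", "se", -0.41)
  fill("ct", "cr", -0.31)
  fill("ct", "es", -0.03)
  fill("se", "cr", 0.28)
  fill("se", "es", -0.05)
  fill("cr", "es", 0.42)
  if (include_age) {
    vars <- c(vars, "age")
    means <- c(means, 0)
    sds <- c(sds, 1)
    r2 <- diag(7)
    dimnames(r2) <- list(vars, vars)
    r2[1:6, 1:6] <- r
    r2["age", "phq9"] <- r2["phq9", "age"] <- -0.13
    r2["age", "gad7"] <- r2["gad7", "age"] <- -0.10
    r <- r2
  }
  moment_spec(vars, means, sds, r)
}

#' Demographic specification for synthetic respondents
#'
#' Describes the sample composition the generator emulates: sample size,
#' proportion of women, and an age marginal calibrated by its median and
#' interquartile range with a hard minimum (adult respondents). Ages are a
#' monotone transform of a standard normal: a two-sided half-normal with
#' separate scales below and above the median so that the median and both
#' quartiles are matched exactly before truncation and rounding.
#'
#' Defaults reproduce the reference survey: 39.99% women (2422 of 6057),
#' median age 34 with IQR 30-40, minimum age 18.
#'
#' @param n Number of respondents.
#' @param female_proportion Proportion of women in \[0, 1\]. Sex is coded
#'   1 = female, 0 = male.
#' @param age_median,age_iqr Median and `c(lower, upper)` quartiles of age
#'   in years.
#' @param age_min Minimum age (truncation point).
#' @param sex_method `"quota"` assigns exactly `round(n * p)` women
#'   (reproducing a printed split exactly); `"bernoulli"` draws sex
#'   independently per respondent.
#' @return An object of class `demographic_spec`.
#' @export
demographic_spec <- function(n = 6057, female_proportion = 0.3999,
                             age_median = 34, age_iqr = c(30, 40),
                             age_min = 18,
                             sex_method = c("quota", "bernoulli")) {
  sex_method <- match.arg(sex_method)
  if (n < 1) abort("`n` must be positive.")
  if (female_proportion < 0 || female_proportion > 1) {
    abort("`female_proportion` must lie in [0, 1].")
  }
  if (length(age_iqr) != 2 || age_iqr[1] > age_median || age_median > age_iqr[2]) {
    abort("Need age_iqr[1] <= age_median <= age_iqr[2].")
  }
  if (age_min > age_iqr[1]) abort("`age_min` must not exceed the lower quartile.")
  structure(
    list(
      n = as.integer(n),
      female_proportion = female_proportion,
      age_median = age_median,
      age_iqr = as.numeric(age_iqr),
      age_min = age_min,
      sex_method = sex_method
    ),
    class = "demographic_spec"
  )
}

# Monotone map from standard-normal z to ages: piecewise linear in z with
# scales chosen so median and quartiles are exact; truncated below at
# age_min and rounded to whole years.
age_from_z <- function(z, demo) {
  q75 <- qnorm(0.75)
  s_lo <- (demo$age_median - demo$age_iqr[1]) / q75
  s_hi <- (demo$age_iqr[2] - demo$age_median) / q75
  age <- demo$age_median + ifelse(z < 0, s_lo, s_hi) * z
  pmax(demo$age_min, round(age))
}
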