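#' Simple mediation: point estimation
#'
#' Estimates the observed-variable mediation model X -> M -> Y with an
#' optional common covariate set in every equation:
#' * `a` from `M ~ X + covariates`,
#' * `b` and `c'` (direct effect) from `Y ~ X + M + covariates`,
#' * `c` (total effect) from `Y ~ X + covariates`.
#'
#' The indirect effect is the product `a * b` and the effect decomposition
#' `c = c' + a * b` holds exactly for least squares with a common covariate
#' set. The proportion mediated `100 * a * b / c` is reported only when
#' `|c|` exceeds `prop_floor`; otherwise it is `NA` with the reason
#' attached.
#'
#' @param data A data frame with complete cases on the used columns.
#' @param x,m,y Names of the predictor, mediator and outcome columns
#'   (distinct).
#' @param covariates Optional character vector of covariate columns,
#'   entered in every equation.
#' @param standardized Fit on z-scored variables? Default `FALSE`
#'   (unstandardized effects).
#' @param prop_floor Smallest `|c|` for which the proportion mediated is
#'   defined.
#' @return An object of class `mediation_fit`: `paths` (a, b, c, c_prime
#'   with SE, t, p), `effects` (total, direct, indirect), and
#'   `proportion_mediated` (percent). See [tidy()] / [glance()].
#' @seealso [bootstrap_effects()] for interval inference,
#'   [mediation_from_moments()] for the closed form given printed moments.
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 1000, seed = 1)
#' fit_mediation(d, x = "ct", m = "se", y = "phq9",
#'               covariates = c("age", "sex"))
fit_mediation <- function(data, x, m, y, covariates = NULL,
                          standardized = FALSE, prop_floor = 1e-8) {
  if (anyDuplicated(c(x, m, y))) abort("`x`, `m`, `y` must be distinct.")
  m_model <- ols_fit(data, m, c(x, covariates), standardized = standardized)
  y_model <- ols_fit(data, y, c(x, m, covariates), standardized = standardized)
  c_model <- ols_fit(data, y, c(x, covariates), standardized = standardized)
  pick <- function(fit, term) {
    r <- fit$coefficients[fit$coefficients$term == term, ]
    tibble(
      estimate = r$estimate, se = r$se,
      statistic = r$statistic, p.value = r$p.value
    )
  }
  paths <- dplyr::bind_rows(
    a = pick(m_model, x), b = pick(y_model, m),
    c = pick(c_model, x), c_prime = pick(y_model, x),
    .id = "path"
  )
  est <- setNames(paths$estimate, paths$path)
  indirect <- unname(est["a"] * est["b"])
  total <- unname(est["c"])
  prop <- if (abs(total) >= prop_floor) 100 * indirect / total else NA_real_
  effects <- tibble(
    effect = c("total", "direct", "indirect"),
    estimate = c(total, unname(est["c_prime"]), indirect)
  )
  structure(
    list(
      paths = paths, effects = effects, proportion_mediated = prop,
      proportion_defined = abs(total) >= prop_floor,
      models = list(m = m_model, y = y_model, total = c_model),
      spec = list(
        x = x, m = m, y = y, covariates = covariates,
        standardized = standardized, n = m_model$n
      )
    ),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  s <- x$spec
  cat("<mediation_fit> ", s$x, " -> ", s$m, " -> ", s$y,
    if (length(s$covariates)) {
      paste0("  | ", paste(s$covariates, collapse = ", "))
    },
    "  (n = ", s$n, ")\n",
    sep = ""
  )
  print(x$paths)
  print(x$effects)
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("proportion mediated: %.1f%%\n", x$proportion_mediated))
  }
  invisible(x)
}

#' Mediation effects from printed moments (closed form)
#'
#' Solves the mediation path coefficients directly from a moment
#' specification (means, SDs, correlation matrix) by the partial-regression
#' closed forms, without generating data: with `r_xm`, `r_xy`, `r_my` the
#' pairwise correlations and `s_x, s_m, s_y` the SDs,
#' `a = r_xm * s_m / s_x`,
#' `b = (r_my - r_xy * r_xm) / (1 - r_xm^2) * s_y / s_m`,
#' `c = r_xy * s_y / s_x`, `c' = c - a * b`.
#'
#' This reproduces what a least-squares fit would estimate on a dataset
#' whose sample moments equal the specification exactly, and is the
#' desk-scale route from a published descriptives table to the implied
#' unstandardized effects.
#'
#' @param spec A [moment_spec()] containing `x`, `m` and `y`.
#' @param x,m,y Variable names within the spec.
#' @param prop_floor As in [fit_mediation()].
#' @return A tibble with one row per quantity: `a`, `b`, `c`, `c_prime`,
#'   `total`, `direct`, `indirect`, `proportion_mediated`.
#' @export
#' @examples
#' mediation_from_moments(adult_survey_moments(), "ct", "se", "phq9")
mediation_from_moments <- function(spec, x, m, y, prop_floor = 1e-8) {
  stopifnot(inherits(spec, "moment_spec"))
  check_columns(
    setNames(as.list(spec$variables), spec$variables),
    c(x, m, y), "spec variable"
  )
  r_xm <- spec$corr[x, m]
  r_xy <- spec$corr[x, y]
  r_my <- spec$corr[m, y]
  s <- spec$sds
  a <- r_xm * s[[m]] / s[[x]]
  b <- (r_my - r_xy * r_xm) / (1 - r_xm^2) * s[[y]] / s[[m]]
  total <- r_xy * s[[y]] / s[[x]]
  indirect <- a * b
  direct <- total - indirect
  prop <- if (abs(total) >= prop_floor) 100 * indirect / total else NA_real_
  tibble(
    quantity = c(
      "a", "b", "c", "c_prime", "total", "direct", "indirect",
      "proportion_mediated"
    ),
    value = c(a, b, total, direct, total, direct, indirect, prop)
  )
}

#' Bootstrap confidence bounds for a statistic
#'
#' Percentile and bias-corrected percentile bounds from a vector of
#' bootstrap replicates. Percentile bounds are the `alpha/2` and
#' `1 - alpha/2` empirical quantiles (order statistics with linear
#' interpolation). Bias-corrected bounds shift the quantile positions to
#' `pnorm(2 * z0 + qnorm(alpha/2))` and `pnorm(2 * z0 + qnorm(1 - alpha/2))`
#' where `z0 = qnorm(P(boot < point))`, replicates exactly equal to the
#' point estimate counting one half (a continuity correction that keeps the
#' probit finite under heavy ties). With `z0 = 0` the two methods coincide
#' exactly.
#'
#' @param values Numeric vector of bootstrap replicates.
#' @param point The point estimate on the original sample.
#' @param level Confidence level, default 0.95.
#' @param method `"bias_corrected"` or `"percentile"`.
#' @return A one-row tibble: `lower`, `upper`, `z0`, `level`, `method`,
#'   `n_boot`.
#' @export
#' @examples
#' bootstrap_interval(rnorm(1000), point = 0)
bootstrap_interval <- function(values, point, level = 0.95,
                               method = c("bias_corrected", "percentile")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  b <- length(values)
  if (b < 2) abort("Need at least 2 finite bootstrap replicates.")
  alpha <- 1 - level
  if (method == "percentile") {
    z0 <- 0
    probs <- c(alpha / 2, 1 - alpha / 2)
  } else {
    p_below <- (sum(values < point) + 0.5 * sum(values == point)) / b
    # guard the probit against an empty/full tail
    p_below <- min(max(p_below, 1 / (2 * b)), 1 - 1 / (2 * b))
    z0 <- qnorm(p_below)
    probs <- pnorm(2 * z0 + qnorm(c(alpha / 2, 1 - alpha / 2)))
  }
  bounds <- boot_quantile(values, probs)
  tibble(
    lower = bounds[1], upper = bounds[2], z0 = z0, level = level,
    method = method, n_boot = b
  )
}

# Fast path-coefficient computation used inside bootstrap loops: plain
# normal-equation solves on prebuilt design matrices.
mediation_paths_fast <- function(xm, mm, xy, yy, xc, yv) {
  fm <- .lm.fit(xm, mm)
  fy <- .lm.fit(xy, yy)
  fc <- .lm.fit(xc, yv)
  if (fm$rank < ncol(xm) || fy$rank < ncol(xy) || fc$rank < ncol(xc)) {
    return(NULL)
  }
  c(
    a = fm$coefficients[2], b = fy$coefficients[3],
    c = fc$coefficients[2], c_prime = fy$coefficients[2]
  )
}

#' Bootstrap inference for mediation effects
#'
#' Nonparametric bootstrap of [fit_mediation()]: whole rows are resampled
#' with replacement (size n), the three regressions are refit on each
#' resample, and percentile or bias-corrected percentile intervals (see
#' [bootstrap_interval()]) are formed for the paths `a` and `b` and the
#' total, direct and indirect effects. The reported `z` is the point
#' estimate divided by the bootstrap SE by default; a first-order delta
#' (Sobel) SE for the indirect effect is available with
#' `se_method = "delta"`.
#'
#' A rank-deficient resample is redrawn (and counted in attribute
#' `n_redrawn` of the result).
#'
#' @inheritParams fit_mediation
#' @param n_boot Number of bootstrap resamples (>= 1000 recommended for
#'   inference; smaller values are for quick checks).
#' @param method Interval type, `"bias_corrected"` (default) or
#'   `"percentile"`.
#' @param level Confidence level.
#' @param seed Integer seed; the same seed reproduces intervals exactly.
#' @param se_method SE for the `z` column: `"bootstrap"` (default) or
#'   `"delta"` (Sobel, indirect effect only).
#' @param keep_boot Keep the matrix of bootstrap replicates (attribute
#'   `boot`)? Default `TRUE`.
#' @return An object of class `mediation_boot`: the point `fit` plus a
#'   tibble `intervals` with `effect`, `estimate`, `boot_se`, `z`,
#'   `lower`, `upper`, `z0`, `stars`.
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 400, seed = 1)
#' bootstrap_effects(d, "ct", "se", "phq9", covariates = c("age", "sex"),
#'                   n_boot = 200, seed = 7)
bootstrap_effects <- function(data, x, m, y, covariates = NULL,
                              n_boot = 5000,
                              method = c("bias_corrected", "percentile"),
                              level = 0.95, seed = NULL,
                              standardized = FALSE,
                              se_method = c("bootstrap", "delta"),
                              keep_boot = TRUE) {
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  fit <- fit_mediation(data, x, m, y,
    covariates = covariates,
    standardized = standardized
  )
  cols <- c(x, m, y, covariates)
  d <- as.data.frame(data)[cols]
  check_complete(d, cols)
  dm <- as.matrix(d)
  n <- nrow(d)
  nc <- length(covariates)
  boot <- matrix(NA_real_, n_boot, 5,
    dimnames = list(NULL, c("a", "b", "total", "direct", "indirect"))
  )
  n_redrawn <- 0L
  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        db <- dm[idx, , drop = FALSE]
        if (standardized) {
          if (any(apply(db, 2, sd) == 0)) {
            n_redrawn <- n_redrawn + 1L
            next
          }
          db <- scale(db)
        }
        cv <- if (nc) db[, covariates, drop = FALSE] else NULL
        xm <- cbind(1, db[, x], cv)
        xy <- cbind(1, db[, x], db[, m], cv)
        pp <- mediation_paths_fast(xm, db[, m], xy, db[, y], xm, db[, y])
        if (!is.null(pp)) break
        n_redrawn <- n_redrawn + 1L
      }
      boot[bi, ] <- c(
        pp["a"], pp["b"], pp["c"], pp["c_prime"],
        pp["a"] * pp["b"]
      )
    }
  })
  point <- c(
    a = fit$paths$estimate[fit$paths$path == "a"],
    b = fit$paths$estimate[fit$paths$path == "b"],
    total = fit$effects$estimate[fit$effects$effect == "total"],
    direct = fit$effects$estimate[fit$effects$effect == "direct"],
    indirect = fit$effects$estimate[fit$effects$effect == "indirect"]
  )
  intervals <- purrr::map_dfr(colnames(boot), function(ef) {
    ci <- bootstrap_interval(boot[, ef], point[[ef]],
      level = level, method = method
    )
    boot_se <- sd(boot[, ef])
    se_z <- if (ef == "indirect" && se_method == "delta") {
      sa <- fit$paths$se[fit$paths$path == "a"]
      sb <- fit$paths$se[fit$paths$path == "b"]
      sqrt(point[["a"]]^2 * sb^2 + point[["b"]]^2 * sa^2)
    } else {
      boot_se
    }
    tibble(
      effect = ef, estimate = point[[ef]], boot_se = boot_se,
      z = point[[ef]] / se_z, lower = ci$lower, upper = ci$upper,
      z0 = ci$z0
    )
  })
  intervals$stars <- ifelse(
    intervals$lower > 0 | intervals$upper < 0, "*", ""
  )
  structure(
    list(
      fit = fit, intervals = intervals,
      proportion_mediated = fit$proportion_mediated,
      settings = list(
        n_boot = n_boot, method = method, level = level, seed = seed,
        se_method = se_method, n = n
      )
    ),
    class = "mediation_boot",
    boot = if (keep_boot) boot,
    n_redrawn = n_redrawn
  )
}

#' @export
print.mediation_boot <- function(x, ...) {
  s <- x$settings
  cat("<mediation_boot> ", s$method, " ", round(100 * s$level),
    "% CIs, ", s$n_boot, " resamples, n = ", s$n, "\n",
    sep = ""
  )
  print(x$intervals)
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("proportion mediated: %.1f%%\n", x$proportion_mediated))
  }
  invisible(x)
}
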