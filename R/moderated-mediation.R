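#' Fit the two stage models of a moderated mediation analysis
#'
#' Hierarchical least-squares fits for first- and second-stage moderated
#' mediation on standardized variables. The first stage regresses the
#' mediator; the second stage regresses the outcome:
#' * stage one: `M ~ covariates | + X + W | + X:W`
#' * stage two: `Y ~ covariates | + X + W + M | + M:W`
#'
#' with `|` separating the hierarchical blocks (control variables, main
#' effects, moderator products). The interaction block is entered only for
#' the stages named in `moderated_stages`; `"none"` fits both stages
#' without products (useful for consistency checks against simple
#' mediation).
#'
#' @param data A data frame with complete cases on the used columns.
#' @param x,m,y,w Names of predictor, mediator, outcome and moderator
#'   columns (distinct).
#' @param covariates Optional covariate columns, entered as block 1 of
#'   both stages.
#' @param moderated_stages Which stage receives its interaction term:
#'   `"both"` (default), `"first"`, `"second"`, or `"none"`.
#' @param w_second Optional distinct moderator for the second stage;
#'   defaults to `w` (one shared moderator, the common design).
#' @param standardized Fit on z-scored variables. Default `TRUE`, which
#'   makes moderator values -1/0/+1 exactly one SD below/at/above the
#'   mean.
#' @return An object of class `stage_models`: `first` and `second`
#'   ([hierarchical_fit()] objects), extracted path coefficients
#'   `$coefficients` (`a`, `a_int`, `b`, `b_int`, absent interactions
#'   reported as 0 with a flag), and the call spec.
#' @seealso [simple_effects()], [bootstrap_conditional()]
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 500, seed = 1)
#' fits <- fit_stage_models(d, x = "ct", m = "se", y = "phq9", w = "es",
#'                          covariates = c("age", "sex"))
#' fits$coefficients
fit_stage_models <- function(data, x, m, y, w, covariates = NULL,
                             moderated_stages = c("both", "first", "second", "none"),
                             w_second = w, standardized = TRUE) {
  moderated_stages <- match.arg(moderated_stages)
  if (anyDuplicated(c(x, m, y, w))) {
    abort("`x`, `m`, `y`, `w` must be distinct columns.")
  }
  mod_first <- moderated_stages %in% c("both", "first")
  mod_second <- moderated_stages %in% c("both", "second")

  blocks1 <- list(c(x, w))
  if (mod_first) blocks1 <- c(blocks1, list(paste0(x, ":", w)))
  blocks2 <- list(c(x, w_second, m))
  if (mod_second) blocks2 <- c(blocks2, list(paste0(m, ":", w_second)))
  if (length(covariates)) {
    blocks1 <- c(list(covariates), blocks1)
    blocks2 <- c(list(covariates), blocks2)
  }

  first <- hierarchical_fit(data, m, blocks1, standardized = standardized)
  second <- hierarchical_fit(data, y, blocks2, standardized = standardized)

  coef_of <- function(hf, term) {
    cf <- hf$steps[[length(hf$steps)]]$coefficients
    row <- cf[cf$term == term, ]
    if (nrow(row) == 0) 0 else row$estimate
  }
  coefficients <- list(
    a = coef_of(first, x),
    a_int = if (mod_first) coef_of(first, paste0(x, ":", w)) else 0,
    b = coef_of(second, m),
    b_int = if (mod_second) coef_of(second, paste0(m, ":", w_second)) else 0,
    first_moderated = mod_first,
    second_moderated = mod_second
  )
  structure(
    list(
      first = first, second = second, coefficients = coefficients,
      spec = list(
        x = x, m = m, y = y, w = w, w_second = w_second,
        covariates = covariates, moderated_stages = moderated_stages,
        standardized = standardized, n = first$steps[[1]]$n
      )
    ),
    class = "stage_models"
  )
}

#' @export
print.stage_models <- function(x, ...) {
  s <- x$spec
  cat("<stage_models> ", s$x, " -> ", s$m, " -> ", s$y,
    ", moderator ", s$w,
    if (!identical(s$w, s$w_second)) paste0(" / ", s$w_second),
    " (", s$moderated_stages, ")\n",
    sep = ""
  )
  cf <- x$coefficients
  cat(sprintf(
    "  a = %.4f, a_int = %.4f, b = %.4f, b_int = %.4f\n",
    cf$a, cf$a_int, cf$b, cf$b_int
  ))
  cat("First stage increments:\n")
  print(x$first$increments)
  cat("Second stage increments:\n")
  print(x$second$increments)
  invisible(x)
}

# Core arithmetic of the conditional-effect table, shared by the point
# estimate and every bootstrap resample. Under the linear-interaction
# model effect(w) = main + w * interaction, so the high-minus-low
# difference is (w_hi - w_lo) * interaction exactly.
conditional_table_values <- function(a, a_int, b, b_int, levels) {
  first <- a + levels * a_int
  second <- b + levels * b_int
  indirect <- first * second
  hi <- length(levels)
  c(
    first, second, indirect,
    first[hi] - first[1], second[hi] - second[1],
    indirect[hi] - indirect[1]
  )
}

#' Simple effects and conditional indirect effects across moderator levels
#'
#' Evaluates the first-stage simple effect `a + w * a_int`, the
#' second-stage simple effect `b + w * b_int`, and their product (the
#' conditional indirect effect) at each moderator level, plus the
#' high-minus-low difference of each column. Levels default to
#' `c(-1, 0, 1)`: one SD below the mean, the mean, and one SD above on the
#' standardized scale.
#'
#' @param fits A [fit_stage_models()] result.
#' @param levels Moderator values at which to evaluate, increasing;
#'   default `c(-1, 0, 1)`.
#' @return An object of class `conditional_effects`: tibble `table` with
#'   `level` (low/mean/high), `w`, `first_stage`, `second_stage`,
#'   `indirect`, and tibble `differences` (high minus low per column).
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 500, seed = 1)
#' fits <- fit_stage_models(d, "ct", "se", "phq9", "es",
#'                          covariates = c("age", "sex"))
#' simple_effects(fits)
simple_effects <- function(fits, levels = c(-1, 0, 1)) {
  stopifnot(inherits(fits, "stage_models"))
  if (length(levels) < 2 || is.unsorted(levels, strictly = TRUE)) {
    abort("`levels` must be at least two strictly increasing values.")
  }
  cf <- fits$coefficients
  vals <- conditional_table_values(cf$a, cf$a_int, cf$b, cf$b_int, levels)
  nl <- length(levels)
  lab <- if (nl == 3) {
    c("low", "mean", "high")
  } else {
    paste0("w", seq_len(nl))
  }
  table <- tibble(
    level = lab, w = levels,
    first_stage = vals[seq_len(nl)],
    second_stage = vals[nl + seq_len(nl)],
    indirect = vals[2 * nl + seq_len(nl)]
  )
  differences <- tibble(
    quantity = c("first_stage", "second_stage", "indirect"),
    difference = vals[3 * nl + 1:3]
  )
  structure(
    list(table = table, differences = differences, levels = levels,
         spec = fits$spec),
    class = "conditional_effects"
  )
}

#' @export
print.conditional_effects <- function(x, ...) {
  cat("<conditional_effects> moderator ", x$spec$w, "\n", sep = "")
  print(x$table)
  cat("High - low differences:\n")
  print(x$differences)
  invisible(x)
}

#' Bootstrap inference for conditional indirect effects
#'
#' Nonparametric bootstrap of the full conditional-effect table: whole rows
#' are resampled with replacement; on each resample the variables are
#' re-standardized, the final-step stage models are refit, and the simple
#' effects, conditional indirect effects and high-minus-low differences
#' are recomputed. Percentile or bias-corrected percentile intervals (see
#' [bootstrap_interval()]) are attached to every cell; an effect is
#' flagged significant when its interval excludes zero.
#'
#' @inheritParams fit_stage_models
#' @inheritParams bootstrap_effects
#' @param levels Moderator values as in [simple_effects()].
#' @return An object of class `conditional_boot`: the point
#'   [simple_effects()] table, tibble `intervals` with one row per cell
#'   (`quantity`, `level`, `estimate`, `boot_se`, `lower`, `upper`, `z0`,
#'   `significant`, `stars`), and the settings. Attribute `n_redrawn`
#'   counts redrawn degenerate resamples.
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), 400, seed = 1)
#' bootstrap_conditional(d, "ct", "se", "phq9", "es",
#'                       covariates = c("age", "sex"),
#'                       n_boot = 200, seed = 7)
bootstrap_conditional <- function(data, x, m, y, w, covariates = NULL,
                                  moderated_stages = c("both", "first", "second", "none"),
                                  w_second = w,
                                  levels = c(-1, 0, 1),
                                  n_boot = 5000,
                                  method = c("bias_corrected", "percentile"),
                                  level = 0.95, seed = NULL,
                                  standardized = TRUE,
                                  keep_boot = FALSE) {
  moderated_stages <- match.arg(moderated_stages)
  method <- match.arg(method)
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  fits <- fit_stage_models(data, x, m, y, w,
    covariates = covariates, moderated_stages = moderated_stages,
    w_second = w_second, standardized = standardized
  )
  point <- simple_effects(fits, levels = levels)
  mod_first <- fits$coefficients$first_moderated
  mod_second <- fits$coefficients$second_moderated

  cols <- unique(c(x, m, y, w, w_second, covariates))
  d <- as.data.frame(data)[cols]
  check_complete(d, cols)
  dm <- as.matrix(d)
  n <- nrow(d)
  nl <- length(levels)
  n_cells <- 3 * nl + 3
  boot <- matrix(NA_real_, n_boot, n_cells)
  n_redrawn <- 0L

  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        db <- dm[idx, , drop = FALSE]
        ok <- !standardized || all(apply(db, 2, sd) > 0)
        if (ok) {
          if (standardized) db <- scale(db)
          cv <- if (length(covariates)) db[, covariates, drop = FALSE] else NULL
          x1 <- cbind(1, db[, x], db[, w], cv)
          if (mod_first) x1 <- cbind(x1, db[, x] * db[, w])
          x2 <- cbind(1, db[, x], db[, w_second], db[, m], cv)
          if (mod_second) x2 <- cbind(x2, db[, m] * db[, w_second])
          f1 <- .lm.fit(x1, db[, m])
          f2 <- .lm.fit(x2, db[, y])
          ok <- f1$rank == ncol(x1) && f2$rank == ncol(x2)
        }
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      a_b <- f1$coefficients[2]
      a_int_b <- if (mod_first) f1$coefficients[ncol(x1)] else 0
      b_b <- f2$coefficients[4]
      b_int_b <- if (mod_second) f2$coefficients[ncol(x2)] else 0
      boot[bi, ] <- conditional_table_values(a_b, a_int_b, b_b, b_int_b, levels)
    }
  })

  lab <- point$table$level
  cell_names <- c(
    paste0("first_stage@", lab), paste0("second_stage@", lab),
    paste0("indirect@", lab),
    "diff_first_stage", "diff_second_stage", "diff_indirect"
  )
  point_vals <- with(
    point,
    c(table$first_stage, table$second_stage, table$indirect,
      differences$difference)
  )
  intervals <- purrr::map_dfr(seq_len(n_cells), function(j) {
    ci <- bootstrap_interval(boot[, j], point_vals[j],
      level = level, method = method
    )
    tibble(
      quantity = sub("@.*$", "", cell_names[j]),
      level = ifelse(grepl("@", cell_names[j]),
        sub("^.*@", "", cell_names[j]), "high - low"
      ),
      estimate = point_vals[j], boot_se = sd(boot[, j]),
      lower = ci$lower, upper = ci$upper, z0 = ci$z0
    )
  })
  intervals$significant <- intervals$lower > 0 | intervals$upper < 0
  intervals$stars <- ifelse(intervals$significant, "*", "")
  colnames(boot) <- cell_names
  structure(
    list(
      fits = fits, point = point, intervals = intervals,
      settings = list(
        n_boot = n_boot, method = method, level = level, seed = seed,
        levels = levels, n = n, moderated_stages = moderated_stages
      )
    ),
    class = "conditional_boot",
    boot = if (keep_boot) boot,
    n_redrawn = n_redrawn
  )
}

#' @export
print.conditional_boot <- function(x, ...) {
  s <- x$settings
  cat("<conditional_boot> ", s$method, " ", round(100 * s$level),
    "% CIs, ", s$n_boot, " resamples, n = ", s$n, "\n",
    sep = ""
  )
  print(x$intervals, n = Inf)
  invisible(x)
}

#' Subgroup (dichotomized-moderator) mediation comparison
#'
#' The subgroup alternative to the full-sample interaction fit: the sample
#' is split at the moderator mean (or median), an unmoderated mediation is
#' fit within each subgroup, and per-subgroup paths and indirect effects
#' are reported. Dichotomization loses information relative to the
#' interaction model and the two approaches can disagree; the full-sample
#' fit is the package default and this function exists to reproduce the
#' comparison.
#'
#' @inheritParams fit_stage_models
#' @param split `"mean"` (default) or `"median"` split of the moderator.
#' @param standardized Standardize within each subgroup? Default `FALSE`
#'   (raw coefficients are comparable across subgroups).
#' @return A tibble with one row per subgroup: `subgroup`, `n`, `a`, `b`,
#'   `indirect`, `total`, `direct`.
#' @export
subgroup_effects <- function(data, x, m, y, w, covariates = NULL,
                             split = c("mean", "median"),
                             standardized = FALSE) {
  split <- match.arg(split)
  check_columns(data, c(x, m, y, w, covariates))
  cut_at <- if (split == "mean") mean(data[[w]]) else median(data[[w]])
  grp <- ifelse(data[[w]] >= cut_at, "high", "low")
  purrr::map_dfr(c("low", "high"), function(gl) {
    dg <- data[grp == gl, , drop = FALSE]
    fit <- fit_mediation(dg, x, m, y,
      covariates = covariates, standardized = standardized
    )
    est <- setNames(fit$paths$estimate, fit$paths$path)
    tibble(
      subgroup = gl, n = nrow(dg),
      a = unname(est["a"]), b = unname(est["b"]),
      indirect = unname(est["a"] * est["b"]),
      total = unname(est["c"]), direct = unname(est["c_prime"])
    )
  })
}
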