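# broom-style tidy()/glance() methods for the package's fitted objects.

#' @rdname modmedr-tidiers
#' @export
tidy.ols_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname modmedr-tidiers
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(
    r.squared = x$r.squared, statistic = x$fstatistic,
    df1 = x$df1, df2 = x$df2, p.value = x$p.value,
    sigma = x$sigma, n = x$n
  )
}

#' Tidy and glance methods for modmedr results
#'
#' broom-style accessors. `tidy()` returns the per-term, per-path or
#' per-cell table of an object; `glance()` returns its one-row model
#' summary.
#'
#' * `ols_fit`: coefficients / fit statistics.
#' * `hier_fit`: coefficients of every step (`type = "coefficients"`) or
#'   the block increments with delta R-squared and incremental F
#'   (`type = "increments"`).
#' * `mediation_fit`: paths a, b, c, c' / effects with proportion
#'   mediated.
#' * `mediation_boot`: effect estimates with bootstrap z and confidence
#'   bounds.
#' * `conditional_effects` / `conditional_boot`: the simple-effect table
#'   (with intervals when bootstrapped).
#'
#' @param x A fitted modmedr object.
#' @param type For `hier_fit`, which table to return.
#' @param ... Unused.
#' @return A tibble.
#' @name modmedr-tidiers
NULL

#' @rdname modmedr-tidiers
#' @export
tidy.hier_fit <- function(x, type = c("coefficients", "increments"), ...) {
  type <- match.arg(type)
  if (type == "increments") {
    return(x$increments)
  }
  purrr::map_dfr(seq_along(x$steps), function(i) {
    dplyr::mutate(x$steps[[i]]$coefficients, step = i, .before = 1)
  })
}

#' @rdname modmedr-tidiers
#' @export
glance.hier_fit <- function(x, ...) {
  last <- x$steps[[length(x$steps)]]
  dplyr::mutate(glance(last), n_blocks = length(x$blocks))
}

#' @rdname modmedr-tidiers
#' @export
tidy.mediation_fit <- function(x, ...) {
  dplyr::mutate(x$paths, stars = signif_stars(.data$p.value))
}

#' @rdname modmedr-tidiers
#' @export
glance.mediation_fit <- function(x, ...) {
  est <- setNames(x$effects$estimate, x$effects$effect)
  tibble(
    total = unname(est["total"]), direct = unname(est["direct"]),
    indirect = unname(est["indirect"]),
    proportion_mediated = x$proportion_mediated, n = x$spec$n
  )
}

#' @rdname modmedr-tidiers
#' @export
tidy.mediation_boot <- function(x, ...) {
  x$intervals
}

#' @rdname modmedr-tidiers
#' @export
glance.mediation_boot <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
    n_boot = x$settings$n_boot, method = x$settings$method,
    level = x$settings$level
  )
}

#' @rdname modmedr-tidiers
#' @export
tidy.conditional_effects <- function(x, ...) {
  x$table
}

#' @rdname modmedr-tidiers
#' @export
tidy.conditional_boot <- function(x, ...) {
  x$intervals
}

#' @rdname modmedr-tidiers
#' @export
glance.conditional_boot <- function(x, ...) {
  s <- x$settings
  tibble(
    n = s$n, n_boot = s$n_boot, method = s$method, level = s$level,
    moderated_stages = s$moderated_stages,
    a = x$fits$coefficients$a, a_int = x$fits$coefficients$a_int,
    b = x$fits$coefficients$b, b_int = x$fits$coefficients$b_int
  )
}

#' @rdname modmedr-tidiers
#' @export
tidy.pearson_matrix <- function(x, ...) {
  vars <- rownames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
    r = x$r[pairs], p.value = x$p[pairs],
    stars = signif_stars(x$p[pairs]), n = x$n
  )
}
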