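#' Generate scale-level survey data from a moment specification
#'
#' Draws `n` respondents from a multivariate normal whose population means,
#' standard deviations and correlations equal the (positive-definite
#' repaired) specification, and appends demographics. A standardized `age`
#' column in the specification is mapped through the monotone age transform
#' of `demographics`, so its printed correlations with the outcomes carry
#' over (up to the slight attenuation of a monotone margin transform); `sex`
#' is appended independently of the scales, reflecting the null sex
#' differences the generator emulates.
#'
#' @param spec A [moment_spec()].
#' @param n Number of respondents (>= 2).
#' @param seed Integer seed; identical seed and spec give byte-identical
#'   datasets. `NULL` uses (and advances) the current RNG stream.
#' @param demographics A [demographic_spec()], or `NULL` to omit `age`/`sex`
#'   columns that are not in the spec.
#' @param pd_floor Eigenvalue floor for [repair_correlation_matrix()].
#' @return A tibble with columns `id`, (optionally) `age`, `sex`, and one
#'   column per spec variable, with attributes `spec`, `seed` and
#'   `repair_delta`.
#' @export
#' @examples
#' d <- generate_scale_level(adult_survey_moments(), n = 500, seed = 1)
#' cor(d$ct, d$se)
generate_scale_level <- function(spec, n, seed = NULL,
                                 demographics = demographic_spec(n = n),
                                 pd_floor = 1e-6) {
  stopifnot(inherits(spec, "moment_spec"))
  if (n < 2) abort("`n` must be at least 2.")
  n <- as.integer(n)
  corr <- repair_correlation_matrix(spec$corr, floor = pd_floor)
  k <- length(spec$variables)
  with_seed(seed, {
    z <- matrix(rnorm(n * k), n, k) %*% chol(corr)
    colnames(z) <- spec$variables
    out <- tibble(id = seq_len(n))
    if (!is.null(demographics)) {
      age_z <- if ("age" %in% spec$variables) z[, "age"] else rnorm(n)
      out$age <- age_from_z(age_z, demographics)
      out$sex <- draw_sex(n, demographics)
    }
    for (v in setdiff(spec$variables, "age")) {
      out[[v]] <- spec$means[[v]] + spec$sds[[v]] * z[, v]
    }
    structure(out,
      spec = spec, seed = seed,
      repair_delta = attr(corr, "repair_delta")
    )
  })
}

draw_sex <- function(n, demo) {
  if (demo$sex_method == "quota") {
    n_f <- round(n * demo$female_proportion)
    sex <- c(rep(1L, n_f), rep(0L, n - n_f))
    sample(sex)
  } else {
    as.integer(stats::runif(n) < demo$female_proportion)
  }
}

#' Item-battery specification
#'
#' Describes a Likert item battery with a compound-symmetric latent
#' structure: every pair of items shares the same latent correlation `rho`,
#' which implies Cronbach's alpha `k * rho / (1 + (k - 1) * rho)` for the
#' continuous battery. Discretizing to Likert categories attenuates the
#' realized alpha; `rho_inflation` can be added to `rho` at draw time to
#' compensate (off by default).
#'
#' @param n_items Number of items (>= 2).
#' @param inter_item_corr Common latent inter-item correlation in \[0, 1).
#' @param likert_min,likert_max Integer response bounds.
#' @param thresholds Strictly increasing cut points on the latent standard
#'   normal scale, length `likert_max - likert_min`. Default: equal
#'   probability categories.
#' @param rho_inflation Amount added to `inter_item_corr` before drawing,
#'   to counter discretization attenuation. Default 0.
#' @return An object of class `item_battery_spec`.
#' @export
#' @examples
#' sp <- item_battery_spec(28, 0.222, 1, 5)
#' implied_alpha(sp) # ~0.889
item_battery_spec <- function(n_items, inter_item_corr,
                              likert_min = 1L, likert_max = 5L,
                              thresholds = NULL, rho_inflation = 0) {
  if (n_items < 2) abort("`n_items` must be at least 2.")
  if (inter_item_corr < 0 || inter_item_corr >= 1) {
    abort("`inter_item_corr` must lie in [0, 1).")
  }
  likert_min <- as.integer(likert_min)
  likert_max <- as.integer(likert_max)
  if (likert_min >= likert_max) abort("Need likert_min < likert_max.")
  n_cut <- likert_max - likert_min
  if (is.null(thresholds)) {
    thresholds <- qnorm(seq_len(n_cut) / (n_cut + 1))
  }
  if (length(thresholds) != n_cut) {
    abort("`thresholds` must have length likert_max - likert_min.")
  }
  if (any(diff(thresholds) <= 0)) abort("`thresholds` must be strictly increasing.")
  if (any(!is.finite(thresholds))) {
    abort("`thresholds` must be finite (inside the latent support).")
  }
  rho_eff <- inter_item_corr + rho_inflation
  if (rho_eff < 0 || rho_eff >= 1) {
    abort("`inter_item_corr + rho_inflation` must lie in [0, 1).")
  }
  spec <- structure(
    list(
      n_items = as.integer(n_items), inter_item_corr = inter_item_corr,
      likert_min = likert_min, likert_max = likert_max,
      thresholds = as.numeric(thresholds), rho_inflation = rho_inflation
    ),
    class = "item_battery_spec"
  )
  a <- implied_alpha(spec)
  if (!(a > 0 && a < 1) && inter_item_corr > 0) {
    abort("Implied Cronbach's alpha must lie in (0, 1).")
  }
  spec
}

#' Cronbach's alpha implied by a compound-symmetric battery
#'
#' @param spec An [item_battery_spec()].
#' @return `k * rho / (1 + (k - 1) * rho)`.
#' @export
implied_alpha <- function(spec) {
  stopifnot(inherits(spec, "item_battery_spec"))
  k <- spec$n_items
  rho <- spec$inter_item_corr
  k * rho / (1 + (k - 1) * rho)
}

#' Generate an item response battery
#'
#' Draws latent standard-normal item scores with the compound-symmetric
#' correlation of `spec` and (by default) discretizes them at the spec's
#' thresholds into integer Likert responses.
#'
#' @param spec An [item_battery_spec()].
#' @param n Number of respondents.
#' @param seed Integer seed, or `NULL`.
#' @param discretize If `FALSE`, return the continuous latent scores
#'   (useful for checking the closed-form alpha without attenuation).
#' @param item_prefix Column name prefix, default `"item"`.
#' @return A tibble of `n` rows and `spec$n_items` columns
#'   (`item_01`, ...), integer when discretized.
#' @export
#' @examples
#' x <- generate_item_level(item_battery_spec(10, 0.4), n = 200, seed = 1)
#' cronbach_alpha(x)
generate_item_level <- function(spec, n, seed = NULL, discretize = TRUE,
                                item_prefix = "item") {
  stopifnot(inherits(spec, "item_battery_spec"))
  if (n < 1) abort("`n` must be positive.")
  n <- as.integer(n)
  k <- spec$n_items
  rho <- spec$inter_item_corr + spec$rho_inflation
  with_seed(seed, {
    # compound-symmetric draw via one common factor plus unique parts
    common <- rnorm(n)
    uniq <- matrix(rnorm(n * k), n, k)
    z <- sqrt(rho) * common + sqrt(1 - rho) * uniq
    if (discretize) {
      z <- matrix(
        spec$likert_min +
          findInterval(z, spec$thresholds),
        n, k
      )
      storage.mode(z) <- "integer"
    }
    colnames(z) <- sprintf(
      "%s_%02d", item_prefix, seq_len(k)
    )
    as_tibble(z)
  })
}

#' Structural (path-model) specification
#'
#' The data-generating model for recovery studies of the moderated
#' mediation machinery, on standardized predictors:
#' \deqn{m = a x + a_w x w + g_m w + e_m, \quad
#'       y = c' x + b m + b_w m w + g_y w + e_y}
#' with `x` and `w` independent standard normal and Gaussian residuals.
#' With `a_w = b_w = 0` the model reduces to simple mediation.
#'
#' @param a Effect of `x` on the mediator `m` (first stage).
#' @param b Effect of `m` on the outcome `y` given `x` (second stage).
#' @param c_prime Direct effect of `x` on `y` given `m`.
#' @param a_w First-stage moderation (`x * w` on `m`).
#' @param b_w Second-stage moderation (`m * w` on `y`).
#' @param w_on_m,w_on_y Moderator main effects.
#' @param sd_m,sd_y Strictly positive residual standard deviations.
#' @return An object of class `structural_spec`.
#' @export
structural_spec <- function(a, b, c_prime, a_w = 0, b_w = 0,
                            w_on_m = 0, w_on_y = 0, sd_m = 1, sd_y = 1) {
  if (sd_m <= 0 || sd_y <= 0) abort("Residual SDs must be strictly positive.")
  structure(
    list(
      a = a, b = b, c_prime = c_prime, a_w = a_w, b_w = b_w,
      w_on_m = w_on_m, w_on_y = w_on_y, sd_m = sd_m, sd_y = sd_y
    ),
    class = "structural_spec"
  )
}

#' Generate data from a structural path model
#'
#' @param spec A [structural_spec()].
#' @param n Number of observations.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with columns `x`, `w`, `m`, `y` and the generating
#'   parameters attached as attribute `true_params` for recovery tests.
#' @export
#' @examples
#' d <- generate_structural(structural_spec(-0.4, -0.25, 0.2), 1000, seed = 1)
#' attr(d, "true_params")$a
generate_structural <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "structural_spec"))
  if (n < 2) abort("`n` must be at least 2.")
  n <- as.integer(n)
  with_seed(seed, {
    x <- rnorm(n)
    w <- rnorm(n)
    m <- spec$a * x + spec$a_w * x * w + spec$w_on_m * w +
      rnorm(n, sd = spec$sd_m)
    y <- spec$c_prime * x + spec$b * m + spec$b_w * m * w +
      spec$w_on_y * w + rnorm(n, sd = spec$sd_y)
    structure(tibble(x = x, w = w, m = m, y = y), true_params = spec)
  })
}

#' Covariance of (x, w, m, y) implied by an unmoderated structural spec
#'
#' Closed-form population covariance of the structural generator when both
#' interaction coefficients are zero; in that case the structural generator
#' has exactly the covariance a [moment_spec()] built from this matrix
#' would target.
#'
#' @param spec A [structural_spec()] with `a_w = b_w = 0`.
#' @return A 4x4 covariance matrix over `x`, `w`, `m`, `y`.
#' @export
structural_covariance <- function(spec) {
  stopifnot(inherits(spec, "structural_spec"))
  if (spec$a_w != 0 || spec$b_w != 0) {
    abort("Closed-form covariance requires a_w = b_w = 0.")
  }
  a <- spec$a
  b <- spec$b
  cp <- spec$c_prime
  gm <- spec$w_on_m
  gy <- spec$w_on_y
  v_m <- a^2 + gm^2 + spec$sd_m^2
  # y = (cp + b a) x + (gy + b gm) w + b e_m + e_y
  cy_x <- cp + b * a
  cy_w <- gy + b * gm
  v_y <- cy_x^2 + cy_w^2 + b^2 * spec$sd_m^2 + spec$sd_y^2
  cov_m_y <- cy_x * a + cy_w * gm + b * spec$sd_m^2
  out <- matrix(c(
    1, 0, a, cy_x,
    0, 1, gm, cy_w,
    a, gm, v_m, cov_m_y,
    cy_x, cy_w, cov_m_y, v_y
  ), 4, 4, dimnames = list(c("x", "w", "m", "y"), c("x", "w", "m", "y")))
  out
}

#' Write a synthetic dataset as CSV with a sidecar JSON
#'
#' Writes the data with a header row and a `<path>.json` sidecar recording
#' the generating spec, seed and positive-definite repair delta, so a
#' dataset on disk is always traceable to its generator call.
#'
#' @param data A tibble from [generate_scale_level()] (or compatible).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(data, path) {
  readr::write_csv(data, path)
  spec <- attr(data, "spec")
  side <- list(
    seed = attr(data, "seed"),
    repair_delta = attr(data, "repair_delta"),
    n = nrow(data)
  )
  if (!is.null(spec)) {
    side$spec <- list(
      variables = spec$variables,
      means = unname(spec$means),
      sds = unname(spec$sds),
      corr = unclass(spec$corr)
    )
  }
  jsonlite::write_json(side, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
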