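#' Configuration for a full analysis run
#'
#' Bundles everything [run_full_analysis()] needs: the input source (a CSV
#' path, an in-memory data frame, or a [moment_spec()] to simulate from),
#' the variable-role mapping, bootstrap settings, and the sensitivity
#' switch that repeats every analysis without covariates.
#'
#' @param input A CSV path, a data frame, or a [moment_spec()].
#' @param roles Named list mapping analysis roles to column names:
#'   `x` (predictor), `m` (mediator), `y` (named character vector of one
#'   or more outcomes), `moderators` (named character vector), and
#'   `covariates`. Defaults follow the scale-level CSV contract of
#'   [generate_scale_level()].
#' @param n Number of respondents to simulate when `input` is a
#'   [moment_spec()].
#' @param n_boot,method,level Bootstrap settings passed through to
#'   [bootstrap_effects()] and [bootstrap_conditional()].
#' @param seed Master seed; forked deterministically into per-stage
#'   substreams so adding a stage never shifts another stage's draws.
#' @param sensitivity Repeat the mediation and moderated-mediation
#'   analyses without covariates?
#' @param demographics A [demographic_spec()] used when simulating.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input = adult_survey_moments(),
                            roles = list(
                              x = "ct", m = "se",
                              y = c(depression = "phq9", anxiety = "gad7"),
                              moderators = c(
                                cognitive_reappraisal = "cr",
                                expressive_suppression = "es"
                              ),
                              covariates = c("age", "sex")
                            ),
                            n = 6057, n_boot = 5000,
                            method = c("bias_corrected", "percentile"),
                            level = 0.95, seed = 1L, sensitivity = TRUE,
                            demographics = demographic_spec(n = n)) {
  method <- match.arg(method)
  for (role in c("x", "m", "y")) {
    if (is.null(roles[[role]]) || !length(roles[[role]])) {
      abort(paste0("`roles$", role, "` must be supplied."))
    }
  }
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  if (is.null(names(roles$y))) names(roles$y) <- roles$y
  if (length(roles$moderators) && is.null(names(roles$moderators))) {
    names(roles$moderators) <- roles$moderators
  }
  structure(
    list(
      input = input, roles = roles, n = as.integer(n),
      n_boot = as.integer(n_boot), method = method, level = level,
      seed = as.integer(seed), sensitivity = isTRUE(sensitivity),
      demographics = demographics
    ),
    class = "analysis_config"
  )
}

#' Validate and ingest a participant-level CSV
#'
#' Reads a rectangular participant file (or accepts an in-memory data
#' frame), drops rows with missing values in any mapped analysis column
#' (counting and recording them), and optionally checks columns against
#' declared valid ranges. More than `max_drop_frac` incomplete rows is a
#' hard error, as is a range violation (reported with row and column).
#'
#' @param input CSV path or data frame.
#' @param mapping Character vector of required column names (the mapped
#'   analysis roles).
#' @param ranges Optional named list of `c(lo, hi)` valid ranges per
#'   column (e.g. a scale's declared total range).
#' @param max_drop_frac Maximum tolerated fraction of dropped rows.
#' @return A tibble of complete cases with attribute `ingestion`: a list
#'   with `n_read`, `n_dropped`, `dropped_rows` (original row numbers).
#' @export
validate_input <- function(input, mapping, ranges = NULL,
                           max_drop_frac = 0.5) {
  data <- if (is.character(input)) {
    if (!file.exists(input)) abort(paste0("File not found: ", input))
    readr::read_csv(input, show_col_types = FALSE)
  } else {
    as_tibble(input)
  }
  check_columns(data, mapping)
  keep <- complete.cases(data[mapping])
  dropped <- which(!keep)
  if (length(dropped) > max_drop_frac * nrow(data)) {
    abort(paste0(
      "More than ", round(100 * max_drop_frac), "% of rows (",
      length(dropped), " of ", nrow(data),
      ") have missing mapped fields."
    ))
  }
  out <- data[keep, , drop = FALSE]
  for (cl in names(ranges)) {
    rng <- ranges[[cl]]
    bad <- which(out[[cl]] < rng[1] | out[[cl]] > rng[2])
    if (length(bad)) {
      abort(paste0(
        "Value ", out[[cl]][bad[1]], " in column '", cl,
        "' (row ", bad[1], ") outside valid range [",
        rng[1], ", ", rng[2], "]."
      ))
    }
  }
  structure(out, ingestion = list(
    n_read = nrow(data), n_dropped = length(dropped),
    dropped_rows = dropped
  ))
}

#' Run the complete analysis pipeline
#'
#' Executes, in order: data ingestion (or simulation from a moment
#' specification), descriptive statistics, the Pearson correlation matrix,
#' Mann-Whitney sex comparisons of each outcome, simple mediation with
#' bootstrap intervals per outcome, and the two-stage moderated mediation
#' (stage fits, simple effects, bootstrap conditional effects) per
#' moderator and outcome — then, if configured, the same mediation and
#' moderation analyses with covariates dropped (sensitivity run).
#'
#' Any stage failure aborts with the stage named. Identical configurations
#' (including the seed) reproduce the bundle exactly; per-stage seeds are
#' recorded in the run log.
#'
#' @param config An [analysis_config()].
#' @return An object of class `report_bundle`: a nested list of tibbles
#'   (`descriptives`, `correlations`, `sex_tests`, `mediation`,
#'   `moderation`, optionally `sensitivity`) plus `log`.
#' @export
#' @examples
#' cfg <- analysis_config(n = 300, n_boot = 99, seed = 42,
#'                        sensitivity = FALSE)
#' bundle <- run_full_analysis(cfg)
#' bundle$mediation$depression$intervals
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  roles <- config$roles
  cond_names <- function(prefix) {
    if (!length(roles$moderators)) {
      return(character())
    }
    unlist(lapply(names(roles$moderators), function(w) {
      paste0(prefix, "cond_", w, "_", names(roles$y))
    }))
  }
  stage_names <- c(
    "data",
    paste0("mediation_", names(roles$y)),
    cond_names(""),
    paste0("sens_mediation_", names(roles$y)),
    cond_names("sens_")
  )
  seeds <- fork_seeds(config$seed, stage_names)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  data <- run_stage("data", {
    if (inherits(config$input, "moment_spec")) {
      generate_scale_level(config$input, config$n,
        seed = seeds$data, demographics = config$demographics
      )
    } else {
      validate_input(config$input,
        mapping = unique(c(
          roles$x, roles$m, unname(roles$y),
          unname(roles$moderators), roles$covariates
        ))
      )
    }
  })
  analysis_vars <- unique(c(
    roles$x, roles$m, unname(roles$y), unname(roles$moderators),
    roles$covariates
  ))

  descriptives <- run_stage("descriptives", describe(data, analysis_vars))
  correlations <- run_stage(
    "correlations",
    pearson_matrix(data, setdiff(analysis_vars, "sex"))
  )
  sex_tests <- run_stage("sex_tests", {
    if ("sex" %in% names(data)) {
      purrr::map_dfr(names(roles$y), function(o) {
        dplyr::mutate(
          mann_whitney_u(data, roles$y[[o]], "sex"),
          outcome = o, .before = 1
        )
      })
    }
  })

  run_block <- function(covs, prefix = "") {
    med <- purrr::map(names(roles$y), function(o) {
      run_stage(paste0(prefix, "mediation_", o), bootstrap_effects(
        data, roles$x, roles$m, roles$y[[o]],
        covariates = covs, n_boot = config$n_boot,
        method = config$method, level = config$level,
        seed = seeds[[paste0(prefix, "mediation_", o)]],
        keep_boot = FALSE
      ))
    })
    names(med) <- names(roles$y)
    mod <- purrr::map(names(roles$moderators), function(wn) {
      per_outcome <- purrr::map(names(roles$y), function(o) {
        nm <- paste0(prefix, "cond_", wn, "_", o)
        run_stage(nm, bootstrap_conditional(
          data, roles$x, roles$m, roles$y[[o]], roles$moderators[[wn]],
          covariates = covs, n_boot = config$n_boot,
          method = config$method, level = config$level,
          seed = seeds[[nm]], keep_boot = FALSE
        ))
      })
      names(per_outcome) <- names(roles$y)
      per_outcome
    })
    names(mod) <- names(roles$moderators)
    list(mediation = med, moderation = mod)
  }

  main <- run_block(roles$covariates)
  sensitivity <- if (config$sensitivity) run_block(NULL, prefix = "sens_")

  log <- list(
    seed = config$seed, stage_seeds = seeds,
    n = nrow(data), n_boot = config$n_boot, method = config$method,
    level = config$level,
    repair_delta = attr(data, "repair_delta") %||% NA_real_,
    package_version = as.character(utils::packageVersion("modmedr"))
  )
  structure(
    list(
      data = data, descriptives = descriptives, correlations = correlations,
      sex_tests = sex_tests, mediation = main$mediation,
      moderation = main$moderation, sensitivity = sensitivity, log = log
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> n =", x$log$n, "\n")
  cat("Mediation intervals:\n")
  for (o in names(x$mediation)) {
    cat(" outcome:", o, "\n")
    print(x$mediation[[o]]$intervals)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits one CSV per table (descriptives, correlations in long form, sex
#' tests, per-outcome mediation tables, per-moderator stage-coefficient
#' and simple-effect tables, and the sensitivity duplicates) plus a single
#' `bundle.json` with every table and the run log. If any write fails the
#' partially written files are removed.
#'
#' @param bundle A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit <- function(tbl, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path)
    written <<- c(written, path)
    tbl
  }
  tables <- list()
  ok <- try({
    tables$descriptives <- emit(bundle$descriptives, "descriptives")
    tables$correlations <- emit(tidy(bundle$correlations), "correlations")
    if (!is.null(bundle$sex_tests)) {
      tables$sex_tests <- emit(bundle$sex_tests, "sex_tests")
    }
    for (o in names(bundle$mediation)) {
      tables[[paste0("mediation_", o)]] <-
        emit(tidy(bundle$mediation[[o]]), paste0("mediation_", o))
    }
    for (wn in names(bundle$moderation)) {
      for (o in names(bundle$moderation[[wn]])) {
        cb <- bundle$moderation[[wn]][[o]]
        tables[[paste0("stages_", wn, "_", o)]] <-
          emit(stage_coefficient_table(cb$fits), paste0("stages_", wn, "_", o))
        tables[[paste0("conditional_", wn, "_", o)]] <-
          emit(tidy(cb), paste0("conditional_", wn, "_", o))
      }
    }
    if (!is.null(bundle$sensitivity)) {
      for (o in names(bundle$sensitivity$mediation)) {
        tables[[paste0("sensitivity_mediation_", o)]] <-
          emit(
            tidy(bundle$sensitivity$mediation[[o]]),
            paste0("sensitivity_mediation_", o)
          )
      }
      for (wn in names(bundle$sensitivity$moderation)) {
        for (o in names(bundle$sensitivity$moderation[[wn]])) {
          tables[[paste0("sensitivity_conditional_", wn, "_", o)]] <-
            emit(
              tidy(bundle$sensitivity$moderation[[wn]][[o]]),
              paste0("sensitivity_conditional_", wn, "_", o)
            )
        }
      }
    }
    json_path <- file.path(dir, "bundle.json")
    jsonlite::write_json(
      c(tables, list(log = bundle$log[setdiff(names(bundle$log), "stage_seeds")])),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
    written <- c(written, json_path)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    unlink(written)
    abort(paste0("Writing report bundle failed: ", attr(ok, "condition")$message))
  }
  invisible(dir)
}

#' Stage-coefficient table in hierarchical-step layout
#'
#' Long-format table of a stage-model pair: one row per step, stage and
#' term with coefficient, t and p, plus per-step R-squared and incremental
#' F — the layout of a published hierarchical-regression table.
#'
#' @param fits A [fit_stage_models()] result.
#' @return A tibble.
#' @export
stage_coefficient_table <- function(fits) {
  stopifnot(inherits(fits, "stage_models"))
  one_stage <- function(hf, stage_label) {
    purrr::map_dfr(seq_along(hf$steps), function(i) {
      fit <- hf$steps[[i]]
      inc <- hf$increments[i, ]
      dplyr::mutate(
        fit$coefficients[fit$coefficients$term != "(Intercept)", ],
        stage = stage_label, step = i,
        r.squared = fit$r.squared, f = fit$fstatistic,
        inc_f = inc$inc_f, inc_p = inc$p.value,
        .before = 1
      )
    })
  }
  dplyr::bind_rows(
    one_stage(fits$first, "first"),
    one_stage(fits$second, "second")
  )
}
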