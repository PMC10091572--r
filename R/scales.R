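#' Declare a questionnaire scale
#'
#' A scale definition records everything needed to score a questionnaire
#' from item-level responses: the item labels (column names), the integer
#' response range, the reverse-keyed item set, an optional subscale
#' structure, the aggregation method, and any administered-but-unscored
#' items (e.g. validity items) that are accepted and ignored.
#'
#' @param name Scale name.
#' @param items Character vector of item column labels.
#' @param response_min,response_max Integer response bounds.
#' @param reverse Labels of reverse-keyed items (subset of `items`);
#'   responses are transformed as `min + max - response` before
#'   aggregation.
#' @param subscales Named list mapping subscale name to item labels; every
#'   item may belong to at most one subscale.
#' @param scoring `"sum"` or `"mean"`.
#' @param unscored Labels of items excluded from all totals.
#' @return An object of class `scale_definition` with the derived valid
#'   total range in `$range`.
#' @seealso [score_scale()], [ctq_definition()], [ses_definition()],
#'   [erq_definition()], [phq9_definition()], [gad7_definition()]
#' @export
scale_definition <- function(name, items, response_min, response_max,
                             reverse = character(), subscales = list(),
                             scoring = c("sum", "mean"),
                             unscored = character()) {
  scoring <- match.arg(scoring)
  items <- as.character(items)
  if (anyDuplicated(items)) abort("`items` must be unique.")
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  if (response_min >= response_max) abort("Need response_min < response_max.")
  if (!all(reverse %in% items)) abort("`reverse` must be a subset of `items`.")
  if (!all(unscored %in% items)) abort("`unscored` must be a subset of `items`.")
  all_sub <- unlist(subscales, use.names = FALSE)
  if (!all(all_sub %in% items)) abort("Subscale items must be declared in `items`.")
  if (anyDuplicated(all_sub)) {
    abort("Every item may belong to at most one subscale.")
  }
  scored <- setdiff(items, unscored)
  k <- length(scored)
  range <- if (scoring == "sum") {
    c(k * response_min, k * response_max)
  } else {
    c(response_min, response_max)
  }
  structure(
    list(
      name = name, items = items, response_min = response_min,
      response_max = response_max, reverse = as.character(reverse),
      subscales = subscales, scoring = scoring,
      unscored = as.character(unscored), range = range
    ),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("<scale_definition> ", x$name, ": ", length(x$items), " items (",
    x$response_min, "-", x$response_max, "), scoring = ", x$scoring,
    ", total range ", x$range[1], "-", x$range[2], "\n",
    sep = ""
  )
  if (length(x$subscales)) {
    cat("  subscales: ", paste(names(x$subscales), collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Score a questionnaire from item responses
#'
#' Reverse-keyed items are transformed as `min + max - response`, then
#' items are aggregated (sum or mean) into a total and per-subscale scores.
#' Unscored items (validity items) are accepted in the input and excluded
#' from every score. Rows must be complete; out-of-range responses are
#' rejected with the offending row and column identified.
#'
#' @param items Data frame or matrix of item responses containing every
#'   column the definition declares.
#' @param definition A [scale_definition()].
#' @return A tibble with column `total` and one column per subscale.
#' @export
#' @examples
#' d <- ses_definition()
#' resp <- as.data.frame(matrix(4L, 2, 10))
#' names(resp) <- d$items
#' resp[d$reverse] <- 1L # keyed maximum
#' score_scale(resp, d)$total # 40 40
score_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  items <- as.data.frame(items)
  check_columns(items, definition$items, what = "item label")
  x <- items[definition$items]
  if (anyNA(x)) {
    bad <- which(is.na(as.matrix(x)), arr.ind = TRUE)[1, ]
    abort(paste0(
      "Missing response at row ", bad[1], ", item '",
      definition$items[bad[2]], "'."
    ))
  }
  out_of_range <- as.matrix(x) < definition$response_min |
    as.matrix(x) > definition$response_max
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)[1, ]
    abort(paste0(
      "Response out of range [", definition$response_min, ", ",
      definition$response_max, "] at row ", bad[1], ", item '",
      definition$items[bad[2]], "'."
    ))
  }
  for (it in definition$reverse) {
    x[[it]] <- definition$response_min + definition$response_max - x[[it]]
  }
  agg <- if (definition$scoring == "sum") rowSums else rowMeans
  scored <- setdiff(definition$items, definition$unscored)
  out <- tibble(total = agg(x[scored]))
  for (sub in names(definition$subscales)) {
    cols <- setdiff(definition$subscales[[sub]], definition$unscored)
    out[[sub]] <- agg(x[cols])
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item battery,
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' with the n-1 variance denominator throughout.
#'
#' @param items Data frame or matrix of numeric item responses: at least 2
#'   columns, 3 rows, and a nonzero total variance.
#' @return A one-row tibble with `alpha`, `k` (items) and `n`
#'   (respondents).
#' @export
#' @examples
#' x <- generate_item_level(item_battery_spec(10, 0.4), 500, seed = 1)
#' cronbach_alpha(x)
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  if (!is.numeric(x)) abort("`items` must be numeric.")
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2) abort("Cronbach's alpha needs at least 2 items.")
  if (n < 3) abort("Cronbach's alpha needs at least 3 respondents.")
  if (anyNA(x)) abort("`items` must be complete (no missing responses).")
  total_var <- var(rowSums(x))
  if (total_var <= 0) {
    abort("Total-score variance is zero; alpha is undefined.")
  }
  item_var <- sum(apply(x, 2, var))
  tibble(alpha = k / (k - 1) * (1 - item_var / total_var), k = k, n = n)
}

# ---- built-in questionnaire definitions -----------------------------------

items_of <- function(prefix, idx) sprintf("%s_%02d", prefix, idx)

#' Built-in questionnaire definitions
#'
#' Standard definitions for the five questionnaires the analysis pipeline
#' understands.
#'
#' * `ctq_definition()`: Childhood Trauma Questionnaire, 28 items on a
#'   1-5 frequency scale; five scored subscales of five items each
#'   (emotional/physical/sexual abuse, emotional/physical neglect, each
#'   ranging 5-25) plus three minimization/denial items that are accepted
#'   and ignored; the canonical seven reverse-keyed items.
#' * `erq_definition()`: Emotion Regulation Questionnaire, 10 items on a
#'   1-7 scale; subscales cognitive reappraisal (6 items) and expressive
#'   suppression (4 items).
#' * `ses_definition()`: Rosenberg Self-Esteem Scale, 10 items on a 1-4
#'   scale, total 10-40; reverse-keyed set defaults to the canonical five
#'   and is configurable because published uses vary.
#' * `phq9_definition()`, `gad7_definition()`: depression / anxiety
#'   symptom scales. Default scoring is the standard sum on 0-3 item
#'   coding (PHQ-9 total 0-27, GAD-7 total 0-21), which is the coding
#'   consistent with scale-level descriptives of the reference survey;
#'   per-item mean scoring and 1-4 coding are available by argument
#'   because survey instruments are sometimes administered that way.
#'
#' @param reverse For `ses_definition()`, labels of reverse-keyed items.
#' @param coding `"0-3"` (standard) or `"1-4"` item coding.
#' @param scoring `"sum"` (default) or `"mean"`.
#' @return A [scale_definition()].
#' @name builtin_scales
NULL

#' @rdname builtin_scales
#' @export
ctq_definition <- function() {
  scale_definition(
    name = "ctq",
    items = items_of("ctq", 1:28),
    response_min = 1, response_max = 5,
    reverse = items_of("ctq", c(2, 5, 7, 13, 19, 26, 28)),
    subscales = list(
      emotional_abuse = items_of("ctq", c(3, 8, 14, 18, 25)),
      physical_abuse = items_of("ctq", c(9, 11, 12, 15, 17)),
      sexual_abuse = items_of("ctq", c(20, 21, 23, 24, 27)),
      emotional_neglect = items_of("ctq", c(5, 7, 13, 19, 28)),
      physical_neglect = items_of("ctq", c(1, 2, 4, 6, 26))
    ),
    unscored = items_of("ctq", c(10, 16, 22))
  )
}

#' @rdname builtin_scales
#' @export
erq_definition <- function() {
  scale_definition(
    name = "erq",
    items = items_of("erq", 1:10),
    response_min = 1, response_max = 7,
    subscales = list(
      cognitive_reappraisal = items_of("erq", c(1, 3, 5, 7, 8, 10)),
      expressive_suppression = items_of("erq", c(2, 4, 6, 9))
    )
  )
}

#' @rdname builtin_scales
#' @export
ses_definition <- function(reverse = items_of("ses", c(3, 5, 8, 9, 10))) {
  scale_definition(
    name = "ses",
    items = items_of("ses", 1:10),
    response_min = 1, response_max = 4,
    reverse = reverse
  )
}

#' @rdname builtin_scales
#' @export
phq9_definition <- function(coding = c("0-3", "1-4"),
                            scoring = c("sum", "mean")) {
  coding <- match.arg(coding)
  scale_definition(
    name = "phq9",
    items = items_of("phq", 1:9),
    response_min = if (coding == "0-3") 0 else 1,
    response_max = if (coding == "0-3") 3 else 4,
    scoring = match.arg(scoring)
  )
}

#' @rdname builtin_scales
#' @export
gad7_definition <- function(coding = c("0-3", "1-4"),
                            scoring = c("sum", "mean")) {
  coding <- match.arg(coding)
  scale_definition(
    name = "gad7",
    items = items_of("gad", 1:7),
    response_min = if (coding == "0-3") 0 else 1,
    response_max = if (coding == "0-3") 3 else 4,
    scoring = match.arg(scoring)
  )
}

#' Read / write a scale definition as JSON
#'
#' Declarative persistence for [scale_definition()] objects so that scoring
#' rules can live next to a dataset.
#'
#' @param definition A [scale_definition()].
#' @param path JSON file path.
#' @return `write_scale_definition()` returns `path` invisibly;
#'   `read_scale_definition()` returns a [scale_definition()].
#' @export
write_scale_definition <- function(definition, path) {
  stopifnot(inherits(definition, "scale_definition"))
  jsonlite::write_json(
    unclass(definition)[c(
      "name", "items", "response_min", "response_max",
      "reverse", "subscales", "scoring", "unscored"
    )],
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scale_definition
#' @export
read_scale_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$subscales) == 0) x$subscales <- list()
  scale_definition(
    name = x$name, items = x$items,
    response_min = x$response_min, response_max = x$response_max,
    reverse = x$reverse %||% character(),
    subscales = as.list(x$subscales),
    scoring = x$scoring, unscored = x$unscored %||% character()
  )
}
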