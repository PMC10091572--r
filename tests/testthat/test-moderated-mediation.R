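test_that("stage-model coefficients equal the normal-equations oracle", {
  d <- toy_moderated()
  fits <- fit_stage_models(d, "x", "m", "y", "w",
    covariates = c("age", "sex"), standardized = TRUE
  )
  z <- as.data.frame(scale(d[c("x", "w", "m", "y", "age", "sex")]))
  # first stage, final step: m ~ age + sex + x + w + x:w
  X1 <- cbind(1, z$age, z$sex, z$x, z$w, z$x * z$w)
  o1 <- ols_oracle(X1, z$m)
  s1 <- fits$first$steps[[3]]$coefficients
  expect_equal(s1$estimate, o1[c(1, 2, 3, 4, 5, 6)], tolerance = 1e-10)
  # second stage, final step: y ~ age + sex + x + w + m + m:w
  X2 <- cbind(1, z$age, z$sex, z$x, z$w, z$m, z$m * z$w)
  o2 <- ols_oracle(X2, z$y)
  s2 <- fits$second$steps[[3]]$coefficients
  expect_equal(s2$estimate, o2, tolerance = 1e-10)
  # extracted path coefficients match the oracle positions
  expect_equal(fits$coefficients$a, o1[4], tolerance = 1e-10)
  expect_equal(fits$coefficients$a_int, o1[6], tolerance = 1e-10)
  expect_equal(fits$coefficients$b, o2[6], tolerance = 1e-10)
  expect_equal(fits$coefficients$b_int, o2[7], tolerance = 1e-10)
})

test_that("simple effects are the stated linear combinations", {
  # published-magnitude second stage: main -0.25, interaction -0.05
  fake <- structure(
    list(
      coefficients = list(
        a = -0.40, a_int = 0, b = -0.25, b_int = -0.05,
        first_moderated = FALSE, second_moderated = TRUE
      ),
      spec = list(w = "w")
    ),
    class = "stage_models"
  )
  se <- simple_effects(fake)
  expect_equal(se$table$second_stage, c(-0.20, -0.25, -0.30))
  expect_equal(
    se$differences$difference[se$differences$quantity == "second_stage"],
    -0.10
  )
  # unmoderated first stage is constant across levels
  expect_equal(se$table$first_stage, rep(-0.40, 3))
  # conditional indirect is the product of the stage effects
  expect_equal(se$table$indirect, se$table$first_stage * se$table$second_stage)
})

test_that("high-low difference equals twice the interaction coefficient", {
  for (i in 1:5) {
    spec <- structural_spec(
      a = rnorm(1), b = rnorm(1), c_prime = rnorm(1),
      a_w = rnorm(1, sd = 0.2), b_w = rnorm(1, sd = 0.2)
    )
    d <- generate_structural(spec, 300, seed = 500 + i)
    fits <- fit_stage_models(d, "x", "m", "y", "w", standardized = FALSE)
    se <- simple_effects(fits)
    diffs <- setNames(se$differences$difference, se$differences$quantity)
    expect_equal(diffs[["first_stage"]], 2 * fits$coefficients$a_int,
      tolerance = 1e-12
    )
    expect_equal(diffs[["second_stage"]], 2 * fits$coefficients$b_int,
      tolerance = 1e-12
    )
  }
})

test_that("zero interactions collapse the table to simple mediation", {
  d <- generate_scale_level(table1_spec(), 500, seed = 27)
  fits <- fit_stage_models(d, "ct", "se", "phq9", "es",
    covariates = c("age", "sex"), moderated_stages = "none"
  )
  se <- simple_effects(fits)
  # identical effects at all levels
  expect_equal(se$table$indirect, rep(se$table$indirect[1], 3))
  expect_equal(se$differences$difference, rep(0, 3))
  # cross-module consistency: equals the mediation module's indirect effect
  # when the moderator enters the covariate set of every equation
  med <- fit_mediation(d, "ct", "se", "phq9",
    covariates = c("age", "sex", "es"), standardized = TRUE
  )
  expect_equal(
    se$table$indirect[2],
    med$effects$estimate[med$effects$effect == "indirect"],
    tolerance = 1e-10
  )
})

test_that("independent moderator yields a null interaction block", {
  set.seed(28)
  d <- generate_structural(structural_spec(-0.4, -0.25, 0.2), 3000, seed = 29)
  fits <- fit_stage_models(d, "x", "m", "y", "w", standardized = FALSE)
  expect_lt(abs(fits$coefficients$a_int), 0.05)
  expect_gt(fits$first$increments$p.value[2], 0.001)
})

test_that("conditional bootstrap replicates an index-stream oracle", {
  set.seed(90)
  d <- generate_structural(
    structural_spec(-0.5, -0.4, 0.2, a_w = -0.15, b_w = -0.1),
    40,
    seed = 91
  )
  got <- bootstrap_conditional(d, "x", "m", "y", "w",
    n_boot = 200, seed = 92, keep_boot = TRUE
  )

  cols <- c("x", "m", "y", "w")
  dm <- as.matrix(as.data.frame(d)[cols])
  set.seed(92)
  cells <- matrix(NA_real_, 200, 12)
  for (b in 1:200) {
    i <- sample.int(40, 40, replace = TRUE)
    db <- scale(dm[i, ])
    z <- as.data.frame(db)
    z$xw <- z$x * z$w
    z$mw <- z$m * z$w
    f1 <- coef(lm(m ~ x + w + xw, z))
    f2 <- coef(lm(y ~ x + w + m + mw, z))
    first <- f1[["x"]] + c(-1, 0, 1) * f1[["xw"]]
    second <- f2[["m"]] + c(-1, 0, 1) * f2[["mw"]]
    cells[b, ] <- c(
      first, second, first * second,
      first[3] - first[1], second[3] - second[1],
      first[3] * second[3] - first[1] * second[1]
    )
  }
  bm <- attr(got, "boot")
  expect_equal(unname(bm), unname(cells), tolerance = 1e-9)

  # and therefore identical intervals
  iv <- got$intervals[got$intervals$quantity == "diff_indirect", ]
  pt <- got$point$differences$difference[3]
  z0 <- qnorm((sum(cells[, 12] < pt) + 0.5 * sum(cells[, 12] == pt)) / 200)
  probs <- pnorm(2 * z0 + qnorm(c(0.025, 0.975)))
  expect_equal(
    c(iv$lower, iv$upper),
    quantile(cells[, 12], probs, type = 7, names = FALSE),
    tolerance = 1e-9
  )
})

test_that("second-stage-only moderation shows the expected difference pattern", {
  d <- generate_structural(
    structural_spec(-0.4, -0.25, 0.2, a_w = 0, b_w = -0.1),
    20000,
    seed = 93
  )
  cb <- bootstrap_conditional(d, "x", "m", "y", "w",
    n_boot = 400, seed = 94, standardized = FALSE
  )
  iv <- cb$intervals
  get <- function(q) iv[iv$quantity == q & iv$level == "high - low", ]
  expect_false(get("diff_first_stage")$significant)
  expect_true(get("diff_second_stage")$significant)
  expect_true(get("diff_indirect")$significant)
  # stronger second stage at high moderator (negative effect grows)
  sec <- iv[iv$quantity == "second_stage", ]
  expect_lt(sec$estimate[sec$level == "high"], sec$estimate[sec$level == "low"])
})

test_that("power of the second-stage difference test rises with moderation", {
  grid <- c(0, 0.05, 0.1, 0.2)
  reps <- 120
  rates <- vapply(seq_along(grid), function(gi) {
    mean(vapply(seq_len(reps), function(i) {
      d <- generate_structural(
        structural_spec(-0.4, -0.25, 0.2, b_w = -grid[gi]),
        500,
        seed = 70000 + 1000 * gi + i
      )
      iv <- bootstrap_conditional(d, "x", "m", "y", "w",
        n_boot = 300, seed = 80000 + 1000 * gi + i,
        standardized = FALSE
      )$intervals
      iv$significant[iv$quantity == "diff_second_stage"]
    }, logical(1)))
  }, numeric(1))
  mc <- 2 * sqrt(0.25 / reps)
  expect_true(all(diff(rates) > -mc))
  expect_gt(rates[4], rates[1])
})

test_that("subgroup approach recovers the direction of the moderation", {
  d <- generate_structural(
    structural_spec(-0.4, -0.25, 0.2, b_w = -0.2),
    20000,
    seed = 95
  )
  sg <- subgroup_effects(d, "x", "m", "y", "w")
  expect_equal(sg$subgroup, c("low", "high"))
  # with b_w < 0 the second-stage effect is more negative for high w
  expect_lt(sg$b[2], sg$b[1])
  expect_equal(sum(sg$n), 20000)
})
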