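test_that("mediation paths equal the normal-equations oracle to 1e-10", {
  d <- toy_mediation()
  fit <- fit_mediation(d, "x", "m", "y")
  a_o <- ols_oracle(cbind(1, d$x), d$m)[2]
  by_o <- ols_oracle(cbind(1, d$x, d$m), d$y)
  c_o <- ols_oracle(cbind(1, d$x), d$y)[2]
  paths <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(paths[["a"]], a_o, tolerance = 1e-10)
  expect_equal(paths[["b"]], by_o[3], tolerance = 1e-10)
  expect_equal(paths[["c_prime"]], by_o[2], tolerance = 1e-10)
  expect_equal(paths[["c"]], c_o, tolerance = 1e-10)
  # decomposition identity on the point fit
  expect_equal(paths[["c"]], paths[["c_prime"]] + paths[["a"]] * paths[["b"]],
    tolerance = 1e-12
  )
})

test_that("closed-form moments reproduce the published effect decomposition", {
  mm <- mediation_from_moments(table1_spec(), "ct", "se", "phq9")
  v <- setNames(mm$value, mm$quantity)
  # from the printed descriptives table these round to 0.13/0.08/0.05
  expect_equal(round(v[["total"]], 2), 0.13)
  expect_equal(round(v[["direct"]], 2), 0.08)
  expect_equal(round(v[["indirect"]], 2), 0.05)
  expect_tol(v[["proportion_mediated"]], 36.2, 1.5)

  ma <- mediation_from_moments(table1_spec(), "ct", "se", "gad7")
  va <- setNames(ma$value, ma$quantity)
  expect_equal(round(va[["total"]], 2), 0.10)
  expect_equal(round(va[["direct"]], 2), 0.07)
  expect_equal(round(va[["indirect"]], 2), 0.03)
  expect_tol(va[["proportion_mediated"]], 32.0, 1.5)

  # a sample drawn from the same moments agrees with the closed form
  d <- generate_scale_level(table1_spec(), 6057, seed = 23)
  fit <- fit_mediation(d, "ct", "se", "phq9", covariates = c("age", "sex"))
  ind <- fit$effects$estimate[fit$effects$effect == "indirect"]
  expect_tol(ind, v[["indirect"]], 0.012)
})

test_that("zero second-stage path gives no mediation", {
  d <- generate_structural(structural_spec(a = -0.4, b = 0, c_prime = 0.2),
    20000,
    seed = 24
  )
  fit <- fit_mediation(d, "x", "m", "y")
  eff <- setNames(fit$effects$estimate, fit$effects$effect)
  expect_tol(eff[["indirect"]], 0, 0.02)
  expect_tol(eff[["total"]] - eff[["direct"]], 0, 0.02)
})

test_that("proportion mediated is undefined for a vanishing total effect", {
  set.seed(77)
  x <- rnorm(200)
  m <- 0.5 * x + rnorm(200)
  y <- as.numeric(resid(lm(rnorm(200) ~ x))) # exactly orthogonal to x
  d <- data.frame(x = x, m = m, y = y)
  fit <- fit_mediation(d, "x", "m", "y")
  expect_false(fit$proportion_defined)
  expect_true(is.na(fit$proportion_mediated))
})

test_that("bootstrap replicates an index-stream oracle exactly", {
  set.seed(88)
  d <- data.frame(x = rnorm(20))
  d$m <- 0.6 * d$x + rnorm(20, sd = 0.7)
  d$y <- 0.3 * d$x + 0.5 * d$m + rnorm(20, sd = 0.7)
  got <- bootstrap_effects(d, "x", "m", "y",
    n_boot = 200, seed = 41,
    method = "bias_corrected", keep_boot = TRUE
  )

  # independent re-implementation over the identical resample index stream
  set.seed(41)
  ind <- numeric(200)
  for (b in 1:200) {
    i <- sample.int(20, 20, replace = TRUE)
    db <- d[i, ]
    a <- coef(lm(m ~ x, db))[["x"]]
    bb <- coef(lm(y ~ x + m, db))[["m"]]
    ind[b] <- a * bb
  }
  pt_a <- coef(lm(m ~ x, d))[["x"]]
  pt_b <- coef(lm(y ~ x + m, d))[["m"]]
  pt <- pt_a * pt_b
  z0 <- qnorm((sum(ind < pt) + 0.5 * sum(ind == pt)) / 200)
  probs <- pnorm(2 * z0 + qnorm(c(0.025, 0.975)))
  bounds <- quantile(ind, probs, type = 7, names = FALSE)

  row <- got$intervals[got$intervals$effect == "indirect", ]
  expect_equal(row$estimate, pt, tolerance = 1e-10)
  expect_equal(row$z0, z0, tolerance = 1e-10)
  expect_equal(c(row$lower, row$upper), bounds, tolerance = 1e-10)

  # decomposition identity holds on every bootstrap resample
  bm <- attr(got, "boot")
  expect_lt(max(abs(bm[, "total"] - bm[, "direct"] - bm[, "indirect"])), 1e-10)
})

test_that("bias-corrected equals percentile when z0 is zero", {
  vals <- c(seq(-1, -0.1, by = 0.1), seq(0.1, 1, by = 0.1))
  bc <- bootstrap_interval(vals, point = 0, method = "bias_corrected")
  pc <- bootstrap_interval(vals, point = 0, method = "percentile")
  expect_equal(bc$z0, 0)
  expect_equal(bc$lower, pc$lower)
  expect_equal(bc$upper, pc$upper)

  # ties at the point estimate count one half
  vals2 <- c(rep(1, 4), rep(2, 4), rep(3, 4))
  bc2 <- bootstrap_interval(vals2, point = 1)
  expect_equal(bc2$z0, qnorm((0 + 0.5 * 4) / 12))
})

test_that("intervals are equivariant under sign flip of the predictor", {
  set.seed(89)
  d <- data.frame(x = rnorm(60))
  d$m <- 0.6 * d$x + rnorm(60, sd = 0.7)
  d$y <- 0.3 * d$x + 0.5 * d$m + rnorm(60, sd = 0.7)
  d2 <- d
  d2$x <- -d2$x
  b1 <- bootstrap_effects(d, "x", "m", "y", n_boot = 300, seed = 42)
  b2 <- bootstrap_effects(d2, "x", "m", "y", n_boot = 300, seed = 42)
  for (ef in c("a", "total", "direct", "indirect")) {
    r1 <- b1$intervals[b1$intervals$effect == ef, ]
    r2 <- b2$intervals[b2$intervals$effect == ef, ]
    expect_equal(r2$estimate, -r1$estimate, tolerance = 1e-10)
    expect_equal(r2$lower, -r1$upper, tolerance = 1e-10)
    expect_equal(r2$upper, -r1$lower, tolerance = 1e-10)
  }
  rb1 <- b1$intervals[b1$intervals$effect == "b", ]
  rb2 <- b2$intervals[b2$intervals$effect == "b", ]
  expect_equal(rb2$estimate, rb1$estimate, tolerance = 1e-10)
  expect_equal(rb2$lower, rb1$lower, tolerance = 1e-10)
})

test_that("same seed reproduces intervals; delta SE flag changes only z", {
  d <- generate_scale_level(table1_spec(), 300, seed = 26)
  b1 <- bootstrap_effects(d, "ct", "se", "phq9", n_boot = 150, seed = 5)
  b2 <- bootstrap_effects(d, "ct", "se", "phq9", n_boot = 150, seed = 5)
  expect_identical(b1$intervals, b2$intervals)

  bd <- bootstrap_effects(d, "ct", "se", "phq9",
    n_boot = 150, seed = 5,
    se_method = "delta"
  )
  expect_equal(
    bd$intervals[c("lower", "upper")],
    b1$intervals[c("lower", "upper")]
  )
  paths <- setNames(b1$fit$paths$estimate, b1$fit$paths$path)
  ses <- setNames(b1$fit$paths$se, b1$fit$paths$path)
  sobel <- sqrt(paths[["a"]]^2 * ses[["b"]]^2 + paths[["b"]]^2 * ses[["a"]]^2)
  zrow <- bd$intervals[bd$intervals$effect == "indirect", ]
  expect_equal(zrow$z, zrow$estimate / sobel, tolerance = 1e-10)
})

test_that("indirect-effect estimator is unbiased within Monte-Carlo error", {
  spec <- structural_spec(a = -0.4, b = -0.25, c_prime = 0.2)
  truth <- -0.4 * -0.25
  est <- vapply(1:60, function(i) {
    d <- generate_structural(spec, 5000, seed = 6000 + i)
    fit <- fit_mediation(d, "x", "m", "y")
    fit$effects$estimate[fit$effects$effect == "indirect"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
})
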