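test_that("describe matches hand arithmetic and the n-1 convention", {
  d <- data.frame(v = c(2, 4, 4, 4, 6), k = rep(7, 5))
  out <- describe(d, c("v", "k"))
  expect_equal(out$mean[1], 4)
  expect_equal(out$sd[1], sqrt(8 / 4)) # n-1 denominator
  expect_equal(out$median[1], 4)
  expect_equal(out$sd[2], 0) # constant column

  # regenerated survey-scale data reproduce the printed descriptives
  big <- generate_scale_level(table1_spec(), 6057, seed = 2)
  ct <- describe(big, "ct")
  expect_tol(ct$mean, 38.46, 0.6)
  expect_tol(ct$sd, 11.67, 0.5)
})

test_that("pearson matrix matches a covariance-ratio oracle", {
  x <- c(1.2, 2.1, 2.9, 4.2, 5.1, 5.9, 7.2, 8.1, 8.8, 10.3)
  y <- c(0.9, 2.3, 2.7, 3.9, 5.4, 5.7, 7.5, 7.8, 9.2, 9.8)
  d <- data.frame(x = x, y = y)
  pm <- pearson_matrix(d)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pm$r["x", "y"], oracle, tolerance = 1e-12)
  expect_equal(pm$p["x", "y"], cor.test(x, y)$p.value, tolerance = 1e-10)

  # diagonal: a column against itself
  expect_equal(unname(diag(pm$r)), c(1, 1))
  expect_equal(unname(diag(pm$p)), c(0, 0))

  big <- generate_scale_level(table1_spec(), 6057, seed = 4)
  pm2 <- pearson_matrix(big, c("ct", "se", "phq9"))
  expect_tol(pm2$r["ct", "phq9"], 0.31, 4 / sqrt(6057))
  expect_error(
    pearson_matrix(data.frame(a = 1:5, b = rep(2, 5))),
    "Constant"
  )
})

test_that("mann-whitney U equals brute-force pair counting", {
  a <- c(1, 3, 5, 9)
  b <- c(2, 4, 8)
  d <- data.frame(v = c(a, b), g = rep(c(0, 1), c(4, 3)))
  out <- mann_whitney_u(d, "v", "g")
  brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(out$u, brute)
  expect_equal(out$p.value, wilcox.test(a, b)$p.value)

  # complete separation pins U at an extreme
  d2 <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c(0, 1), each = 3))
  u2 <- mann_whitney_u(d2, "v", "g")$u
  expect_true(u2 == 0 || u2 == 9)

  # identical group distributions: no significant difference
  set.seed(51)
  d3 <- data.frame(v = rnorm(3000), g = rep(0:1, 1500))
  expect_gt(mann_whitney_u(d3, "v", "g")$p.value, 0.05)
})

test_that("ols matches the normal-equations oracle to 1e-10", {
  d <- toy_regression()
  fit <- ols_fit(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  expect_equal(fit$coefficients$estimate, ols_oracle(X, d$y),
    tolerance = 1e-10
  )

  # outcome equal to a predictor
  d$z <- d$x1
  fit2 <- suppressWarnings(ols_fit(d, "z", "x1")) # perfect fit warns
  expect_equal(fit2$coefficients$estimate[2], 1, tolerance = 1e-12)
  expect_equal(fit2$r.squared, 1, tolerance = 1e-12)

  # rank deficiency is reported with the offending term
  d$x1b <- d$x1
  expect_error(ols_fit(d, "y", c("x1", "x1b")), "x1b")
})

test_that("standardized coefficients are affine-invariant and B*sd/sd", {
  d <- generate_scale_level(table1_spec(), 400, seed = 6)
  f_raw <- ols_fit(d, "phq9", c("ct", "se"))
  f_std <- ols_fit(d, "phq9", c("ct", "se"), standardized = TRUE)
  # std estimate of the raw fit equals the standardized fit's estimate
  expect_equal(
    f_raw$coefficients$std_estimate[-1],
    f_std$coefficients$estimate[-1],
    tolerance = 1e-10
  )
  # B * sd(x)/sd(y) identity, computed directly
  b_ct <- f_raw$coefficients$estimate[f_raw$coefficients$term == "ct"]
  expect_equal(
    f_raw$coefficients$std_estimate[f_raw$coefficients$term == "ct"],
    b_ct * sd(d$ct) / sd(d$phq9),
    tolerance = 1e-12
  )
  # affine rescaling of inputs leaves standardized coefficients unchanged
  d2 <- d
  d2$ct <- 3 * d2$ct + 10
  d2$phq9 <- 0.5 * d2$phq9 - 2
  f_std2 <- ols_fit(d2, "phq9", c("ct", "se"), standardized = TRUE)
  expect_equal(f_std2$coefficients$estimate, f_std$coefficients$estimate,
    tolerance = 1e-10
  )
})

test_that("unstandardized slope from survey moments matches the closed form", {
  d <- generate_scale_level(table1_spec(), 6057, seed = 8)
  fit <- ols_fit(d, "se", "ct")
  # population value -0.41 * 5.49 / 11.67 = -0.1929
  expect_tol(
    fit$coefficients$estimate[2],
    -0.41 * 5.49 / 11.67, 0.02
  )
})

test_that("hierarchical fit reproduces refit-from-scratch increments", {
  d <- toy_moderated()
  hf <- hierarchical_fit(d, "y",
    blocks = list(c("age", "sex"), c("x", "w", "m"), "m:w")
  )
  # delta R2 equals differences of independently computed R2s
  z <- as.data.frame(scale(d[c("y", "age", "sex", "x", "w", "m")]))
  z$mw <- z$m * z$w
  r2 <- c(
    summary(lm(y ~ age + sex, z))$r.squared,
    summary(lm(y ~ age + sex + x + w + m, z))$r.squared,
    summary(lm(y ~ age + sex + x + w + m + mw, z))$r.squared
  )
  expect_equal(hf$increments$r.squared, r2, tolerance = 1e-10)
  expect_equal(hf$increments$delta_r2, diff(c(0, r2)), tolerance = 1e-10)
  # R2 non-decreasing, increments sum to the full-model R2
  expect_true(all(hf$increments$delta_r2 >= -1e-12))
  expect_equal(sum(hf$increments$delta_r2), r2[3], tolerance = 1e-12)
  # incremental F agrees with the nested-model anova
  a23 <- anova(
    lm(y ~ age + sex + x + w + m, z),
    lm(y ~ age + sex + x + w + m + mw, z)
  )
  expect_equal(hf$increments$inc_f[3], a23$F[2], tolerance = 1e-8)
  expect_equal(hf$increments$p.value[3], a23$`Pr(>F)`[2], tolerance = 1e-8)

  expect_error(
    hierarchical_fit(d, "y", blocks = list("x", c("x", "w"))),
    "disjoint"
  )
})

test_that("null data give incremental F near its null expectation", {
  set.seed(61)
  d <- data.frame(
    y = rnorm(2000), x = rnorm(2000), w = rnorm(2000),
    age = rnorm(2000), sex = rep(0:1, 1000)
  )
  hf <- hierarchical_fit(d, "y",
    blocks = list(c("age", "sex"), c("x", "w"), "x:w")
  )
  expect_gt(hf$increments$p.value[3], 0.01)
  expect_lt(hf$increments$inc_f[3], qf(0.999, 1, hf$increments$df2[3]))
})
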