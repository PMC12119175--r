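test_that("intercept-only Poisson MLEs have their closed forms", {
  d <- data.frame(effort = c(1, 1, 1), count_af = c(1, 2, 3))
  f <- fit_count_model(count_model_spec("af", random_intercept = "none"), d)
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)
  d2 <- data.frame(effort = 200, count_af = 2)
  f2 <- fit_count_model(count_model_spec("af", random_intercept = "none"), d2)
  expect_equal(unname(f2$coefficients), log(0.01), tolerance = 1e-8)
})

test_that("GLM fit matches the independent IRLS oracle", {
  dat <- make_count_data(150, beta = c(x1 = 0.5, x2 = -0.3), seed = 51)
  f <- fit_count_model(
    count_model_spec("af", c("x1", "x2"), random_intercept = "none"), dat)
  X <- cbind(1, dat$x1, dat$x2)
  o <- oracle_irls_poisson(X, dat$count_af, log(dat$effort))
  expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-6)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
})

test_that("GLMM on sigma = 0 data recovers the GLM solution", {
  dat <- make_count_data(300, beta = c(x1 = 0.4), sigma_year = 0, seed = 52)
  fg <- fit_count_model(
    count_model_spec("af", "x1", random_intercept = "year"), dat)
  o <- oracle_irls_poisson(cbind(1, dat$x1), dat$count_af, log(dat$effort))
  expect_equal(unname(fg$coefficients), o$beta, tolerance = 1e-4)
  expect_lt(abs(fg$loglik - o$loglik), 1e-4)
})

test_that("AGHQ marginal likelihood matches dense numerical integration", {
  set.seed(53)
  n <- 12
  X <- cbind(1, rnorm(n))
  y <- rpois(n, exp(0.5 + 0.4 * X[, 2]))
  off <- rep(0, n)
  grp <- factor(rep(1:3, each = 4))
  for (theta in list(NULL, 1.5)) {
    ours <- aghq_marginal_loglik(c(0.5, 0.4), 0.6, theta, X, y, off, grp,
                                 q = 15)
    brute <- oracle_marginal_loglik(c(0.5, 0.4), 0.6, theta, X, y, off, grp)
    expect_lt(abs(ours - brute), 1e-4)
  }
  # quadrature convergence
  l31 <- aghq_marginal_loglik(c(0.5, 0.4), 0.6, NULL, X, y, off, grp, q = 31)
  l63 <- aghq_marginal_loglik(c(0.5, 0.4), 0.6, NULL, X, y, off, grp, q = 63)
  expect_lt(abs(l31 - l63), 1e-6)
  # sigma -> 0 limit reduces to the GLM log-likelihood
  glm_ll <- sum(dpois(y, exp(0.5 + 0.4 * X[, 2]), log = TRUE))
  l0 <- aghq_marginal_loglik(c(0.5, 0.4), 1e-8, NULL, X, y, off, grp, q = 15)
  expect_lt(abs(l0 - glm_ll), 1e-6)
})

test_that("aicc follows the closed form and guards its domain", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_error(aicc(-10, 3, 4), "n > k \\+ 1")
  expect_lt(aicc(-10, 2, 1e7) - 24, 1e-5)   # large-n limit: AICc -> AIC
})

test_that("likelihood-ratio test handles identity, nesting and tails", {
  dat <- make_count_data(100, beta = c(x1 = 0.5, x2 = 0), seed = 54)
  full <- fit_count_model(
    count_model_spec("af", c("x1", "x2"), random_intercept = "none"), dat)
  red <- fit_count_model(
    count_model_spec("af", "x1", random_intercept = "none"), dat)
  lt <- lr_test(full, red)
  expect_equal(lt$df, 1)
  expect_gte(lt$statistic, 0)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(lr_test(red, full), "not nested")
  # chi-square upper tail reference value
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 5e-4)
})

test_that("likelihood is invariant under predictor reordering", {
  dat <- make_count_data(200, beta = c(x1 = 0.5, x2 = -0.4, x3 = 0.2),
                         sigma_year = 0.3, seed = 55)
  f1 <- fit_count_model(
    count_model_spec("af", c("x1", "x2", "x3"), random_intercept = "year"),
    dat)
  f2 <- fit_count_model(
    count_model_spec("af", c("x3", "x1", "x2"), random_intercept = "year"),
    dat)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$coefficients[c("x1", "x2", "x3")],
               f2$coefficients[c("x1", "x2", "x3")], tolerance = 1e-5)
})

test_that("rank-deficient designs error naming the aliased term", {
  dat <- make_count_data(100, beta = c(x1 = 0.3), seed = 56)
  dat$x2 <- dat$x1
  expect_error(
    fit_count_model(count_model_spec("af", c("x1", "x2"),
                                     random_intercept = "none"), dat),
    "aliased")
})

test_that("response curves follow the closed-form prediction", {
  d <- data.frame(effort = rep(100, 60), count_af = rpois(60, 2),
                  x1 = rnorm(60))
  f <- fit_count_model(count_model_spec("af", "x1",
                                        random_intercept = "none"), d)
  pr <- predict_response(f, "x1", z = c(-1, 0, 1))
  b0 <- f$coefficients[["(Intercept)"]]
  bv <- f$coefficients[["x1"]]
  expect_equal(pr$predicted, 100 * exp(b0 + bv * c(-1, 0, 1)))
  # a negative coefficient gives a strictly decreasing curve
  if (bv > 0) bv <- -bv
  f$coefficients[["x1"]] <- bv
  pr2 <- predict_response(f, "x1", z = seq(-2, 2, 0.5))
  expect_true(all(diff(pr2$predicted) < 0))
  expect_error(predict_response(f, "nope"), "not in the fitted model")
})
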