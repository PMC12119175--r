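fake_ranked <- function(aicc, labels = NULL, fits = NULL) {
  tab <- data.frame(model = labels %||% paste0("m", seq_along(aicc)),
                    k = 2, loglik = 0, aicc = aicc)
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  tab$delta <- tab$aicc - tab$aicc[1]
  structure(list(table = tab, fits = (fits %||%
    replicate(length(aicc), list(), simplify = FALSE))[ord]),
    class = "habseg_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fake_fit <- function(coefs, ses) {
  structure(list(coefficients = coefs, se = ses), class = "habseg_fit")
}

test_that("enumeration fits 2^p subsets and is order-invariant", {
  dat <- make_count_data(120, beta = c(x1 = 0.6, x2 = 0, x3 = 0), seed = 71)
  r3 <- enumerate_and_rank("af", c("x1", "x2", "x3"), dat)
  expect_identical(nrow(r3$table), 8L)
  r0 <- enumerate_and_rank("af", character(0), dat)
  expect_identical(nrow(r0$table), 1L)
  expect_identical(r0$table$model, "1")
  # same ranking whatever the candidate order
  r3b <- enumerate_and_rank("af", c("x3", "x1", "x2"), dat)
  expect_identical(r3$table$model, r3b$table$model)
  expect_equal(r3$table$aicc, r3b$table$aicc, tolerance = 1e-8)
  expect_error(enumerate_and_rank("af", paste0("v", 1:16), dat), "restrict")
})

test_that("competing set applies the strict delta threshold and weights", {
  cs <- competing_set(fake_ranked(c(100, 101.9, 102.1)))
  expect_identical(nrow(cs$table), 2L)
  cs2 <- competing_set(fake_ranked(c(100, 102)))   # boundary excluded
  expect_identical(nrow(cs2$table), 1L)
  expect_equal(cs2$table$weight, 1)
  cs3 <- competing_set(fake_ranked(c(10, 11)))     # delta = {0, 1}
  expect_equal(cs3$table$weight, c(1, exp(-0.5)) / (1 + exp(-0.5)),
               tolerance = 1e-10)
  expect_equal(cs3$table$weight, c(0.62246, 0.37754), tolerance = 1e-4)
  expect_equal(sum(cs3$table$weight), 1, tolerance = 1e-12)
})

test_that("coefficient averaging matches the hand-computed oracle", {
  cs <- structure(list(
    table = data.frame(model = c("a", "b"), weight = c(0.5, 0.5)),
    fits = list(fake_fit(c("(Intercept)" = 0, v = 1), c("(Intercept)" = 1, v = 0.2)),
                fake_fit(c("(Intercept)" = 0), c("(Intercept)" = 1)))),
    class = "habseg_competing")
  full <- average_coefficients(cs, "full")
  cond <- average_coefficients(cs, "conditional")
  expect_equal(full$estimate[full$variable == "v"], 0.5)
  expect_equal(cond$estimate[cond$variable == "v"], 1)
  # unconditional SE, full mode: 0.5*sqrt(0.2^2+0.25) + 0.5*sqrt(0+0.25)
  expect_equal(full$se[full$variable == "v"],
               0.5 * sqrt(0.04 + 0.25) + 0.5 * 0.5, tolerance = 1e-12)
  # absent everywhere -> exact 0
  ext <- average_coefficients(cs, "full", variables = "ghost")
  expect_identical(ext$estimate[ext$variable == "ghost"], 0)
  # three-model spreadsheet oracle
  w <- c(0.5, 0.3, 0.2)
  b <- c(1.0, 0.4, NA)  # absent from third model
  cs3 <- structure(list(
    table = data.frame(model = c("a", "b", "c"), weight = w),
    fits = list(fake_fit(c(v = 1.0), c(v = 0.1)),
                fake_fit(c(v = 0.4), c(v = 0.3)),
                fake_fit(c(u = 2), c(u = 0.2)))),
    class = "habseg_competing")
  got <- average_coefficients(cs3, "full")
  bbar <- 0.5 * 1 + 0.3 * 0.4 + 0.2 * 0
  expect_equal(got$estimate[got$variable == "v"], bbar)
  sebar <- 0.5 * sqrt(0.1^2 + (1 - bbar)^2) +
    0.3 * sqrt(0.3^2 + (0.4 - bbar)^2) + 0.2 * sqrt(0 + bbar^2)
  expect_equal(got$se[got$variable == "v"], sebar, tolerance = 1e-12)
})

test_that("full averaging shrinks towards zero relative to conditional", {
  dat <- make_count_data(120, beta = c(x1 = 0.5, x2 = 0.1, x3 = 0),
                         seed = 72)
  cs <- competing_set(enumerate_and_rank("af", c("x1", "x2", "x3"), dat))
  full <- average_coefficients(cs, "full")
  cond <- average_coefficients(cs, "conditional")
  m <- merge(full, cond, by = "variable")
  expect_true(all(abs(m$estimate.x) <= abs(m$estimate.y) + 1e-12))
})

test_that("best significant model drops null predictors", {
  # one strong and one null predictor
  dat <- make_count_data(300, beta = c(x1 = 0.8, x2 = 0), seed = 73)
  r <- enumerate_and_rank("af", c("x1", "x2"), dat)
  best <- best_significant_model(r)
  expect_true("x1" %in% names(best$fit$coefficients))
  expect_false("x2" %in% names(best$fit$coefficients))
  expect_true(all(best$pvalues < 0.05))
  expect_gt(length(best$path), 0)
})
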