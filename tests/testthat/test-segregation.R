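rv <- function(beta, w = NULL, stratum = NA) {
  list(beta = beta, w = w %||% setNames(rep(1, length(beta)), names(beta)),
       stratum = stratum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("weighted distance obeys the basic identities", {
  a <- rv(c(x = 1, y = 0))
  b <- rv(c(x = 0, y = 0))
  expect_equal(weighted_distance(a, a), 0)
  expect_equal(weighted_distance(a, b), 1)
  # homogeneity: doubling every coefficient difference doubles the distance
  a2 <- rv(c(x = 2, y = 0))
  expect_equal(weighted_distance(a2, b), 2 * weighted_distance(a, b))
  expect_error(weighted_distance(rv(c(x = 1), w = c(x = -0.1)), b),
               "nonnegative")
  expect_error(
    weighted_distance(list(beta = setNames(numeric(0), character(0)),
                           w = setNames(numeric(0), character(0))),
                      list(beta = setNames(numeric(0), character(0)),
                           w = setNames(numeric(0), character(0)))),
    "no overlapping variables")
  expect_error(weighted_distance(rv(c(x = 1), stratum = "low"),
                                 rv(c(x = 1), stratum = "high")),
               "different strata")
})

test_that("every convention is a metric for shared weights", {
  set.seed(91)
  vars <- c("a", "b", "c", "d")
  for (conv in c("mean_w", "coord_w", "coord_sqrtw", "norm_w")) {
    for (rep in 1:25) {
      w <- setNames(runif(4, 0.01, 1), vars)
      v1 <- rv(setNames(rnorm(4), vars), w)
      v2 <- rv(setNames(rnorm(4), vars), w)
      v3 <- rv(setNames(rnorm(4), vars), w)
      d12 <- weighted_distance(v1, v2, conv)
      d21 <- weighted_distance(v2, v1, conv)
      d13 <- weighted_distance(v1, v3, conv)
      d23 <- weighted_distance(v2, v3, conv)
      expect_equal(d12, d21, tolerance = 1e-12)          # symmetry
      expect_equal(weighted_distance(v1, v1, conv), 0)   # identity
      expect_lte(d13, d12 + d23 + 1e-12)                 # triangle
      expect_gte(d12, 0)
    }
  }
})

test_that("wilcoxon rank sum matches enumeration and handles ties", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)           # complete separation
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p.value, 1)
  # exact case against stats::wilcox.test as independent oracle
  set.seed(92)
  x <- rnorm(4); y <- rnorm(4) + 0.5
  ours <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_match(ours$method, "exact")
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  # tie-corrected normal approximation against wilcox.test
  x2 <- c(rpois(30, 3)); y2 <- c(rpois(25, 4))
  ours2 <- wilcoxon_rank_sum(x2, y2)
  ref2 <- suppressWarnings(wilcox.test(x2, y2, exact = FALSE,
                                       correct = FALSE))
  expect_equal(ours2$statistic, unname(ref2$statistic))
  expect_equal(ours2$p.value, ref2$p.value, tolerance = 1e-10)
})

test_that("jackknife builds the full LOW x HIGH pair grid", {
  d <- simulate_h2_dataset(93, n_low = 6, n_high = 5)
  rep <- jackknife_distances(d, c("tcov", "moist"), refit_selection = FALSE)
  expect_identical(rep$n_pairs, 30L)
  expect_identical(nrow(rep$pairs), 30L)
  expect_identical(length(rep$low_loo), 6L)
  expect_identical(length(rep$high_loo), 5L)
  # deterministic recomputation, and invariant to transect row order
  rep2 <- jackknife_distances(d, c("tcov", "moist"), refit_selection = FALSE)
  expect_identical(rep$pairs, rep2$pairs)
  perm <- d[sample(nrow(d)), ]
  rep3 <- jackknife_distances(perm, c("tcov", "moist"),
                              refit_selection = FALSE)
  expect_equal(sort(rep3$pairs$d_low), sort(rep$pairs$d_low),
               tolerance = 1e-8)
  expect_equal(rep3$d_low, rep$d_low, tolerance = 1e-10)
})

test_that("duplicate transects are exchangeable in the jackknife", {
  # each stratum holds duplicated copies: removing either copy of the same
  # transect must give the same leave-one-out distance
  d <- simulate_h2_dataset(94, n_low = 4, n_high = 4)
  dup <- rbind(d, d)
  dup$transect_id <- sprintf("T%03d", seq_len(nrow(dup)))
  rep <- jackknife_distances(dup, c("tcov", "moist"), refit_selection = FALSE)
  # copies of LOW transects land at positions 1..4 and 5..8 of the stratum
  expect_equal(rep$low_loo[1:4], rep$low_loo[5:8], tolerance = 1e-8)
  expect_equal(rep$high_loo[1:4], rep$high_loo[5:8], tolerance = 1e-8)
})

test_that("jackknife CI and paired t follow their definitions", {
  fake <- function(dl, dh) structure(
    list(pairs = data.frame(d_low = dl, d_high = dh),
         n_pairs = length(dl)), class = "habseg_distance_report")
  set.seed(95)
  r <- fake(rnorm(200, 2, 0.1), rnorm(200, 1, 0.1))
  out <- jackknife_ci_and_test(r)
  expect_equal(out$df, 199)
  expect_equal(out$ci_low, unname(quantile(r$pairs$d_low, c(.025, .975))))
  expect_gt(out$t, 10)
  expect_lt(out$p.value, 1e-10)
  # constant differences: flagged, infinite t
  rc <- fake(rep(2, 10), rep(1.5, 10))
  outc <- jackknife_ci_and_test(rc)
  expect_true(outc$constant)
  expect_identical(outc$t, Inf)
  # symmetric null differences keep |t| small most of the time
  hits <- 0L
  for (i in 1:100) {
    rr <- fake(rnorm(50, 1, 0.2), rnorm(50, 1, 0.2))
    if (abs(jackknife_ci_and_test(rr)$t) < 2) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("printed-table ingestion reports distances per convention", {
  path <- system.file("extdata", "averaged_coefficients_low_high.csv",
                      package = "habseg")
  tab <- distance_from_table(path)
  expect_identical(nrow(tab), 8L)   # 2 strata x 4 conventions
  expect_true(all(is.finite(tab$distance)) && all(tab$distance > 0))
  # hand-computed mean_w oracle for the LOW stratum ("<1" -> 0.5%)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  low <- raw[raw$stratum == "low", ]
  wnum <- ifelse(grepl("<", low$w), 0.5, suppressWarnings(as.numeric(low$w)))
  af <- low$species == "af"
  m <- merge(data.frame(v = low$variable[af], ba = low$beta[af],
                        wa = wnum[af] / 100),
             data.frame(v = low$variable[!af], bc = low$beta[!af],
                        wc = wnum[!af] / 100))
  oracle <- sqrt(sum((m$wa + m$wc) / 2 * (m$ba - m$bc)^2))
  got <- tab$distance[tab$stratum == "low" & tab$convention == "mean_w"]
  expect_equal(got, oracle, tolerance = 1e-12)
})
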