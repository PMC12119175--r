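test_that("config invariants are enforced with the field named", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(effort_range = c(0, 40), seed = 1), "effort_range")
  expect_error(sim_config(sigma_year = -1, seed = 1), "sigma_year")
  expect_error(sim_config(family = "negbin", theta = 0, seed = 1), "theta")
  expect_error(sim_config(years = numeric(0), seed = 1), "years")
  expect_error(sim_config(n_transects = 10, n_sites = 11, seed = 1),
               "n_sites")
})

test_that("null model mean count matches the closed form rate", {
  cfg <- sim_config(n_transects = 10000, n_sites = 100, years = 2004,
                    effort_range = c(100, 100),
                    true_beta = list(af = numeric(0), cg = numeric(0)),
                    intercepts = c(af = log(0.02), cg = log(0.02)),
                    sigma_year = 0, seed = 11)
  d <- generate_dataset(cfg)
  # mean = 100 * 0.02 = 2; allow 3 Monte-Carlo standard errors
  mc_se <- sd(d$count_af) / sqrt(nrow(d))
  expect_lt(abs(mean(d$count_af) - 2), 3 * mc_se)
})

test_that("generation is seed-deterministic, byte-for-byte on CSV", {
  cfg <- sim_config(n_transects = 60, n_sites = 20, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_transects(d1, f1); write_transects(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("negbin counts are overdispersed relative to poisson", {
  base <- list(n_transects = 10000, n_sites = 100, years = 2004,
               effort_range = c(100, 100),
               true_beta = list(af = numeric(0), cg = numeric(0)),
               sigma_year = 0)
  dp <- generate_dataset(do.call(sim_config, c(base, list(seed = 3))))
  dn <- generate_dataset(do.call(sim_config,
    c(base, list(family = "negbin", theta = 0.5, seed = 3))))
  vmr <- function(x) var(x) / mean(x)
  expect_lt(vmr(dp$count_af), 1.2)     # Poisson: VMR ~ 1
  expect_gt(vmr(dn$count_af), 2)       # NB2 with theta 0.5, mu 2: ~ 1 + mu/theta
})

test_that("counts are nonnegative integers and effort stays in range", {
  d <- generate_dataset(sim_config(n_transects = 300, n_sites = 40, seed = 5))
  for (v in c("count_af", "count_cg")) {
    expect_true(all(d[[v]] >= 0))
    expect_identical(d[[v]], as.integer(d[[v]]))
  }
  expect_true(all(d$effort >= 90 & d$effort <= 160))
  rho <- cor(d[, habseg:::habitat_variables()], method = "spearman")
  expect_lte(max(abs(rho[upper.tri(rho)])), 0.6)
})

test_that("study replica reproduces the design skeleton for any seed", {
  for (seed in c(1, 42)) {
    d <- generate_study_replica(seed)
    expect_identical(nrow(d), 81L)
    expect_identical(sum(d$elevation <= 1300), 42L)
    expect_identical(sum(d$elevation > 1300), 39L)
    expect_identical(sum(d$year %% 2 == 1), 50L)
    expect_identical(sum(d$year %% 2 == 0), 31L)
  }
  d1 <- generate_study_replica(1)
  d2 <- generate_study_replica(2)
  expect_false(identical(d1$count_af, d2$count_af))
  expect_identical(dim(d1), dim(d2))
  expect_identical(sum(d2$elevation <= 1300), 42L)
})

test_that("species counts are conditionally independent when gamma is 0", {
  beta <- list(af = c(tcov = 0.4, moist = 0.3), cg = c(tcov = 0.4, moist = 0.3))
  cfg <- sim_config(n_transects = 10000, n_sites = 500, years = 2004,
                    effort_range = c(100, 100), true_beta = beta,
                    sigma_year = 0, seed = 9)
  d <- generate_dataset(cfg)
  z <- scale(d[, c("tcov", "moist")])
  eta <- log(0.025) + drop(z %*% c(0.4, 0.3))
  mu <- d$effort * exp(eta)
  r <- cor((d$count_af - mu) / sqrt(mu), (d$count_cg - mu) / sqrt(mu))
  expect_lt(abs(r), 0.05)
})

test_that("interspecific suppression shifts the second species' counts", {
  base <- list(n_transects = 4000, n_sites = 200, years = 2004,
               effort_range = c(100, 100),
               true_beta = list(af = numeric(0), cg = numeric(0)),
               sigma_year = 0)
  d0 <- generate_dataset(do.call(sim_config, c(base, list(seed = 13))))
  dg <- generate_dataset(do.call(sim_config,
    c(base, list(competition_gamma = c(af = -0.5, cg = 0), seed = 13))))
  # af is drawn second: with gamma < 0 its counts become negatively
  # associated with the vole's rate
  r0 <- cor(d0$count_af, d0$count_cg, method = "spearman")
  rg <- cor(dg$count_af, dg$count_cg, method = "spearman")
  expect_lt(rg, r0 - 0.1)
})
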