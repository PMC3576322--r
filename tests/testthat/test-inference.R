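test_that("mcmc configuration validates and exposes both profiles", {
  cfg <- mtc_mcmc()
  expect_equal(cfg$chains, 2)
  expect_equal(cfg$burn_in, 50000)
  expect_equal(cfg$samples, 100000)
  fast <- mtc_mcmc(profile = "fast")
  expect_equal(fast$chains, 4)
  expect_error(mtc_mcmc(chains = 1), "chains")
  expect_error(mtc_mcmc(samples = 10), "samples")
})

test_that("sampling is bit-reproducible under a fixed seed", {
  cons <- build_contrasts(tiny_arms())
  m <- build_mtc_model(cons, mtc_spec("continuous", c("Ada", "Eta"),
                                      mtx_adjust = FALSE), mtc_priors())
  cfg <- mtc_mcmc(chains = 2, burn_in = 500, samples = 1000, seed = 7)
  d1 <- run_mcmc(m, cfg)
  d2 <- run_mcmc(m, cfg)
  expect_identical(lapply(d1$samples, as.matrix),
                   lapply(d2$samples, as.matrix))
  d3 <- run_mcmc(m, mtc_mcmc(chains = 2, burn_in = 500, samples = 1000,
                             seed = 8))
  expect_false(identical(as.matrix(d1$samples[[1]]),
                         as.matrix(d3$samples[[1]])))
})

test_that("study-effect posterior matches its conjugate closed form", {
  # one contrast, vague basic-parameter prior: marginally the study effect is
  # conjugate-normal, alpha | D ~ N(delta, se^2) (prior shrinkage O(se^2/1e4))
  delta <- 0.30; se <- 0.08
  cons <- data.frame(trial_id = "t1", drug = "Ada", delta_obs = delta,
                     se = se, mtx_diff = 0, baseline = 1)
  m <- build_mtc_model(cons,
                       mtc_spec("continuous", "Ada", mtx_adjust = FALSE,
                                baseline_multiplier = TRUE),
                       mtc_priors())
  d <- run_mcmc(m, mtc_mcmc(chains = 2, burn_in = 5000, samples = 25000,
                            seed = 3), monitor = "alpha")
  al <- do.call(rbind, lapply(d$samples, as.matrix))[, "alpha"]
  ess <- effective_sample_size(d)[["alpha"]]
  mcse <- se / sqrt(ess)
  expect_lt(abs(mean(al) - delta), 3 * mcse)
  expect_equal(sd(al), se, tolerance = 0.05)
})

test_that("prior-only sampling recovers the prior exactly", {
  spec <- mtc_spec("continuous", c("Ada", "Eta"), mtx_adjust = FALSE)
  m <- build_mtc_model(NULL, spec, mtc_priors())
  d <- run_mcmc(m, mtc_mcmc(chains = 2, burn_in = 1000, samples = 20000,
                            seed = 5))
  mat <- do.call(rbind, lapply(d$samples, as.matrix))
  # a ~ N(0, 100^2)
  expect_lt(abs(mean(mat[, "a[1]"])), 3 * 100 / sqrt(40000) * 2)
  expect_equal(sd(mat[, "a[1]"]), 100, tolerance = 0.05)
  # sigma ~ Uniform(0, 2): mean 1, sd 2/sqrt(12), and the whole distribution
  expect_equal(mean(mat[, "sigma"]), 1, tolerance = 0.03)
  expect_equal(sd(mat[, "sigma"]), 2 / sqrt(12), tolerance = 0.05)
  ks <- suppressWarnings(ks.test(mat[, "sigma"], "punif", 0, 2))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("effective sample size matches i.i.d. and AR(1) oracles", {
  set.seed(21)
  iid <- coda::mcmc.list(coda::mcmc(matrix(rnorm(5000), ncol = 1,
                                           dimnames = list(NULL, "x"))),
                         coda::mcmc(matrix(rnorm(5000), ncol = 1,
                                           dimnames = list(NULL, "x"))))
  expect_equal(unname(effective_sample_size(iid)["x"]), 10000,
               tolerance = 0.10)

  rho <- 0.9
  ar1 <- function(n) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1) * sqrt(1 - rho^2)
    x
  }
  ml <- coda::mcmc.list(coda::mcmc(matrix(ar1(20000), ncol = 1,
                                          dimnames = list(NULL, "x"))),
                        coda::mcmc(matrix(ar1(20000), ncol = 1,
                                          dimnames = list(NULL, "x"))))
  theory <- 40000 * (1 - rho) / (1 + rho)
  expect_equal(unname(effective_sample_size(ml)["x"]), theory,
               tolerance = 0.20)

  const <- coda::mcmc.list(coda::mcmc(matrix(1, 500, 1,
                                             dimnames = list(NULL, "x"))),
                           coda::mcmc(matrix(1, 500, 1,
                                             dimnames = list(NULL, "x"))))
  expect_warning(ess_c <- effective_sample_size(const), "undefined")
  expect_true(is.na(ess_c[["x"]]))
})

test_that("split-chain Rhat flags disagreeing chains and accepts matching ones", {
  set.seed(31)
  same <- coda::mcmc.list(coda::mcmc(matrix(rnorm(4000), ncol = 1,
                                            dimnames = list(NULL, "x"))),
                          coda::mcmc(matrix(rnorm(4000), ncol = 1,
                                            dimnames = list(NULL, "x"))))
  expect_lt(abs(rhat_split(same)[["x"]] - 1), 0.02)

  apart <- coda::mcmc.list(coda::mcmc(matrix(rnorm(4000, 0), ncol = 1,
                                             dimnames = list(NULL, "x"))),
                           coda::mcmc(matrix(rnorm(4000, 10), ncol = 1,
                                             dimnames = list(NULL, "x"))))
  expect_gt(rhat_split(apart)[["x"]], 1.1)

  single <- coda::mcmc.list(coda::mcmc(matrix(rnorm(100), ncol = 1)))
  expect_error(rhat_split(single), "2 chains")
})
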