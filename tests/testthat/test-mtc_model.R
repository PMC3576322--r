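test_that("model spec enforces its structural constraints", {
  expect_error(mtc_spec("binomial", baseline_multiplier = TRUE),
               "continuous")
  expect_error(mtc_spec("continuous", covariate_gamma = TRUE), "binomial")
  expect_error(mtc_spec("continuous", treatments = c("P", "Ada")), "P")
  expect_error(mtc_priors(effect_var = -1))
})

test_that("prior-only model density is the prior alone", {
  spec <- mtc_spec("continuous", c("Ada", "Eta"), mtx_adjust = TRUE)
  pri <- mtc_priors()
  m <- build_mtc_model(NULL, spec, pri)
  par <- list(a = c(0.2, -0.1), b = 0.05, sigma = 0.5)
  expected <- sum(dnorm(par$a, 0, 100, log = TRUE)) +
    dnorm(par$b, 0, 100, log = TRUE) + dunif(par$sigma, 0, 2, log = TRUE)
  expect_equal(m$log_density(par), expected, tolerance = 1e-12)
  # outside the heterogeneity prior support
  expect_identical(m$log_density(modifyList(par, list(sigma = 2.5))), -Inf)
})

test_that("single-trial continuous likelihood is the closed-form normal term", {
  cons <- data.frame(trial_id = "t1", drug = "Ada", delta_obs = 0.30,
                     se = 0.10, mtx_diff = 0, baseline = 1.5)
  spec <- mtc_spec("continuous", "Ada", mtx_adjust = FALSE,
                   baseline_multiplier = TRUE)
  pri <- mtc_priors()
  m <- build_mtc_model(cons, spec, pri)
  # at alpha = delta/lambda the likelihood term sits at its mode
  par <- list(a = 0.2, sigma = 0.1, alpha = 0.30 / 1.5)
  expected <- dnorm(0.30, 0.30, 0.10, log = TRUE) +
    dnorm(par$alpha, 0.2, 0.1, log = TRUE) +
    dnorm(0.2, 0, 100, log = TRUE) + dunif(0.1, 0, 2, log = TRUE)
  expect_equal(m$log_density(par), expected, tolerance = 1e-12)
})

test_that("continuous joint density matches the term-by-term oracle to 1e-10", {
  arms <- impute_missing_sd(filter_trials(bundled_arms(), "haq"))
  cons <- build_contrasts(arms)
  spec <- mtc_spec("continuous", baseline_multiplier = TRUE)
  pri <- mtc_priors()
  m <- build_mtc_model(cons, spec, pri)
  for (s in 1:5) {
    par <- random_par(m, seed = s)
    expect_equal(m$log_density(par),
                 oracle_log_density_continuous(cons, spec, pri, par),
                 tolerance = 1e-10)
  }
})

test_that("binomial joint density matches the term-by-term oracle to 1e-10", {
  arms <- filter_trials(bundled_arms(), "acr20")
  pri <- mtc_priors()
  for (gamma_flag in c(FALSE, TRUE)) {
    spec <- mtc_spec("binomial", covariate_gamma = gamma_flag)
    m <- build_mtc_model(arms, spec, pri, response = "acr20")
    for (s in 1:3) {
      par <- random_par(m, seed = 10 * s + gamma_flag)
      expect_equal(m$log_density(par),
                   oracle_log_density_binomial(arms, spec, pri, par),
                   tolerance = 1e-10)
    }
  }
})

test_that("with no MTX-discordant arms the adjusted model reduces to the basic one", {
  cons <- data.frame(trial_id = c("t1", "t2"), drug = c("Ada", "Eta"),
                     delta_obs = c(0.3, 0.4), se = c(0.1, 0.12),
                     mtx_diff = c(0, 0), baseline = c(1.5, 1.6))
  pri <- mtc_priors()
  m_adj <- build_mtc_model(cons, mtc_spec("continuous", c("Ada", "Eta"),
                                          mtx_adjust = TRUE), pri)
  m_basic <- build_mtc_model(cons, mtc_spec("continuous", c("Ada", "Eta"),
                                            mtx_adjust = FALSE), pri)
  par <- list(a = c(0.2, 0.25), sigma = 0.1, alpha = c(0.19, 0.27))
  par_b0 <- c(par, list(b = 0))
  expect_equal(m_adj$log_density(par_b0),
               m_basic$log_density(par) + dnorm(0, 0, 100, log = TRUE),
               tolerance = 1e-12)
})

test_that("model construction rejects mismatched inputs", {
  arms <- tiny_arms()
  cons <- build_contrasts(arms)
  expect_error(build_mtc_model(cons, mtc_spec("binomial")), "counts")
  expect_error(build_mtc_model(arms, mtc_spec("continuous")), "contrast")
  expect_error(build_mtc_model(cons, mtc_spec("continuous", "Ada")),
               "not in spec")
  arms$acr20[1] <- NA
  expect_error(build_mtc_model(arms, mtc_spec("binomial")), "missing counts")
})

test_that("pairwise contrasts are antisymmetric, transitive and placebo-anchored", {
  spec <- mtc_spec("continuous")
  fn <- pairwise_contrast_fn(spec)
  a <- c(0.20, 0.10, 0.31, 0.23, 0.25)
  ic <- fn(list(a = a))
  expect_equal(ic["Inf", "Ada"], -0.10)
  expect_equal(ic["Ada", "P"], 0.20)
  expect_equal(unname(diag(ic)), rep(0, 6))
  expect_equal(ic, -t(ic))
  set.seed(3)
  a <- rnorm(5)
  ic <- fn(a)
  for (k in 1:6) for (l in 1:6) for (j in 1:6)
    expect_equal(ic[k, l] + ic[l, j], ic[k, j], tolerance = 1e-12)
})

test_that("relabelling treatments permutes effects consistently", {
  arms <- filter_trials(bundled_arms(), "acr20")
  pri <- mtc_priors()
  t1 <- c("Ada", "Inf", "Eta", "Gol", "Cert")
  t2 <- rev(t1)
  m1 <- build_mtc_model(arms, mtc_spec("binomial", t1), pri)
  m2 <- build_mtc_model(arms, mtc_spec("binomial", t2), pri)
  par <- random_par(m1, seed = 4)
  par2 <- par
  par2$a <- par$a[match(t1, t2)]   # same effect per drug, reordered
  expect_equal(m1$log_density(par), m2$log_density(par2), tolerance = 1e-12)
})

test_that("density is proper: it falls toward -Inf at the parameter extremes", {
  arms <- impute_missing_sd(filter_trials(bundled_arms(), "haq"))
  cons <- build_contrasts(arms)
  m <- build_mtc_model(cons, mtc_spec("continuous", baseline_multiplier = TRUE),
                       mtc_priors())
  par <- random_par(m, seed = 8)
  base <- m$log_density(par)
  expect_true(is.finite(base))
  far <- par; far$a[1] <- 1e6
  expect_lt(m$log_density(far), base - 1e6)
  tiny <- par; tiny$sigma <- 1e-12
  expect_lt(m$log_density(tiny), base)
  out <- par; out$sigma <- 3
  expect_identical(m$log_density(out), -Inf)
})
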