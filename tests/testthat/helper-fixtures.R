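# Shared fixtures and small oracles for the test suite.

bundled_arms <- function() anti_tnf_trials()

# a minimal two-trial, two-drug arm table built in code
tiny_arms <- function() {
  data.frame(
    trial_id = c("t1", "t1", "t2", "t2"),
    drug = c("P", "Ada", "P", "Eta"),
    n = c(50, 55, 60, 58),
    mtx = c(1, 1, 0, 0),
    haq_mean = c(0.10, 0.40, 0.05, 0.45),
    haq_sd = c(0.5, 0.5, 0.6, 0.6),
    acr20 = c(10, 25, 12, 30),
    acr50 = c(5, 15, 6, 20),
    acr70 = c(2, 8, 3, 10),
    haq_baseline = c(1.5, 1.5, 1.6, 1.6),
    stringsAsFactors = FALSE)
}

# brute-force oracle: materialize one value per patient, then mean / pop-SD
acrcont_oracle <- function(groups, means) {
  vals <- rep(means, times = groups)
  mu <- mean(vals)
  list(mean = mu, sd = sqrt(mean((vals - mu)^2)))
}

# all permutations of 1..n (n <= 4 here)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = i - 1)
  }
  out
}

# short-but-converged MCMC settings for test fits
test_mcmc <- function(seed = 42, binomial = FALSE) {
  if (binomial) {
    mtc_mcmc(chains = 2, burn_in = 10000, samples = 12500, seed = seed)
  } else {
    mtc_mcmc(chains = 2, burn_in = 2000, samples = 6000, seed = seed)
  }
}

# arm table with the published derived responder counts attached
arms_with_published_counts <- function() {
  arms <- bundled_arms()
  pub <- published_derived_outcomes()
  stopifnot(identical(paste(arms$trial_id, arms$drug),
                      paste(pub$trial_id, pub$drug)))
  arms$haq20 <- pub$haq20
  arms$haq50 <- pub$haq50
  arms
}

# independent term-by-term joint log-density oracle, written directly from
# the model equations, deliberately row-by-row and unvectorized
oracle_log_density_continuous <- function(contrasts, spec, priors, par) {
  lp <- 0
  eff_keys <- unique(paste(contrasts$trial_id, contrasts$drug))
  for (j in seq_len(nrow(contrasts))) {
    e <- match(paste(contrasts$trial_id[j], contrasts$drug[j]), eff_keys)
    m <- par$alpha[e]
    if (spec$baseline_multiplier) m <- m * contrasts$baseline[j]
    if (spec$mtx_adjust) m <- m + par$b * contrasts$mtx_diff[j]
    lp <- lp + dnorm(contrasts$delta_obs[j], m, contrasts$se[j], log = TRUE)
  }
  for (e in seq_along(eff_keys)) {
    drug <- sub("^\\S+ ", "", eff_keys[e])
    k <- match(drug, spec$treatments)
    lp <- lp + dnorm(par$alpha[e], par$a[k], par$sigma, log = TRUE)
  }
  for (k in seq_along(spec$treatments))
    lp <- lp + dnorm(par$a[k], 0, sqrt(priors$effect_var), log = TRUE)
  if (spec$mtx_adjust)
    lp <- lp + dnorm(par$b, 0, sqrt(priors$effect_var), log = TRUE)
  lp + dunif(par$sigma, 0, priors$sigma_upper, log = TRUE)
}

oracle_log_density_binomial <- function(arms, spec, priors, par,
                                        response = "acr20") {
  lp <- 0
  studies <- unique(arms$trial_id)
  trt <- arms[arms$drug != "P", ]
  eff_keys <- unique(paste(trt$trial_id, trt$drug))
  for (s in seq_along(studies)) {
    ca <- arms[arms$trial_id == studies[s] & arms$drug == "P", ]
    eta <- par$mu[s]
    if (spec$mtx_adjust) eta <- eta + par$b * ca$mtx
    lp <- lp + dbinom(ca[[response]], ca$n, plogis(eta), log = TRUE)
    lp <- lp + dnorm(par$mu[s], 0, sqrt(priors$effect_var), log = TRUE)
  }
  for (j in seq_len(nrow(trt))) {
    s <- match(trt$trial_id[j], studies)
    e <- match(paste(trt$trial_id[j], trt$drug[j]), eff_keys)
    eta <- par$mu[s] + par$alpha[e]
    if (spec$mtx_adjust) eta <- eta + par$b * trt$mtx[j]
    if (spec$covariate_gamma) {
      lam_s <- arms$haq_baseline[arms$trial_id == studies[s] &
                                   arms$drug == "P"]
      eta <- eta + par$gamma * lam_s
    }
    lp <- lp + dbinom(trt[[response]][j], trt$n[j], plogis(eta), log = TRUE)
  }
  for (e in seq_along(eff_keys)) {
    drug <- sub("^\\S+ ", "", eff_keys[e])
    k <- match(drug, spec$treatments)
    lp <- lp + dnorm(par$alpha[e], par$a[k], par$sigma, log = TRUE)
  }
  for (k in seq_along(spec$treatments))
    lp <- lp + dnorm(par$a[k], 0, sqrt(priors$effect_var), log = TRUE)
  if (spec$mtx_adjust)
    lp <- lp + dnorm(par$b, 0, sqrt(priors$effect_var), log = TRUE)
  if (spec$covariate_gamma)
    lp <- lp + dnorm(par$gamma, 0, sqrt(priors$effect_var), log = TRUE)
  lp + dunif(par$sigma, 0, priors$sigma_upper, log = TRUE)
}

# random interior parameter point of the right dimensions
random_par <- function(model, seed = 1) {
  set.seed(seed)
  dims <- model$dims
  par <- list(a = rnorm(dims$K, 0, 0.5),
              sigma = runif(1, 0.05, 0.5))
  if (model$spec$mtx_adjust) par$b <- rnorm(1, 0, 0.3)
  if (dims$E > 0) par$alpha <- rnorm(dims$E, 0, 0.5)
  if (dims$S > 0) par$mu <- rnorm(dims$S, -1, 0.5)
  if (model$spec$covariate_gamma) par$gamma <- rnorm(1, 0, 0.2)
  par
}
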