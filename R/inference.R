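# Posterior sampling via JAGS (Gibbs sampling), with the long run lengths
# used for the published analyses as defaults and a short profile for
# simulation studies, justified by effective-sample-size diagnostics rather
# than run length.

#' MCMC configuration
#'
#' @param chains number of chains (>= 2, so convergence diagnostics are
#'   available).
#' @param burn_in iterations discarded per chain (includes the adaptation
#'   phase).
#' @param samples iterations kept per chain.
#' @param thin thinning interval (default 1; effective sample size is
#'   reported instead of thinning).
#' @param seed integer seed; the same seed and configuration reproduce the
#'   draws exactly.
#' @param profile `"paper"` (2 chains, 50,000 burn-in, 100,000 kept -- the
#'   published run lengths) or `"fast"` (4 chains, 2,500 kept each, for
#'   simulation studies and tests); explicit arguments override the profile.
#' @return an object of class `"mtc_mcmc"`.
#' @export
mtc_mcmc <- function(chains = NULL, burn_in = NULL, samples = NULL,
                     thin = 1, seed = 1, profile = c("paper", "fast")) {
  profile <- match.arg(profile)
  def <- switch(profile,
                paper = list(chains = 2, burn_in = 50000, samples = 100000),
                fast = list(chains = 4, burn_in = 2000, samples = 2500))
  chains <- if (is.null(chains)) def$chains else chains
  burn_in <- if (is.null(burn_in)) def$burn_in else burn_in
  samples <- if (is.null(samples)) def$samples else samples
  stopifnot(chains >= 2, samples >= 1000, burn_in >= 0, thin >= 1)
  structure(list(chains = chains, burn_in = burn_in, samples = samples,
                 thin = thin, seed = as.integer(seed), profile = profile),
            class = "mtc_mcmc")
}

# deterministic, jittered initial values; one list per chain
make_inits <- function(model, config) {
  dims <- model$dims
  spec <- model$spec
  up <- model$priors$sigma_upper
  jd <- model$jags_data
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  lapply(seq_len(config$chains), function(ch) {
    ini <- list(a = stats::rnorm(dims$K, 0, 0.1),
                sigma = stats::runif(1, 0.25 * up, 0.75 * up))
    if (spec$mtx_adjust) ini$b <- stats::rnorm(1, 0, 0.1)
    if (dims$E > 0) ini$alpha <- stats::rnorm(dims$E, 0, 0.1)
    if (spec$likelihood == "binomial" && dims$S > 0) {
      emp <- log((jd$rc + 0.5) / (jd$nc - jd$rc + 0.5))
      ini$mu <- emp + stats::rnorm(dims$S, 0, 0.1)
    }
    if (spec$covariate_gamma) ini$gamma <- stats::rnorm(1, 0, 0.1)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- config$seed * 100 + ch
    ini
  })
}

init_log_density <- function(model, ini) {
  par <- ini[setdiff(names(ini), c(".RNG.name", ".RNG.seed"))]
  model$log_density(par)
}

#' Sample the posterior of an MTC model
#'
#' Runs JAGS on the model's generated code with deterministic, seed-jittered
#' initial values (effects near 0, heterogeneity SD at mid-support,
#' control-group logits at their empirical values).  Initialization points
#' with non-finite joint density are rejected and redrawn up to a limit.
#' Convergence diagnostics (split-chain Rhat and effective sample size) are
#' computed on the kept draws; a warning is issued if any Rhat exceeds 1.1.
#'
#' @param model an [build_mtc_model()] object.
#' @param config an [mtc_mcmc()] configuration.
#' @param monitor extra node names to monitor (e.g. `"alpha"`).
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return an object of class `"mtc_draws"`: list with `samples` (a
#'   `coda::mcmc.list`), `spec`, `config`, `ess`, `rhat`.
#' @export
run_mcmc <- function(model, config = mtc_mcmc(), monitor = character(0),
                     quiet = TRUE) {
  stopifnot(inherits(model, "mtc_model"), inherits(config, "mtc_mcmc"))
  inits <- make_inits(model, config)
  for (attempt in 1:25) {
    ld <- vapply(inits, function(i) init_log_density(model, i), numeric(1))
    if (all(is.finite(ld))) break
    if (attempt == 25)
      stop("could not find finite-density initial values")
    config2 <- config
    config2$seed <- config$seed + 1000L * attempt
    bad <- which(!is.finite(ld))
    inits[bad] <- make_inits(model, config2)[bad]
  }

  vars <- c("a", "sigma")
  if (model$spec$mtx_adjust) vars <- c(vars, "b")
  if (model$spec$likelihood == "binomial" && model$dims$S > 0)
    vars <- c(vars, "mu")
  if (model$spec$covariate_gamma) vars <- c(vars, "gamma")
  vars <- unique(c(vars, monitor))

  n_adapt <- min(1000, config$burn_in)
  jm <- rjags::jags.model(textConnection(model$jags_code),
                          data = model$jags_data, inits = inits,
                          n.chains = config$chains, n.adapt = n_adapt,
                          quiet = quiet)
  if (config$burn_in > n_adapt)
    stats::update(jm, n.iter = config$burn_in - n_adapt,
                  progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = vars,
                                 n.iter = config$samples * config$thin,
                                 thin = config$thin,
                                 progress.bar = "none")
  out <- structure(list(samples = samples, spec = model$spec,
                        config = config, dims = model$dims),
                   class = "mtc_draws")
  out$ess <- effective_sample_size(out)
  out$rhat <- rhat_split(out)
  high <- out$rhat[is.finite(out$rhat) & out$rhat > 1.1]
  if (length(high) > 0)
    warning("possible non-convergence: Rhat > 1.1 for ",
            paste(names(high), collapse = ", "))
  out
}

as_mcmc_list <- function(x) {
  if (inherits(x, "mtc_draws")) return(x$samples)
  if (inherits(x, "mcmc.list")) return(x)
  if (is.matrix(x)) return(coda::mcmc.list(coda::mcmc(x)))
  stop("cannot interpret draws object")
}

#' Effective sample size per parameter
#'
#' Autocorrelation-adjusted effective number of independent draws, pooled
#' over chains (spectral estimate).  A numerically constant chain has no
#' defined autocorrelation time; its ESS is reported as `NA` with a warning.
#'
#' @param draws an `mtc_draws` object or a `coda::mcmc.list`.
#' @return named vector of effective sample sizes.
#' @export
effective_sample_size <- function(draws) {
  ml <- as_mcmc_list(draws)
  mat <- do.call(rbind, lapply(ml, as.matrix))
  ess <- coda::effectiveSize(ml)
  const <- apply(mat, 2, function(v) stats::var(v) < .Machine$double.eps)
  if (any(const)) {
    warning("constant chain(s) for ", paste(names(ess)[const], collapse = ", "),
            ": ESS undefined")
    ess[const] <- NA_real_
  }
  ess
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the usual between/within variance ratio is
#' computed over the resulting 2m half-chains; values near 1 indicate
#' convergence.  Requires at least two chains.
#'
#' @param draws an `mtc_draws` object or a `coda::mcmc.list`.
#' @return named vector of Rhat values (NaN for constant parameters).
#' @export
rhat_split <- function(draws) {
  ml <- as_mcmc_list(draws)
  if (length(ml) < 2) stop("rhat requires at least 2 chains")
  half <- function(m) {
    n <- floor(nrow(m) / 2)
    list(m[seq_len(n), , drop = FALSE],
         m[seq(nrow(m) - n + 1, nrow(m)), , drop = FALSE])
  }
  pieces <- unlist(lapply(ml, function(ch) half(as.matrix(ch))),
                   recursive = FALSE)
  n <- nrow(pieces[[1]])
  means <- sapply(pieces, colMeans)
  vars <- sapply(pieces, function(m) apply(m, 2, stats::var))
  if (is.null(dim(means))) {           # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
    pn <- colnames(as.matrix(ml[[1]]))
  } else pn <- rownames(means)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  var_plus <- (n - 1) / n * W + B / n
  rhat <- sqrt(var_plus / W)
  names(rhat) <- pn
  rhat
}
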