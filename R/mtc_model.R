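# Mixed treatment comparison models over a star-shaped network of
# placebo-controlled trials.
#
# Continuous likelihood (arm-vs-control differences):
#   Delta_j ~ N(alpha_{s(j),k} * lambda_j + b * (I.t_j - I.c_{s(j)}), se_j^2)
# with the baseline multiplier lambda_j optional (used for the raw HAQ
# improvement, where the drug effect scales with baseline disability, and
# dropped for measures that are already relative to baseline).
#
# Binomial likelihood (arm-level responder counts):
#   r.c_s ~ Bin(n.c_s, invlogit(mu_s + b * I.c_s))              once per study
#   r.t_j ~ Bin(n.t_j, invlogit(mu_{s(j)} + b * I.t_j + alpha_{s(j),k}
#                               [+ gamma * lambda_{s(j)}]))
#
# Hierarchy: alpha_{s,k} ~ N(a_k, sigma^2), shared by all arms of the same
# (study, drug) -- fixed effects within a study, random effects between
# trials, one heterogeneity SD for all comparisons.  The methotrexate effect
# b is a fixed effect.  Priors: normal(0, large variance) on all location
# parameters, uniform(0, upper) on sigma.

#' Specify an MTC model variant
#'
#' @param likelihood `"continuous"` (normal likelihood on arm-vs-control
#'   differences) or `"binomial"` (responder counts).
#' @param treatments ordered active-treatment labels; placebo `"P"` is always
#'   the reference and must not be listed.
#' @param mtx_adjust include the additive methotrexate effect `b`.
#' @param baseline_multiplier multiply the drug effect by the arm's baseline
#'   HAQ (continuous likelihood only).
#' @param covariate_gamma add the baseline-HAQ meta-regression term
#'   `gamma * lambda` to the treatment-arm logit (binomial likelihood only).
#' @return an object of class `"mtc_spec"`.
#' @export
mtc_spec <- function(likelihood = c("continuous", "binomial"),
                     treatments = TREATMENTS,
                     mtx_adjust = TRUE,
                     baseline_multiplier = FALSE,
                     covariate_gamma = FALSE) {
  likelihood <- match.arg(likelihood)
  stopifnot(length(treatments) >= 1, !"P" %in% treatments,
            !anyDuplicated(treatments))
  if (baseline_multiplier && likelihood != "continuous")
    stop("baseline_multiplier requires the continuous likelihood")
  if (covariate_gamma && likelihood != "binomial")
    stop("covariate_gamma requires the binomial likelihood")
  structure(list(likelihood = likelihood,
                 treatments = treatments,
                 mtx_adjust = mtx_adjust,
                 baseline_multiplier = baseline_multiplier,
                 covariate_gamma = covariate_gamma),
            class = "mtc_spec")
}

#' Prior hyperparameters for the MTC models
#'
#' Location parameters (basic effects, methotrexate effect, control-group
#' logits, meta-regression coefficient) get independent normal(0,
#' `effect_var`) priors; the between-trial SD gets a uniform(0,
#' `sigma_upper`) prior.
#'
#' @param effect_var prior variance of location parameters (default 10000,
#'   i.e. SD 100 -- vague on both the improvement-difference and log-odds
#'   scales).
#' @param sigma_upper upper bound of the uniform heterogeneity prior
#'   (default 2; sensitivity reruns use 5 or 7).
#' @return an object of class `"mtc_priors"`.
#' @export
mtc_priors <- function(effect_var = 10000, sigma_upper = 2) {
  stopifnot(effect_var > 0, sigma_upper > 0)
  structure(list(effect_var = effect_var, sigma_upper = sigma_upper),
            class = "mtc_priors")
}

#' Build an evaluable MTC model from data
#'
#' Assembles the index structures, the JAGS model code and an R evaluator of
#' the joint log-density for one model variant.  Continuous models take the
#' contrast table of [build_contrasts()]; binomial models take a validated
#' arm table plus the name of the responder-count column.  A model built from
#' zero rows of data is the prior alone.
#'
#' @param data contrasts (continuous) or arms (binomial); may be `NULL` or
#'   empty for a prior-only model.
#' @param spec an [mtc_spec()].
#' @param priors an [mtc_priors()].
#' @param response responder-count column for the binomial likelihood
#'   (e.g. `"acr20"`, `"haq20"`).
#' @return an object of class `"mtc_model"`: a list with the prepared data
#'   (`jags_data`), the model code (`jags_code`), parameter dimensions, and
#'   `log_density(par)`, where `par` is a named list with elements `a`
#'   (length-K vector, order of `spec$treatments`), `sigma`, and as
#'   applicable `b`, `alpha` (one per study-by-drug effect), `mu` (one per
#'   study), `gamma`.
#' @export
build_mtc_model <- function(data, spec, priors = mtc_priors(),
                            response = "acr20") {
  stopifnot(inherits(spec, "mtc_spec"), inherits(priors, "mtc_priors"))
  empty <- is.null(data) || nrow(data) == 0
  if (!empty && spec$likelihood == "binomial" && "delta_obs" %in% names(data))
    stop("binomial likelihood requires arm-level counts, not contrasts")
  if (!empty && spec$likelihood == "continuous" &&
      !"delta_obs" %in% names(data))
    stop("continuous likelihood requires a contrast table; see build_contrasts()")

  if (spec$likelihood == "continuous") {
    model <- build_continuous_model(data, spec, priors, empty)
  } else {
    model <- build_binomial_model(data, spec, priors, response, empty)
  }
  model$spec <- spec
  model$priors <- priors
  class(model) <- "mtc_model"
  model
}

build_continuous_model <- function(contrasts, spec, priors, empty) {
  K <- length(spec$treatments)
  if (!empty) {
    unknown <- setdiff(unique(contrasts$drug), spec$treatments)
    if (length(unknown) > 0)
      stop("treatment(s) in data but not in spec: ",
           paste(unknown, collapse = ", "))
    eff_key <- paste(contrasts$trial_id, contrasts$drug, sep = "\r")
    eff <- match(eff_key, unique(eff_key))
    E <- max(eff)
    drug_of_eff <- match(contrasts$drug[match(unique(eff_key), eff_key)],
                         spec$treatments)
    M <- nrow(contrasts)
    lam <- if (spec$baseline_multiplier) contrasts$baseline else rep(1, M)
    if (anyNA(lam)) stop("baseline HAQ missing but baseline_multiplier is on")
    xm <- contrasts$mtx_diff
    D <- contrasts$delta_obs
    se <- contrasts$se
  } else {
    M <- 0L; E <- 0L; drug_of_eff <- integer(0)
    lam <- xm <- D <- se <- numeric(0); eff <- integer(0)
  }

  jd <- list(K = K, prec.a = 1 / priors$effect_var, up = priors$sigma_upper)
  if (M > 0) {
    jd$M <- M; jd$E <- E
    jd$D <- D; jd$w <- 1 / se^2
    if (spec$baseline_multiplier) jd$lam <- lam
    if (spec$mtx_adjust) jd$xm <- xm
    jd$eff <- eff; jd$drug <- drug_of_eff
  }

  log_density <- function(par) {
    a <- par$a; sigma <- par$sigma
    stopifnot(length(a) == K, length(sigma) == 1)
    lp <- sum(stats::dnorm(a, 0, sqrt(priors$effect_var), log = TRUE)) +
      stats::dunif(sigma, 0, priors$sigma_upper, log = TRUE)
    if (spec$mtx_adjust)
      lp <- lp + stats::dnorm(par$b, 0, sqrt(priors$effect_var), log = TRUE)
    if (M > 0) {
      alpha <- par$alpha
      stopifnot(length(alpha) == E)
      lp <- lp + sum(stats::dnorm(alpha, a[drug_of_eff], sigma, log = TRUE))
      mu_j <- alpha[eff] * lam +
        (if (spec$mtx_adjust) par$b * xm else 0)
      lp <- lp + sum(stats::dnorm(D, mu_j, se, log = TRUE))
    }
    lp
  }

  list(jags_data = jd,
       jags_code = jags_code_continuous(spec, M > 0),
       dims = list(K = K, E = E, M = M, S = 0L),
       log_density = log_density)
}

build_binomial_model <- function(arms, spec, priors, response, empty) {
  K <- length(spec$treatments)
  if (!empty) {
    validate_arms(arms)
    if (!response %in% names(arms))
      stop("response column '", response, "' not found")
    if (anyNA(arms[[response]]))
      stop("response column '", response, "' has missing counts; ",
           "filter trials first")
    bad <- which(arms[[response]] > arms$n | arms[[response]] < 0)
    if (length(bad) > 0)
      stop("responder count outside [0, n] at row ", bad[1])
    unknown <- setdiff(setdiff(unique(arms$drug), "P"), spec$treatments)
    if (length(unknown) > 0)
      stop("treatment(s) in data but not in spec: ",
           paste(unknown, collapse = ", "))
    studies <- unique(arms$trial_id)
    S <- length(studies)
    ctl <- arms[arms$drug == "P", , drop = FALSE]
    ctl <- ctl[match(studies, ctl$trial_id), , drop = FALSE]
    trt <- arms[arms$drug != "P", , drop = FALSE]
    M <- nrow(trt)
    study <- match(trt$trial_id, studies)
    eff_key <- paste(trt$trial_id, trt$drug, sep = "\r")
    eff <- match(eff_key, unique(eff_key))
    E <- max(eff)
    drug_of_eff <- match(trt$drug[match(unique(eff_key), eff_key)],
                         spec$treatments)
    rc <- ctl[[response]]; nc <- ctl$n; Ic <- ctl$mtx
    rt <- trt[[response]]; nt <- trt$n; It <- trt$mtx
    lam_s <- ctl$haq_baseline        # study-level baseline for meta-regression
    if (spec$covariate_gamma && anyNA(lam_s))
      stop("study baseline HAQ missing but covariate_gamma is on")
  } else {
    S <- 0L; M <- 0L; E <- 0L
    rc <- nc <- Ic <- rt <- nt <- It <- lam_s <- numeric(0)
    study <- eff <- drug_of_eff <- integer(0)
  }

  jd <- list(K = K, prec.a = 1 / priors$effect_var, up = priors$sigma_upper)
  if (M > 0) {
    jd$S <- S; jd$M <- M; jd$E <- E
    jd$rc <- rc; jd$nc <- nc; jd$rt <- rt; jd$nt <- nt
    jd$study <- study; jd$eff <- eff; jd$drug <- drug_of_eff
    if (spec$mtx_adjust) { jd$Ic <- Ic; jd$It <- It }
    if (spec$covariate_gamma) jd$lam <- lam_s
  }

  log_density <- function(par) {
    a <- par$a; sigma <- par$sigma
    stopifnot(length(a) == K, length(sigma) == 1)
    lp <- sum(stats::dnorm(a, 0, sqrt(priors$effect_var), log = TRUE)) +
      stats::dunif(sigma, 0, priors$sigma_upper, log = TRUE)
    if (spec$mtx_adjust)
      lp <- lp + stats::dnorm(par$b, 0, sqrt(priors$effect_var), log = TRUE)
    if (spec$covariate_gamma)
      lp <- lp + stats::dnorm(par$gamma, 0, sqrt(priors$effect_var),
                              log = TRUE)
    if (M > 0) {
      alpha <- par$alpha; mu <- par$mu
      stopifnot(length(alpha) == E, length(mu) == S)
      lp <- lp + sum(stats::dnorm(mu, 0, sqrt(priors$effect_var), log = TRUE))
      lp <- lp + sum(stats::dnorm(alpha, a[drug_of_eff], sigma, log = TRUE))
      eta_c <- mu + (if (spec$mtx_adjust) par$b * Ic else 0)
      lp <- lp + sum(stats::dbinom(rc, nc, stats::plogis(eta_c), log = TRUE))
      eta_t <- mu[study] + alpha[eff] +
        (if (spec$mtx_adjust) par$b * It else 0) +
        (if (spec$covariate_gamma) par$gamma * lam_s[study] else 0)
      lp <- lp + sum(stats::dbinom(rt, nt, stats::plogis(eta_t), log = TRUE))
    }
    lp
  }

  list(jags_data = jd,
       jags_code = jags_code_binomial(spec, M > 0),
       dims = list(K = K, E = E, M = M, S = S),
       log_density = log_density)
}

jags_code_continuous <- function(spec, has_data) {
  lik <- if (has_data) paste0(
    "  for (j in 1:M) {\n",
    "    theta[j] <- alpha[eff[j]]",
    if (spec$baseline_multiplier) " * lam[j]" else "",
    if (spec$mtx_adjust) " + b * xm[j]" else "", "\n",
    "    D[j] ~ dnorm(theta[j], w[j])\n",
    "  }\n",
    "  for (e in 1:E) {\n",
    "    alpha[e] ~ dnorm(a[drug[e]], tau)\n",
    "  }\n") else ""
  paste0(
    "model {\n", lik,
    "  for (k in 1:K) {\n",
    "    a[k] ~ dnorm(0, prec.a)\n",
    "  }\n",
    if (spec$mtx_adjust) "  b ~ dnorm(0, prec.a)\n" else "",
    "  sigma ~ dunif(0, up)\n",
    "  tau <- 1 / (sigma * sigma)\n",
    "}\n")
}

jags_code_binomial <- function(spec, has_data) {
  lik <- if (has_data) paste0(
    "  for (s in 1:S) {\n",
    "    logit(pc[s]) <- mu[s]",
    if (spec$mtx_adjust) " + b * Ic[s]" else "", "\n",
    "    rc[s] ~ dbin(pc[s], nc[s])\n",
    "    mu[s] ~ dnorm(0, prec.a)\n",
    "  }\n",
    "  for (j in 1:M) {\n",
    "    logit(pt[j]) <- mu[study[j]] + alpha[eff[j]]",
    if (spec$mtx_adjust) " + b * It[j]" else "",
    if (spec$covariate_gamma) " + gamma * lam[study[j]]" else "", "\n",
    "    rt[j] ~ dbin(pt[j], nt[j])\n",
    "  }\n",
    "  for (e in 1:E) {\n",
    "    alpha[e] ~ dnorm(a[drug[e]], tau)\n",
    "  }\n") else ""
  paste0(
    "model {\n", lik,
    "  for (k in 1:K) {\n",
    "    a[k] ~ dnorm(0, prec.a)\n",
    "  }\n",
    if (spec$mtx_adjust) "  b ~ dnorm(0, prec.a)\n" else "",
    if (spec$covariate_gamma) "  gamma ~ dnorm(0, prec.a)\n" else "",
    "  sigma ~ dunif(0, up)\n",
    "  tau <- 1 / (sigma * sigma)\n",
    "}\n")
}

#' Pairwise indirect-comparison function
#'
#' Returns a function mapping a parameter set (or a bare basic-effect vector)
#' to the full antisymmetric matrix of indirect comparisons
#' `IC[k, l] = a_k - a_l`, with placebo included as reference (`a_P = 0`), so
#' `IC[k, "P"] = a_k`.
#'
#' @param spec an [mtc_spec()] with at least two treatments (placebo counts
#'   as one).
#' @return `function(par) -> matrix` with treatment-labelled dimnames.
#' @export
pairwise_contrast_fn <- function(spec) {
  stopifnot(inherits(spec, "mtc_spec"))
  labels <- c(spec$treatments, "P")
  if (length(labels) < 2) stop("need at least two treatments")
  function(par) {
    a <- if (is.list(par)) par$a else par
    stopifnot(length(a) == length(spec$treatments))
    full <- c(a, 0)
    ic <- outer(full, full, `-`)
    dimnames(ic) <- list(labels, labels)
    ic
  }
}
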