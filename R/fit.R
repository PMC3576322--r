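# User-facing modelling interface: one fitting function per outcome measure,
# returning a classed fit object with the usual methods.

#' Fit a mixed treatment comparison model to an arm-level trial table
#'
#' The single entry point for the analyses: picks the model variant the
#' outcome calls for, prepares the data (trial filtering, SD imputation,
#' derived-outcome construction), builds the hierarchical model and samples
#' its posterior.
#'
#' Outcome-to-model mapping:
#' \describe{
#'   \item{`haq`}{continuous likelihood on HAQ-improvement contrasts with the
#'     baseline-HAQ multiplier, so the basic parameters are fractions of
#'     baseline disability recovered.}
#'   \item{`acrcont`}{continuous likelihood on reconstructed continuous-ACR
#'     contrasts, no baseline multiplier (the measure is already relative to
#'     baseline).}
#'   \item{`acr20`, `acr50`, `acr70`}{binomial likelihood on the reported
#'     responder counts; effects are log odds ratios, reported as ORs.}
#'   \item{`haq20`, `haq50`}{binomial likelihood on dichotomized-HAQ
#'     responder counts.  If the table already carries `haq20`/`haq50`
#'     columns they are used as given; otherwise they are derived
#'     analytically via [dichotomize_haq()].}
#' }
#' All variants include the additive methotrexate effect.
#'
#' @param arms a validated arm table (see [read_trials()],
#'   [anti_tnf_trials()]).
#' @param outcome outcome measure, one of `"haq"`, `"haq20"`, `"haq50"`,
#'   `"acr20"`, `"acr50"`, `"acr70"`, `"acrcont"`.
#' @param priors an [mtc_priors()].
#' @param mcmc an [mtc_mcmc()] configuration.
#' @param means_source treatment-arm group means for the continuous-ACR
#'   reconstruction (`"meanACR"` default, `"ACRhybrid"` for the sensitivity
#'   variant).
#' @param mtx_adjust include the additive methotrexate term (default `TRUE`).
#' @param covariate_gamma add the baseline-HAQ meta-regression term
#'   (binomial outcomes only).
#' @param quiet suppress JAGS progress output.
#' @return an object of class `"mtc_fit"` with methods `print`, `summary`,
#'   `coef`, `plot` and `as.matrix`.
#' @examples
#' \dontrun{
#' arms <- anti_tnf_trials()
#' fit <- mtc_fit(arms, "haq", mcmc = mtc_mcmc(profile = "fast"))
#' summary(fit)
#' }
#' @export
mtc_fit <- function(arms,
                    outcome = c("haq", "haq20", "haq50", "acr20", "acr50",
                                "acr70", "acrcont"),
                    priors = mtc_priors(),
                    mcmc = mtc_mcmc(),
                    means_source = c("meanACR", "ACRhybrid"),
                    mtx_adjust = TRUE,
                    covariate_gamma = FALSE,
                    quiet = TRUE) {
  outcome <- match.arg(outcome)
  means_source <- match.arg(means_source)
  validate_arms(arms)
  arms <- filter_trials(arms, outcome)
  if (nrow(arms) == 0) stop("no trials report outcome '", outcome, "'")
  treatments <- TREATMENTS[TREATMENTS %in% arms$drug]

  if (outcome == "haq") {
    arms <- impute_missing_sd(arms)
    data <- build_contrasts(arms)
    spec <- mtc_spec("continuous", treatments, mtx_adjust = mtx_adjust,
                     baseline_multiplier = TRUE)
    model <- build_mtc_model(data, spec, priors)
  } else if (outcome == "acrcont") {
    arms <- add_derived_outcomes(arms, "acrcont", means_source = means_source)
    data <- build_contrasts(arms, mean_col = "acrcont_mean",
                            sd_col = "acrcont_sd")
    spec <- mtc_spec("continuous", treatments, mtx_adjust = mtx_adjust,
                     baseline_multiplier = FALSE)
    model <- build_mtc_model(data, spec, priors)
  } else {
    if (outcome %in% c("haq20", "haq50") && !outcome %in% names(arms)) {
      arms <- impute_missing_sd(arms)
      arms <- add_derived_outcomes(arms, outcome, mode = "analytic")
    }
    data <- arms
    spec <- mtc_spec("binomial", treatments, mtx_adjust = mtx_adjust,
                     covariate_gamma = covariate_gamma)
    model <- build_mtc_model(data, spec, priors, response = outcome)
  }

  draws <- run_mcmc(model, mcmc, quiet = quiet)
  structure(list(outcome = outcome,
                 spec = spec,
                 priors = priors,
                 model = model,
                 data = data,
                 draws = draws,
                 n_trials = length(unique(
                   if (is.data.frame(data)) data$trial_id else character(0))),
                 call = match.call()),
            class = "mtc_fit")
}

#' @export
print.mtc_fit <- function(x, ...) {
  cat("Mixed treatment comparison fit\n")
  cat("  outcome:    ", x$outcome, " (", x$spec$likelihood, " likelihood",
      if (x$spec$baseline_multiplier) ", baseline multiplier" else "",
      if (x$spec$mtx_adjust) ", additive MTX effect" else "", ")\n", sep = "")
  cat("  treatments: ", paste(x$spec$treatments, collapse = ", "),
      " (reference: P)\n", sep = "")
  cat("  trials:     ", x$n_trials, "\n", sep = "")
  cfg <- x$draws$config
  cat(sprintf("  mcmc:       %d chains, %s burn-in, %s kept per chain\n",
              cfg$chains,
              format(cfg$burn_in, big.mark = ",", scientific = FALSE),
              format(cfg$samples, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  diagnostics: max Rhat %.3f, min ESS %.0f\n",
              max(x$draws$rhat, na.rm = TRUE),
              min(x$draws$ess, na.rm = TRUE)))
  cat("\nPosterior means:\n")
  print(round(stats::coef(x), 3))
  invisible(x)
}

#' @export
summary.mtc_fit <- function(object, level = 0.8, ...) {
  summarize_comparisons(object, level = level)
}

#' @export
coef.mtc_fit <- function(object, ...) {
  mat <- as.matrix(object)
  trts <- object$spec$treatments
  K <- length(trts)
  a_cols <- if (K == 1) "a" else paste0("a[", seq_len(K), "]")
  out <- colMeans(mat[, a_cols, drop = FALSE])
  names(out) <- paste0("a_", trts)
  if (object$spec$mtx_adjust) out <- c(out, b = mean(mat[, "b"]))
  if (object$spec$covariate_gamma) out <- c(out, gamma = mean(mat[, "gamma"]))
  c(out, sigma = mean(mat[, "sigma"]))
}

#' @export
as.matrix.mtc_fit <- function(x, ...) {
  do.call(rbind, lapply(x$draws$samples, as.matrix))
}

#' @export
plot.mtc_fit <- function(x, level = 0.8, ...) {
  plot_forest(summarize_comparisons(x, level = level),
              main = sprintf("%s (%.0f%% CrI)", x$outcome, 100 * level))
}
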