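# Measurement-construction procedures: a continuous ACR response rebuilt from
# nested binary responder counts, and binary HAQ 20/50 responders derived from
# the continuous HAQ improvement.

# round half away from zero; stated explicitly because scaled responder counts
# sit on .5 boundaries more often than generic doubles
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Partition an arm into nested ACR response groups
#'
#' Converts nested cumulative responder counts into disjoint group sizes:
#' group 1 are non-responders (`n - acr20`), group 2 achieve ACR20 but not
#' ACR50, group 3 ACR50 but not ACR70, group 4 ACR70.
#'
#' @param n arm size.
#' @param acr20,acr50,acr70 nested responder counts.
#' @return integer vector `c(N1, N2, N3, N4)` summing to `n`.
#' @export
acr_group_counts <- function(n, acr20, acr50, acr70) {
  if (any(is.na(c(n, acr20, acr50, acr70))))
    stop("responder counts must be complete")
  if (!(acr70 >= 0 && acr70 <= acr50 && acr50 <= acr20 && acr20 <= n))
    stop("responder counts must be nested: 0 <= acr70 <= acr50 <= acr20 <= n")
  c(n - acr20, acr20 - acr50, acr50 - acr70, acr70)
}

#' Mean of the reconstructed continuous ACR response
#'
#' Weighted mean over the four response groups,
#' `sum(N_i * m_i) / N`, where `m_i` is the assumed mean response of group i
#' (see [acr_group_means()]).
#'
#' @param groups 4-vector of group sizes from [acr_group_counts()].
#' @param means 4-vector of group mean responses (fractions).
#' @return the arm mean continuous ACR response (fraction in \[-1, 1\]).
#' @export
acrcont_mean <- function(groups, means) {
  stopifnot(length(groups) == 4, length(means) == 4)
  n <- sum(groups)
  if (n <= 0) stop("arm size must be positive")
  sum(groups * means) / n
}

#' SD of the reconstructed continuous ACR response
#'
#' Population-form weighted standard deviation over the four response groups:
#' `sqrt(sum(N_i * (m_i - mean)^2) / N)` (divisor `N`, not `N - 1`).
#'
#' @inheritParams acrcont_mean
#' @return the arm SD of the continuous ACR response.
#' @export
acrcont_sd <- function(groups, means) {
  stopifnot(length(groups) == 4, length(means) == 4)
  n <- sum(groups)
  if (n <= 0) stop("arm size must be positive")
  mu <- sum(groups * means) / n
  sqrt(sum(groups * (means - mu)^2) / n)
}

#' Dichotomize a continuous HAQ improvement into responder counts
#'
#' A patient is a HAQ 20 (50) responder if their HAQ score improved by at
#' least 20% (50%) of the arm's baseline HAQ, i.e. the response threshold is
#' `cutoff * baseline` on the improvement scale.  Patient improvements are
#' modelled as normal with the arm's mean and SD.  In `"montecarlo"` mode
#' `n_draws` patient improvements are simulated, and the responder proportion
#' is scaled to the arm size and rounded (half away from zero) -- the
#' procedure that produced the bundled derived table.  `"analytic"` mode
#' returns the infinite-draw limit `n * (1 - pnorm((threshold - mean)/sd))`,
#' rounded the same way.
#'
#' @param mean,sd arm mean and SD of HAQ improvement (HAQ units); `sd = 0` is
#'   treated as a point mass.
#' @param n arm size.
#' @param baseline baseline HAQ score of the arm.
#' @param cutoff response cutoff as a fraction of baseline (0.2 or 0.5).
#' @param mode `"analytic"` (default) or `"montecarlo"`.
#' @param n_draws simulated patients in Monte-Carlo mode (default 1000).
#' @return integer responder count in `[0, n]`.
#' @export
dichotomize_haq <- function(mean, sd, n, baseline, cutoff = 0.2,
                            mode = c("analytic", "montecarlo"),
                            n_draws = 1000) {
  mode <- match.arg(mode)
  if (any(is.na(c(mean, sd, n, baseline))))
    stop("mean, sd, n and baseline must all be present")
  if (sd < 0) stop("sd must be non-negative")
  if (!cutoff %in% c(0.2, 0.5))
    stopifnot(cutoff > 0, cutoff < 1)
  threshold <- cutoff * baseline
  p <- if (sd == 0) {
    as.numeric(mean >= threshold)
  } else if (mode == "analytic") {
    1 - stats::pnorm((threshold - mean) / sd)
  } else {
    mean(stats::rnorm(n_draws, mean, sd) >= threshold)
  }
  count <- round_half_away(n * p)
  min(max(count, 0), n)
}

#' Add derived outcome columns to an arm table
#'
#' Applies the measurement constructions arm by arm: `haq20`/`haq50` responder
#' counts via [dichotomize_haq()] and the continuous ACR mean/SD via
#' [acrcont_mean()]/[acrcont_sd()] (treatment arms use the `means_source`
#' group means, control arms always the conservative control-group midpoints).
#' Arms with missing inputs get missing outputs.  With a fixed `seed` the
#' Monte-Carlo mode is fully reproducible.
#'
#' @param arms a validated arm table.
#' @param targets derived columns to add, subset of
#'   `c("haq20", "haq50", "acrcont")`.
#' @param means_source group means for treatment arms: `"meanACR"` (default)
#'   or `"ACRhybrid"`.
#' @param mode,n_draws passed to [dichotomize_haq()].
#' @param seed optional integer seed for Monte-Carlo mode.
#' @return `arms` with derived columns appended (`haq20`, `haq50`,
#'   `acrcont_mean`, `acrcont_sd` as requested).
#' @export
add_derived_outcomes <- function(arms,
                                 targets = c("haq20", "haq50", "acrcont"),
                                 means_source = c("meanACR", "ACRhybrid"),
                                 mode = c("analytic", "montecarlo"),
                                 n_draws = 1000, seed = NULL) {
  targets <- match.arg(targets, several.ok = TRUE)
  means_source <- match.arg(means_source)
  mode <- match.arg(mode)
  validate_arms(arms)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n_arm <- nrow(arms)
  if ("haq20" %in% targets || "haq50" %in% targets) {
    for (cutoff in c(0.2, 0.5)) {
      col <- if (cutoff == 0.2) "haq20" else "haq50"
      if (!col %in% targets) next
      arms[[col]] <- rep(NA_real_, n_arm)
      for (i in seq_len(n_arm)) {
        if (is.na(arms$haq_mean[i]) || is.na(arms$haq_sd[i]) ||
            is.na(arms$haq_baseline[i])) next
        arms[[col]][i] <- dichotomize_haq(arms$haq_mean[i], arms$haq_sd[i],
                                          arms$n[i], arms$haq_baseline[i],
                                          cutoff, mode = mode,
                                          n_draws = n_draws)
      }
    }
  }
  if ("acrcont" %in% targets) {
    m_trt <- acr_group_means(means_source)
    m_ctl <- acr_group_means("control")
    arms$acrcont_mean <- rep(NA_real_, n_arm)
    arms$acrcont_sd <- rep(NA_real_, n_arm)
    for (i in seq_len(n_arm)) {
      if (is.na(arms$acr20[i]) || is.na(arms$acr50[i]) || is.na(arms$acr70[i]))
        next
      g <- acr_group_counts(arms$n[i], arms$acr20[i], arms$acr50[i],
                            arms$acr70[i])
      m <- if (arms$drug[i] == "P") m_ctl else m_trt
      arms$acrcont_mean[i] <- acrcont_mean(g, m)
      arms$acrcont_sd[i] <- acrcont_sd(g, m)
    }
  }
  arms
}
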