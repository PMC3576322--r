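#' @keywords internal
"_PACKAGE"

# Treatment coding used throughout: placebo "P" plus the five anti-TNF agents.
TREATMENTS <- c("Ada", "Inf", "Eta", "Gol", "Cert")

ARM_COLS <- c("trial_id", "drug", "n", "mtx", "haq_mean", "haq_sd",
              "acr20", "acr50", "acr70", "haq_baseline")

#' Read an arm-level trial table
#'
#' Reads a delimited file with one row per trial arm and validates it.  The
#' expected columns are `trial_id`, `drug` (one of `P`, `Ada`, `Inf`, `Eta`,
#' `Gol`, `Cert`), `n`, `mtx` (0/1 indicator of concurrent methotrexate),
#' `haq_mean`, `haq_sd` (mean and SD of the HAQ improvement, HAQ units),
#' `acr20`, `acr50`, `acr70` (responder counts) and `haq_baseline` (baseline
#' HAQ score, 0--3).  Missing summaries are marked `-` in the bundled fixtures
#' and become `NA`; they are never silently zeroed.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator, default `","`.
#' @param na strings to treat as missing, default `"-"`.
#' @return a validated `data.frame` of arms, row order preserved.
#' @seealso [anti_tnf_trials()] for the bundled dataset, [validate_arms()].
#' @export
read_trials <- function(path, sep = ",", na = c("-", "NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  arms <- utils::read.table(path, header = TRUE, sep = sep,
                            na.strings = na, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ARM_COLS, names(arms))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("n", "mtx", "haq_mean", "haq_sd", "acr20", "acr50", "acr70",
                "haq_baseline")) {
    v <- suppressWarnings(as.numeric(arms[[col]]))
    bad <- which(!is.na(arms[[col]]) & is.na(v))
    if (length(bad) > 0)
      stop("malformed value in column '", col, "' at row ", bad[1])
    arms[[col]] <- v
  }
  validate_arms(arms)
  arms
}

#' Validate an arm-level trial table
#'
#' Checks the structural invariants of the arm table: responder counts are
#' nested (`acr70 <= acr50 <= acr20 <= n`), sample sizes are positive, the
#' methotrexate indicator is 0/1, baseline HAQ lies in \[0, 3\], SDs are
#' non-negative, and every trial has exactly one placebo arm and at least one
#' treatment arm.  Errors name the offending row.
#'
#' @param arms a `data.frame` of arms as returned by [read_trials()].
#' @return `arms`, invisibly, if valid.
#' @export
validate_arms <- function(arms) {
  stopifnot(is.data.frame(arms))
  missing_cols <- setdiff(ARM_COLS, names(arms))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(arms) == 0) return(invisible(arms))

  bad_drug <- which(!arms$drug %in% c("P", TREATMENTS))
  if (length(bad_drug) > 0)
    stop("unknown drug '", arms$drug[bad_drug[1]], "' at row ", bad_drug[1])
  bad_n <- which(is.na(arms$n) | arms$n < 1)
  if (length(bad_n) > 0) stop("invalid patient count at row ", bad_n[1])
  bad_mtx <- which(!arms$mtx %in% c(0, 1))
  if (length(bad_mtx) > 0) stop("mtx indicator must be 0/1 at row ", bad_mtx[1])
  bad_base <- which(!is.na(arms$haq_baseline) &
                      (arms$haq_baseline < 0 | arms$haq_baseline > 3))
  if (length(bad_base) > 0)
    stop("baseline HAQ outside [0, 3] at row ", bad_base[1])
  bad_sd <- which(!is.na(arms$haq_sd) & arms$haq_sd < 0)
  if (length(bad_sd) > 0) stop("negative haq_sd at row ", bad_sd[1])

  # nested responder counts, ignoring missing cells
  chk <- function(lo, hi, lab) {
    bad <- which(!is.na(arms[[lo]]) & !is.na(arms[[hi]]) &
                   (arms[[lo]] > arms[[hi]]))
    if (length(bad) > 0)
      stop("responder counts not nested (", lab, ") at row ", bad[1])
  }
  chk("acr20", "n", "acr20 > n")
  chk("acr50", "acr20", "acr50 > acr20")
  chk("acr70", "acr50", "acr70 > acr50")
  bad_neg <- which(!is.na(arms$acr70) & arms$acr70 < 0)
  if (length(bad_neg) > 0) stop("negative responder count at row ", bad_neg[1])

  for (id in unique(arms$trial_id)) {
    d <- arms$drug[arms$trial_id == id]
    if (sum(d == "P") != 1)
      stop("trial '", id, "' must have exactly one placebo (control) arm")
    if (sum(d != "P") < 1)
      stop("trial '", id, "' has no treatment arm")
    if (length(unique(d[d != "P"])) > 1)
      stop("trial '", id, "' compares more than one active drug; ",
           "the evidence network is star-shaped")
  }
  invisible(arms)
}

#' Bundled anti-TNF trial dataset
#'
#' The arm-level summary data of the sixteen placebo-controlled randomized
#' trials of adalimumab, infliximab, etanercept, golimumab and certolizumab
#' in methotrexate-experienced rheumatoid arthritis used throughout the
#' package: 16 placebo arms and 34 treatment arms.
#'
#' @return a validated `data.frame` of 50 arms.
#' @export
anti_tnf_trials <- function() {
  read_trials(system.file("extdata", "anti_tnf_trials.csv", package = "ramtc"))
}

#' Published derived outcomes (HAQ 20/50 responders and continuous ACR)
#'
#' The published per-arm table of derived outcomes accompanying the bundled
#' trials: HAQ 20 and HAQ 50 responder counts obtained by 1000-draw
#' Monte-Carlo dichotomization of the continuous HAQ improvement, and the
#' reconstructed continuous ACR response (mean and SD).  These are given
#' inputs for the binary-HAQ models; the package can regenerate them with
#' [dichotomize_haq()] and [acrcont_mean()] up to Monte-Carlo noise.
#'
#' @return a `data.frame` with columns `trial_id`, `drug`, `n`, `haq20`,
#'   `haq50`, `acrcont_mean`, `acrcont_sd`.
#' @export
published_derived_outcomes <- function() {
  utils::read.csv(system.file("extdata", "derived_outcomes_published.csv",
                              package = "ramtc"),
                  na.strings = "-", stringsAsFactors = FALSE)
}

#' Mean continuous ACR response by responder group
#'
#' Mean percentage improvement (as a fraction) assumed for the four nested ACR
#' response groups (non-responders; ACR20-not-50; ACR50-not-70; ACR70), as
#' estimated from patient-level registry data for treated patients
#' (`"meanACR"`, the default, and `"ACRhybrid"`) or taken as conservative
#' interval midpoints for control groups (`"control"`: 0.00, 0.35, 0.60,
#' 0.85).
#'
#' @param source one of `"meanACR"`, `"ACRhybrid"`, `"control"`.
#' @return numeric vector of length 4, non-decreasing, in \[-1, 1\].
#' @export
acr_group_means <- function(source = c("meanACR", "ACRhybrid", "control")) {
  source <- match.arg(source)
  tab <- utils::read.csv(system.file("extdata", "acr_group_means.csv",
                                     package = "ramtc"),
                         stringsAsFactors = FALSE)
  m <- as.numeric(tab[tab$source == source, paste0("group", 1:4)])
  stopifnot(length(m) == 4, !is.unsorted(m), all(m >= -1 & m <= 1))
  m
}

#' Estimate a standard deviation from an interquartile range
#'
#' Normal-approximation conversion used when a trial reports an IQR instead of
#' an SD: `sd = iqr / (2 * qnorm(0.75))`, i.e. division by about 1.349.
#'
#' @param iqr non-negative interquartile range, outcome units.
#' @return estimated SD in the same units.
#' @export
sd_from_iqr <- function(iqr) {
  if (any(is.na(iqr)) || any(iqr < 0)) stop("iqr must be non-negative")
  iqr / (2 * stats::qnorm(0.75))
}

#' Impute missing HAQ-improvement SDs with the maximum observed SD
#'
#' For arms that report a mean HAQ improvement but no SD, substitutes the
#' maximum SD observed anywhere in the dataset (the most conservative of the
#' standard missing-SD rules).  The returned table carries an
#' `"sd_imputation"` attribute listing every imputed cell.
#'
#' @param arms a validated arm table.
#' @return `arms` with `haq_sd` completed where `haq_mean` is present.
#' @export
impute_missing_sd <- function(arms) {
  validate_arms(arms)
  if (all(is.na(arms$haq_sd)))
    stop("all haq_sd missing: no basis for imputation")
  max_sd <- max(arms$haq_sd, na.rm = TRUE)
  idx <- which(!is.na(arms$haq_mean) & is.na(arms$haq_sd))
  report <- data.frame(row = idx,
                       trial_id = arms$trial_id[idx],
                       drug = arms$drug[idx],
                       imputed_sd = rep(max_sd, length(idx)))
  arms$haq_sd[idx] <- max_sd
  attr(arms, "sd_imputation") <- report
  arms
}

#' Restrict a trial table to trials reporting a given outcome completely
#'
#' A trial is kept only if the summaries required for `outcome` are present in
#' every one of its arms: the mean HAQ improvement for `haq`/`haq20`/`haq50`
#' (the SD may still be imputed) and the nested ACR responder counts for
#' `acr20`/`acr50`/`acr70`/`acrcont`.
#'
#' @param arms a validated arm table.
#' @param outcome one of `"haq"`, `"haq20"`, `"haq50"`, `"acr20"`, `"acr50"`,
#'   `"acr70"`, `"acrcont"`.
#' @return the subset of `arms`; row order preserved.
#' @export
filter_trials <- function(arms,
                          outcome = c("haq", "haq20", "haq50", "acr20",
                                      "acr50", "acr70", "acrcont")) {
  outcome <- match.arg(outcome)
  validate_arms(arms)
  if (nrow(arms) == 0) return(arms)
  cols <- switch(outcome,
                 haq = , haq20 = , haq50 = c("haq_mean", "haq_baseline"),
                 acr20 = "acr20", acr50 = "acr50", acr70 = "acr70",
                 acrcont = c("acr20", "acr50", "acr70"))
  complete <- !Reduce(`|`, lapply(cols, function(cl) is.na(arms[[cl]])))
  keep_trials <- names(which(tapply(complete, arms$trial_id, all)))
  out <- arms[arms$trial_id %in% keep_trials, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Arm-versus-control contrasts for the continuous models
#'
#' For every treatment arm computes the observed relative effect
#' `delta_obs = mean_t - mean_c` and its sampling standard error
#' `se = sqrt(sd_t^2/n_t + sd_c^2/n_c)` against the trial's placebo arm,
#' together with the methotrexate indicator difference
#' `mtx_diff = I.t - I.c` and the treatment arm's baseline HAQ.  Arms sharing
#' a control each yield their own contrast; the induced correlation is
#' deliberately ignored, matching the independent-contrast likelihood of the
#' multi-arm model.
#'
#' @param arms a validated arm table.
#' @param mean_col,sd_col columns holding the arm mean and SD of the outcome
#'   (defaults: the HAQ improvement columns; use `acrcont_mean`/`acrcont_sd`
#'   after [add_derived_outcomes()] for the continuous ACR model).
#' @return a `data.frame` with one row per usable treatment arm: `trial_id`,
#'   `drug`, `delta_obs`, `se`, `mtx_diff`, `baseline`.  Treatment arms with a
#'   missing mean are skipped with a warning; a missing SD is an error
#'   (impute first).
#' @export
build_contrasts <- function(arms, mean_col = "haq_mean", sd_col = "haq_sd") {
  validate_arms(arms)
  out <- list()
  for (id in unique(arms$trial_id)) {
    tr <- arms[arms$trial_id == id, , drop = FALSE]
    ctl <- tr[tr$drug == "P", , drop = FALSE]
    trt <- tr[tr$drug != "P", , drop = FALSE]
    if (is.na(ctl[[mean_col]])) {
      warning("trial '", id, "': control arm mean missing; trial skipped")
      next
    }
    if (is.na(ctl[[sd_col]]))
      stop("trial '", id, "': control arm SD missing; impute first")
    for (j in seq_len(nrow(trt))) {
      if (is.na(trt[[mean_col]][j])) {
        warning("trial '", id, "': treatment arm ", j,
                " mean missing; arm skipped")
        next
      }
      if (is.na(trt[[sd_col]][j]))
        stop("trial '", id, "': treatment arm ", j, " SD missing; impute first")
      out[[length(out) + 1]] <- data.frame(
        trial_id = id,
        drug = trt$drug[j],
        delta_obs = trt[[mean_col]][j] - ctl[[mean_col]],
        se = sqrt(trt[[sd_col]][j]^2 / trt$n[j] +
                    ctl[[sd_col]]^2 / ctl$n),
        mtx_diff = trt$mtx[j] - ctl$mtx,
        baseline = trt$haq_baseline[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(trial_id = character(), drug = character(),
                      delta_obs = numeric(), se = numeric(),
                      mtx_diff = numeric(), baseline = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(all(res$se > 0), all(res$mtx_diff %in% c(-1, 0, 1)))
  res
}
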