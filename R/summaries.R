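# Posterior reporting surface: pairwise comparisons with equal-tailed
# credible intervals, significance flags, and forest-plot export.

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param draws numeric sample vector (at least 100 draws recommended).
#' @param level interval mass in (0, 1); default 0.8.
#' @return numeric `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 0.8) {
  if (length(draws) == 0) stop("no draws")
  stopifnot(level > 0, level < 1)
  unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE))
}

#' Summarize all pairwise treatment comparisons
#'
#' Builds the full reporting table from posterior draws: each active
#' treatment versus placebo, then every active-versus-active pair, then the
#' between-trial SD.  Continuous models are reported as differences in
#' improvement (null 0); binomial models as odds ratios, obtained by
#' exponentiating the log-odds-ratio draws draw-wise before averaging (so
#' the reported mean is the posterior mean of the OR).  A comparison is
#' flagged significant when its interval excludes the null.
#'
#' @param draws an `mtc_draws` or `mtc_fit` object.
#' @param level credible level (default 0.8).
#' @return a `data.frame` of class `"mtc_summary"` with columns
#'   `comparison`, `scale`, `mean`, `lo`, `hi`, `significant`.
#' @export
summarize_comparisons <- function(draws, level = 0.8) {
  if (inherits(draws, "mtc_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "mtc_draws"))
  spec <- draws$spec
  mat <- do.call(rbind, lapply(draws$samples, as.matrix))
  trts <- spec$treatments
  K <- length(trts)
  a_cols <- if (K == 1) "a" else paste0("a[", seq_len(K), "]")
  if (!all(a_cols %in% colnames(mat)))
    stop("basic parameters not found in draws")
  a <- mat[, a_cols, drop = FALSE]
  colnames(a) <- trts
  odds <- spec$likelihood == "binomial"
  scale_lab <- if (odds) "odds_ratio" else "difference"
  null_val <- if (odds) 1 else 0

  row_of <- function(label, d) {
    x <- if (odds) exp(d) else d
    ci <- credible_interval(x, level)
    data.frame(comparison = label, scale = scale_lab,
               mean = mean(x), lo = ci[1], hi = ci[2],
               significant = ci[1] > null_val | ci[2] < null_val,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (k in seq_len(K))
    rows[[length(rows) + 1]] <- row_of(paste(trts[k], "vs P"), a[, k])
  if (K >= 2) {
    for (k in 2:K) for (l in seq_len(k - 1))
      rows[[length(rows) + 1]] <- row_of(paste(trts[k], "vs", trts[l]),
                                         a[, k] - a[, l])
  }
  sig <- mat[, "sigma"]
  ci <- credible_interval(sig, level)
  rows[[length(rows) + 1]] <- data.frame(
    comparison = "sigma", scale = "sd", mean = mean(sig),
    lo = ci[1], hi = ci[2], significant = NA, stringsAsFactors = FALSE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("mtc_summary", "data.frame")
  out
}

#' @export
print.mtc_summary <- function(x, digits = 2, ...) {
  lv <- attr(x, "level")
  cat(sprintf("Pairwise comparisons (%s scale, %.0f%% credible intervals)\n",
              x$scale[1], 100 * lv))
  shown <- data.frame(
    comparison = x$comparison,
    estimate = sprintf("%.*f (%.*f, %.*f)%s", digits, x$mean, digits, x$lo,
                       digits, x$hi,
                       ifelse(!is.na(x$significant) & x$significant, " *", "")),
    stringsAsFactors = FALSE)
  print(shown, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Export a comparison table as CSV or forest plot
#'
#' @param summaries an [summarize_comparisons()] table.
#' @param path output file; extension is taken literally (use e.g. `.csv` or
#'   `.pdf`).
#' @param format `"csv"` writes one row per comparison; `"plot"` renders a
#'   forest plot (points and interval bars; odds ratios on a log axis;
#'   significant comparisons drawn in red).
#' @return `path`, invisibly.
#' @export
forest_export <- function(summaries, path, format = c("csv", "plot")) {
  format <- match.arg(format)
  stopifnot(inherits(summaries, "mtc_summary"))
  if (nrow(summaries) == 0) stop("empty summary table")
  if (!dir.exists(dirname(path)))
    stop("cannot write to ", path, ": directory does not exist")
  if (format == "csv") {
    utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  } else {
    grDevices::pdf(path, width = 7, height = 5.5)
    on.exit(grDevices::dev.off())
    plot_forest(summaries)
  }
  invisible(path)
}

# base-graphics forest plot; rows top to bottom, sigma row dropped
plot_forest <- function(summaries, main = NULL) {
  s <- summaries[summaries$comparison != "sigma", , drop = FALSE]
  odds <- s$scale[1] == "odds_ratio"
  null_val <- if (odds) 1 else 0
  n <- nrow(s)
  y <- rev(seq_len(n))
  xlim <- range(c(s$lo, s$hi, null_val))
  col <- ifelse(s$significant, "red3", "grey25")
  lv <- attr(summaries, "level")
  if (is.null(main))
    main <- sprintf("Pairwise efficacy (%.0f%% CrI)", 100 * lv)
  graphics::par(mar = c(4, 8, 3, 1))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5),
                 log = if (odds) "x" else "",
                 xlab = if (odds) "odds ratio" else "difference in improvement",
                 ylab = "", yaxt = "n", main = main)
  graphics::abline(v = null_val, lty = 2, col = "grey60")
  graphics::segments(s$lo, y, s$hi, y, col = col, lwd = 1.8)
  graphics::points(s$mean, y, pch = 15, col = col)
  graphics::axis(2, at = y, labels = s$comparison, las = 1, cex.axis = 0.8)
  invisible(NULL)
}
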