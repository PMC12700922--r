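#' Dice overlap coefficient
#'
#' `2|X intersect Y| / (|X| + |Y|)` between two binary masks of identical
#' shape; 1 for identical non-empty masks, 0 for disjoint ones. Both masks
#' empty is undefined and raises an error.
#'
#' @param x,y Logical arrays of the same shape (numeric arrays are treated as
#'   nonzero = foreground).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    abort_ctpa("masks must have identical shape", "ctpa_value_error")
  x <- as.logical(x); y <- as.logical(y)
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L)
    abort_ctpa("Dice undefined: both masks are empty", "ctpa_value_error")
  2 * sum(x & y) / (nx + ny)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Agreement between k raters over n subjects with the one-way ANOVA model:
#' `ICC = (MS_R - MS_w) / (MS_R + (k - 1) MS_w)` where `MS_R` is the
#' between-subject and `MS_w` the within-subject mean square. The 95%
#' confidence interval uses the exact F method for the single-rater one-way
#' ICC: with `F = MS_R / MS_w` on `(n - 1, n(k - 1))` degrees of freedom, the
#' bounds are `(F/F* - 1) / (F/F* + k - 1)` at the appropriate F quantiles.
#'
#' @param values Numeric n x k matrix: one row per subject, one column per
#'   rater; no missing cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci95` (lo, hi), `ms_between`, `ms_within`,
#'   `n`, `k`.
#' @export
icc_oneway <- function(values, conf_level = 0.95) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    abort_ctpa("ratings must be finite numerics with no missing cells", "ctpa_value_error")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    abort_ctpa("need at least 2 subjects and 2 raters", "ctpa_value_error")
  subj_means <- rowMeans(values)
  grand <- mean(values)
  ms_r <- k * sum((subj_means - grand)^2) / (n - 1)
  ms_w <- sum((values - subj_means)^2) / (n * (k - 1))
  if (ms_r == 0 && ms_w == 0)
    abort_ctpa("all ratings identical: ICC is degenerate", "ctpa_value_error")
  if (ms_w == 0) {
    icc <- 1
    ci <- c(1, 1)
  } else {
    icc <- (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
    alpha <- 1 - conf_level
    f_obs <- ms_r / ms_w
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci95 = ci, ms_between = ms_r, ms_within = ms_w, n = n, k = k)
}

#' Tolerance-based measurement accuracy
#'
#' A pair counts "correct" when the automated value is within a relative
#' tolerance of the manual one: `|auto - manual| / |manual| <= rel_tol`.
#' Accuracy is the fraction of correct pairs; its uncertainty is a seeded
#' bootstrap standard error over subjects.
#'
#' @param auto,manual Equal-length numeric vectors; `manual` must be nonzero.
#' @param rel_tol Relative tolerance defining "correct" (default 0.10).
#' @param B Number of bootstrap resamples for the standard error.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `acc` and `se`.
#' @export
accuracy <- function(auto, manual, rel_tol = 0.10, B = 1000L, seed = 20260101) {
  if (length(auto) != length(manual))
    abort_ctpa("auto and manual must have equal length", "ctpa_value_error")
  n <- length(auto)
  if (n < 1L) abort_ctpa("need at least one pair", "ctpa_value_error")
  if (any(manual == 0))
    abort_ctpa("manual values must be nonzero for relative tolerance", "ctpa_value_error")
  if (rel_tol <= 0) abort_ctpa("rel_tol must be > 0", "ctpa_value_error")
  correct <- abs(auto - manual) / abs(manual) <= rel_tol
  acc <- mean(correct)
  se <- with_seed(seed, {
    boots <- vapply(seq_len(B), function(i) mean(correct[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    stats::sd(boots)
  })
  list(acc = acc, se = se)
}

#' Bland-Altman agreement analysis
#'
#' Differences `auto - manual` summarized by their mean (bias) and 95% limits
#' of agreement `bias +/- 1.96 sd` (sample standard deviation, n - 1). The
#' per-pair means are returned for plotting differences against means.
#'
#' @param auto,manual Equal-length numeric vectors, n >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `diffs`,
#'   `means`.
#' @export
bland_altman <- function(auto, manual) {
  if (length(auto) != length(manual))
    abort_ctpa("auto and manual must have equal length", "ctpa_value_error")
  if (length(auto) < 2L)
    abort_ctpa("Bland-Altman needs at least 2 pairs", "ctpa_value_error")
  diffs <- auto - manual
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, diffs = diffs, means = (auto + manual) / 2)
}

#' Per-index agreement between automated and manual measurements
#'
#' For each index present in the records, pairs each subject's `auto` and
#' `manual` value, builds the n x 2 ratings matrix, and computes
#' [icc_oneway()], [accuracy()] and [bland_altman()]. Every subject must have
#' exactly one value per (index, source); unpaired subjects are an error
#' naming subject and index.
#'
#' @param records Measurement data frame (see [measurement_records()]) with
#'   both `auto` and `manual` rows.
#' @param rel_tol Relative tolerance passed to [accuracy()].
#' @param boot_seed Seed for the accuracy bootstrap.
#' @return Named list (one entry per index) of agreement reports: `icc`,
#'   `icc_ci95`, `accuracy`, `accuracy_se`, `bland_altman`, `n`.
#' @export
evaluate_agreement <- function(records, rel_tol = 0.10, boot_seed = 20260101) {
  records <- validate_measurements(records)
  out <- list()
  for (index in intersect(INDEX_NAMES, unique(records$index_name))) {
    ri <- records[records$index_name == index, ]
    a <- ri[ri$source == "auto", ]
    m <- ri[ri$source == "manual", ]
    dup <- c(a$subject_id[duplicated(a$subject_id)],
             m$subject_id[duplicated(m$subject_id)])
    if (length(dup))
      abort_ctpa(sprintf("duplicate %s measurements for subject(s) %s",
                         index, paste(unique(dup), collapse = ", ")),
                 "ctpa_value_error")
    unpaired <- union(setdiff(a$subject_id, m$subject_id),
                      setdiff(m$subject_id, a$subject_id))
    if (length(unpaired))
      abort_ctpa(sprintf("subject(s) %s lack a paired auto/manual %s value",
                         paste(sort(unpaired), collapse = ", "), index),
                 "ctpa_value_error")
    ids <- sort(a$subject_id)
    av <- a$value[match(ids, a$subject_id)]
    mv <- m$value[match(ids, m$subject_id)]
    icc <- icc_oneway(cbind(auto = av, manual = mv))
    acc <- accuracy(av, mv, rel_tol = rel_tol, seed = boot_seed)
    ba <- bland_altman(av, mv)
    out[[index]] <- list(icc = icc$icc, icc_ci95 = icc$ci95,
                         accuracy = acc$acc, accuracy_se = acc$se,
                         bland_altman = ba, n = length(ids))
  }
  if (!length(out))
    abort_ctpa("no recognized index measurements in records", "ctpa_value_error")
  out
}

#' Bland-Altman plot for one index
#'
#' Differences against means with the bias and 95% limits of agreement drawn
#' as horizontal lines.
#'
#' @param ba Result of [bland_altman()].
#' @param path PNG output path.
#' @param title Plot title.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(ba, path, title = "Bland-Altman") {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(ba$means, ba$diffs, pch = 19, col = "steelblue",
                 xlab = "Mean of auto and manual", ylab = "Auto - manual",
                 main = title)
  graphics::abline(h = ba$bias, col = "black", lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "firebrick", lty = 2)
  invisible(path)
}
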