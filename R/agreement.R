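# Log-scale test-retest agreement statistics: within-lesion SD and CV,
# repeatability coefficient, one-way ICC, Bland-Altman ratio limits of
# agreement, and Q-Q coordinates.
#
# Two spread estimators are deliberately kept distinct: sigma_w =
# sqrt(sum(d^2) / (2n)) (no mean subtraction; the Bland-Altman
# within-subject SD) feeds the repeatability coefficient, while the
# mean-subtracted n-1 SD of the log differences feeds the limits of
# agreement and the sample-size module.

# accept a 2-column object (test, retest) or the data frame from
# extract_pairs(); returns a 2-column numeric matrix
.as_pairs <- function(pairs) {
  if (is.data.frame(pairs) && all(c("test", "retest") %in% names(pairs)))
    pairs <- cbind(pairs$test, pairs$retest)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) .stop_validation("pairs must have two columns (test, retest)")
  storage.mode(pairs) <- "double"
  pairs
}

#' Paired log differences
#'
#' For each lesion, `d = log(retest) - log(test)`: the log of the
#' retest/test ratio, the quantity all repeatability statistics are built
#' on.
#'
#' @param pairs two columns (test, retest); the data frame from
#'   [extract_pairs()] is accepted directly.
#' @return Numeric vector of log differences, one per lesion, order
#'   preserved.
#' @export
#' @examples
#' log_paired_diffs(extract_pairs(table1_fixture(), "k1"))
log_paired_diffs <- function(pairs) {
  p <- .as_pairs(pairs)
  if (any(!is.finite(p)) || any(p <= 0))
    .stop_validation("log_paired_diffs: all measurement values must be > 0")
  log(p[, 2]) - log(p[, 1])
}

#' Within-subject SD of log differences
#'
#' The Bland-Altman within-subject SD for two replicates,
#' \eqn{\sigma_w = \sqrt{\sum d_i^2 / (2n)}} (no mean subtraction).  On the
#' log scale, `100 * sigma_w` reads as the within-subject coefficient of
#' variation (small-sigma approximation).
#'
#' @param diffs log differences from [log_paired_diffs()] (`n >= 2`).
#' @return Non-negative scalar.
#' @export
within_subject_sd <- function(diffs) {
  if (length(diffs) < 2L) .stop_validation("within_subject_sd: need n >= 2")
  sqrt(sum(diffs^2) / (2 * length(diffs)))
}

#' Repeatability coefficient as a percent change
#'
#' \eqn{RC\% = 100\,(e^{1.96 \sqrt{2} \sigma_w} - 1)}: the relative
#' test-retest difference that 95% of repeated measurements are expected to
#' stay within, back-transformed from the log scale.
#'
#' @param sigma_w_log within-subject log-scale SD (`>= 0`).
#' @return RC in percent (`>= 0`, monotone in `sigma_w_log`).
#' @export
#' @examples
#' repeatability_percent(0.1)  # ~31.9
repeatability_percent <- function(sigma_w_log) {
  if (any(sigma_w_log < 0)) .stop_validation("repeatability_percent: sigma must be >= 0")
  100 * (exp(1.96 * sqrt(2) * sigma_w_log) - 1)
}

#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) from the one-way ANOVA decomposition of the log-transformed
#' values with lesion as the grouping factor and `k = 2` replicates:
#' \eqn{(MS_B - MS_W)/(MS_B + MS_W)}.
#'
#' @param pairs two columns (test, retest) of positive values; the ICC is
#'   computed on the log scale.
#' @param log transform to the log scale first (default `TRUE`).
#' @return Scalar in `(-1, 1]`.
#' @export
#' @examples
#' icc_oneway(extract_pairs(table1_fixture(), "k1"))  # 0.98
icc_oneway <- function(pairs, log = TRUE) {
  p <- .as_pairs(pairs)
  n <- nrow(p)
  if (n < 2L) .stop_validation("icc_oneway: need at least 2 lesions")
  if (log) {
    if (any(p <= 0)) .stop_validation("icc_oneway: values must be > 0 on the log scale")
    p <- base::log(p)
  }
  gm <- rowMeans(p)
  grand <- mean(p)
  msb <- 2 * sum((gm - grand)^2) / (n - 1)
  msw <- sum((p - gm)^2) / n
  if (msb + msw <= 0) .stop_compute("icc_oneway: zero total variance, ICC undefined")
  (msb - msw) / (msb + msw)
}

#' Bland-Altman limits of agreement on the ratio scale
#'
#' Mean and 95% limits of agreement of the log differences, back-transformed
#' to retest/test ratios: `exp(mean_d +/- 1.96 * sd_d)` with the
#' mean-subtracted, `n - 1` SD.  Asymmetric ratio limits are reported as
#' such, not symmetrised.
#'
#' @inheritParams icc_oneway
#' @return A list: `mean_ratio`, `loa_ratio_low`, `loa_ratio_high`,
#'   `mean_log_diff`, `sd_log_diff`.
#' @export
bland_altman <- function(pairs) {
  d <- log_paired_diffs(pairs)
  if (length(d) < 2L) .stop_validation("bland_altman: need n >= 2")
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_ratio = exp(m), loa_ratio_low = exp(m - 1.96 * s),
       loa_ratio_high = exp(m + 1.96 * s), mean_log_diff = m, sd_log_diff = s)
}

#' Normal Q-Q coordinates of the log differences
#'
#' Ordered differences paired with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`, for visual normality checks.
#'
#' @param diffs numeric vector (`n >= 3`).
#' @return Data frame with columns `theoretical`, `observed`.
#' @export
qq_normal_coords <- function(diffs) {
  n <- length(diffs)
  if (n < 3L) .stop_validation("qq_normal_coords: need n >= 3")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             observed = sort(diffs))
}

#' Test-retest repeatability report
#'
#' Runs the full agreement chain — log differences, within-subject SD and
#' CV, repeatability coefficient, one-way ICC, Bland-Altman ratio limits —
#' for each measure of a paired table.
#'
#' @param table a [paired_table].
#' @param measures measures to analyse (default all four).
#' @return A data frame of class `"repeatability"`, one row per measure,
#'   with columns `measure`, `n_lesions`, `mean_log_diff`, `sd_log_diff`,
#'   `sigma_w_log`, `wcv_percent`, `repeatability_percent`, `icc`,
#'   `mean_ratio`, `loa_ratio_low`, `loa_ratio_high`.
#' @export
#' @examples
#' repeatability(table1_fixture())
repeatability <- function(table, measures = c("k1", "suv_max", "suv_mean", "suv_peak")) {
  stopifnot(inherits(table, "paired_table"))
  rows <- lapply(measures, function(m) {
    pr <- extract_pairs(table, m)
    d <- log_paired_diffs(pr)
    sw <- within_subject_sd(d)
    ba <- bland_altman(pr)
    data.frame(measure = m, n_lesions = length(d),
               mean_log_diff = ba$mean_log_diff, sd_log_diff = ba$sd_log_diff,
               sigma_w_log = sw, wcv_percent = 100 * sw,
               repeatability_percent = repeatability_percent(sw),
               icc = icc_oneway(pr), mean_ratio = ba$mean_ratio,
               loa_ratio_low = ba$loa_ratio_low,
               loa_ratio_high = ba$loa_ratio_high)
  })
  structure(do.call(rbind, rows), class = c("repeatability", "data.frame"))
}

#' @export
print.repeatability <- function(x, digits = 3, ...) {
  cat(sprintf("Test-retest repeatability (n = %d lesions)\n", x$n_lesions[1]))
  shown <- data.frame(measure = x$measure, ICC = round(x$icc, 2),
                      `repeatability %` = round(x$repeatability_percent, 1),
                      `wCV %` = round(x$wcv_percent, 1),
                      `mean ratio` = round(x$mean_ratio, digits),
                      `LoA low` = round(x$loa_ratio_low, digits),
                      `LoA high` = round(x$loa_ratio_high, digits),
                      check.names = FALSE)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' @export
plot.repeatability <- function(x, table, measure = "k1", ...) {
  pr <- extract_pairs(table, measure)
  d <- log_paired_diffs(pr)
  avg <- (pr$test + pr$retest) / 2
  row <- x[x$measure == measure, ]
  graphics::plot(avg, pr$retest / pr$test, log = "y",
                 xlab = sprintf("mean %s", measure),
                 ylab = "retest / test ratio", pch = 16, ...)
  graphics::abline(h = c(row$mean_ratio, row$loa_ratio_low, row$loa_ratio_high),
                   lty = c(1, 3, 3))
  invisible(x)
}
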