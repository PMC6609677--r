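# Paired log-normal sample-size calculation: subjects needed to detect a
# relative change with a two-sided paired t-test on log-transformed values.

#' Required sample size for a relative change in a paired log-normal measure
#'
#' Smallest number of subjects `n >= 2` such that a two-sided paired t-test
#' on the log-transformed values detects a relative change `1 + delta` with
#' the requested power.  The default is the iterative central-t condition
#' \deqn{t^{-1}(1 - \alpha/2;\, n-1) + t^{-1}(\mathrm{power};\, n-1) \le
#'       |\ln(1 + \delta)|\,\sqrt{n} / \sigma_d,}
#' iterated over `n`.  `method = "z"` gives the plain normal-approximation
#' sample size (a lower bound); `method = "exact"` uses the noncentral-t
#' power function.
#'
#' @param sigma_d log-scale SD of the paired differences (mean-subtracted,
#'   `n - 1` estimator; `> 0`).
#' @param relative_change signed relative change to detect, in `(-1, 0)` or
#'   `(0, 1)` (e.g. `-0.30` for a 30% decrease).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.95).
#' @param method `"t"` (iterative central-t, default), `"z"`
#'   (normal approximation) or `"exact"` (noncentral-t power).
#' @param n_max search cap.
#' @return Integer sample size (`>= 2`).
#' @export
#' @examples
#' d <- log_paired_diffs(extract_pairs(table1_fixture(), "k1"))
#' required_n(sd(d), -0.5)  # 3
required_n <- function(sigma_d, relative_change, alpha = 0.05, power = 0.95,
                       method = c("t", "z", "exact"), n_max = 1e6) {
  method <- match.arg(method)
  if (!is.finite(sigma_d) || sigma_d < 0)
    .stop_validation("required_n: sigma_d must be finite and >= 0")
  if (!is.finite(relative_change) || relative_change == 0 ||
      abs(relative_change) >= 1)
    .stop_validation("required_n: |relative_change| must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    .stop_validation("required_n: alpha and power must be in (0, 1)")
  delta <- abs(log(1 + relative_change))
  if (sigma_d == 0) return(2L)
  if (method == "z")
    return(max(2L, as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) *
                                         sigma_d / delta)^2))))
  for (n in 2:n_max) {
    ok <- if (method == "t") {
      qt(1 - alpha / 2, n - 1) + qt(power, n - 1) <= delta * sqrt(n) / sigma_d
    } else {
      .power_paired_t(n, sigma_d, delta, alpha) >= power
    }
    if (ok) return(as.integer(n))
  }
  .stop_compute("required_n: no n <= %g attains the requested power", n_max)
}

# exact power of the two-sided one-sample t-test via the noncentral t
.power_paired_t <- function(n, sigma, delta, alpha) {
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- sqrt(n) * delta / sigma
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Sample-size grid for a paired table
#'
#' Computes [required_n()] for every measure and requested relative change,
#' with `sigma_d` estimated per measure as the mean-subtracted `n - 1` SD of
#' the log test-retest differences.
#'
#' @param table a [paired_table].
#' @param changes relative changes to detect (default `-20%`, `-30%`,
#'   `-50%`).
#' @param alpha,power,method passed to [required_n()].
#' @param measures measures to include.
#' @return A data frame of class `"sample_size_table"` with columns
#'   `measure`, `relative_change`, `sigma_d`, `alpha`, `power`, `n`.
#' @export
#' @examples
#' sample_size_table(table1_fixture())
sample_size_table <- function(table, changes = c(-0.2, -0.3, -0.5),
                              alpha = 0.05, power = 0.95, method = "t",
                              measures = c("k1", "suv_max", "suv_mean", "suv_peak")) {
  stopifnot(inherits(table, "paired_table"))
  rows <- lapply(measures, function(m) {
    d <- log_paired_diffs(extract_pairs(table, m))
    sigma_d <- stats::sd(d)
    data.frame(measure = m, relative_change = changes, sigma_d = sigma_d,
               alpha = alpha, power = power,
               n = vapply(changes, function(ch)
                 required_n(sigma_d, ch, alpha, power, method), integer(1)))
  })
  structure(do.call(rbind, rows), class = c("sample_size_table", "data.frame"))
}

#' @export
print.sample_size_table <- function(x, ...) {
  cat(sprintf("Sample sizes for a paired log-normal design (alpha = %g two-sided, power = %g)\n",
              x$alpha[1], x$power[1]))
  wide <- stats::reshape(as.data.frame(x)[c("measure", "relative_change", "n")],
                         idvar = "measure", timevar = "relative_change",
                         direction = "wide")
  names(wide) <- sub("^n\\.", "N at ", names(wide))
  print.data.frame(wide, row.names = FALSE)
  invisible(x)
}
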