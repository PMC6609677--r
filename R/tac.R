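#' Time-activity curve
#'
#' Construct a framed time-activity curve (TAC): per-frame start time,
#' duration and frame-averaged activity concentration.  Frames must be
#' non-overlapping and strictly increasing.  All times are in seconds;
#' activity is in any consistent concentration unit (Bq/mL, SUV, ...).
#' Curves are assumed decay-corrected.
#'
#' @param start numeric vector of frame start times (s).
#' @param duration numeric vector of frame durations (s), all `> 0`.
#' @param value numeric vector of frame-averaged activity concentrations.
#' @return A data frame of class `"tac"` with columns `start`, `duration`,
#'   `value`.
#' @seealso [input_function()], [read_tac()], [write_tac()]
#' @export
#' @examples
#' tac(start = seq(0, 55, by = 5), duration = 5, value = dgamma(1:12, 3))
tac <- function(start, duration, value) {
  n <- length(start)
  duration <- rep_len(duration, n)
  if (length(value) != n)
    .stop_validation("tac: 'value' has length %d, expected %d", length(value), n)
  if (n == 0L) .stop_validation("tac: empty curve")
  if (!all(is.finite(start)) || !all(is.finite(duration)) || !all(is.finite(value)))
    .stop_validation("tac: non-finite frame times or values")
  if (any(duration <= 0)) .stop_validation("tac: frame durations must be > 0")
  if (is.unsorted(start, strictly = TRUE))
    .stop_validation("tac: frame starts must be strictly increasing")
  if (n > 1L && any(start[-1] < start[-n] + duration[-n] - 1e-9))
    .stop_validation("tac: frames overlap")
  structure(data.frame(start = as.numeric(start),
                       duration = as.numeric(duration),
                       value = as.numeric(value)),
            class = c("tac", "data.frame"))
}

.tac_mid <- function(x) x$start + x$duration / 2
.tac_end <- function(x) x$start[nrow(x)] + x$duration[nrow(x)]

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames, %.0f-%.0f s, peak %.4g at %.0f s\n",
              nrow(x), x$start[1], .tac_end(x), max(x$value),
              .tac_mid(x)[which.max(x$value)]))
  invisible(x)
}

#' Read / write a time-activity curve as CSV
#'
#' The on-disk format is comma-separated with header
#' `frame_start_s,frame_duration_s,value`.
#'
#' @param path file path.
#' @return `read_tac()` returns a [tac]; `write_tac()` invisibly returns
#'   `path`.
#' @export
read_tac <- function(path) {
  if (!file.exists(path)) .stop_validation("TAC file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_duration_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stop_validation("TAC file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tac(df$frame_start_s, df$frame_duration_s, df$value)
}

#' @param x a [tac].
#' @rdname read_tac
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(frame_start_s = x$start, frame_duration_s = x$duration,
                   value = x$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arterial input function
#'
#' An input function is a blood [tac] plus the delay and dispersion
#' parameters describing how it was aligned to the tissue of interest.
#' Freshly extracted image-derived input functions carry
#' `delay = dispersion_tau = 0`; [delay_dispersion_correct()] fills them in.
#'
#' @param curve a [tac] of blood activity.
#' @param delay time shift applied to the source curve (s).
#' @param dispersion_tau time constant of the mono-exponential dispersion
#'   kernel applied to the source curve (s, `>= 0`).
#' @return An object of class `"input_function"`.
#' @export
input_function <- function(curve, delay = 0, dispersion_tau = 0) {
  stopifnot(inherits(curve, "tac"))
  if (!is.finite(delay) || !is.finite(dispersion_tau) || dispersion_tau < 0)
    .stop_validation("input_function: delay/dispersion_tau must be finite, tau >= 0")
  structure(list(curve = curve, delay = as.numeric(delay),
                 dispersion_tau = as.numeric(dispersion_tau)),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function: %d frames, delay %.2f s, dispersion tau %.2f s\n",
              nrow(x$curve), x$delay, x$dispersion_tau))
  invisible(x)
}
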