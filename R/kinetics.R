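# One-tissue compartment kinetics, IDIF extraction, delay/dispersion correction.
#
# All internal integration uses a fine time grid on which the input curve is
# piecewise linear; the exponential convolution is then exact per grid
# interval, so coarse late frames introduce no quadrature error.

# exact \int_0^t e^{-b(t-s)} x(s) ds for x piecewise linear on grid t
# (values x at the grid nodes); returns the integral at every node, 0 at t[1]
.expconv_plin <- function(t, x, b) {
  n <- length(t)
  h <- diff(t)
  a0 <- x[-n]
  m <- (x[-1] - x[-n]) / h
  if (b <= 0) {
    inc <- a0 * h + m * h^2 / 2
    return(c(0, cumsum(inc)))
  }
  E <- exp(-b * h)
  inc <- a0 * (1 - E) / b + m * (h * (1 - E) / b - (1 - E * (1 + b * h)) / b^2)
  # y_{i+1} = y_i * E_i + inc_i; closed form via cumulative products unless
  # the decay underflows, in which case fall back to the sequential loop
  if (b * (t[n] - t[1]) < 500) {
    P <- cumprod(E)
    y <- P * cumsum(inc / P)
  } else {
    y <- numeric(n - 1L)
    acc <- 0
    for (i in seq_len(n - 1L)) {
      acc <- acc * E[i] + inc[i]
      y[i] <- acc
    }
  }
  c(0, y)
}

# fine grid covering [t0, t1] that contains every frame boundary and
# input-curve midpoint falling inside the span
.fine_grid <- function(t0, t1, frames, input_curve, dt) {
  g <- c(seq(t0, t1, by = dt), t1,
         frames$start, frames$start + frames$duration,
         .tac_mid(input_curve))
  g <- sort(unique(round(g, 9)))
  g[g >= t0 - 1e-9 & g <= t1 + 1e-9]
}

# input curve values at arbitrary times: piecewise linear between frame
# midpoints, constant beyond the first/last midpoint
.input_at <- function(input_curve, t) {
  mid <- .tac_mid(input_curve)
  if (length(mid) == 1L) return(rep(input_curve$value, length(t)))
  stats::approx(mid, input_curve$value, xout = t, rule = 2)$y
}

# trapezoidal frame averages of y sampled on grid t (frame edges are nodes)
.frame_average <- function(t, y, frames) {
  vapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    j <- which(t >= s - 1e-9 & t <= e + 1e-9)
    tt <- t[j]; yy <- y[j]
    sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) / (e - s)
  }, numeric(1))
}

# precompute grid, interpolated input and per-frame trapezoid weights so the
# model can be re-evaluated cheaply inside optimisation loops
.onetc_precompute <- function(input_curve, frames, dt) {
  fr_end <- max(frames$start + frames$duration)
  if (.tac_end(input_curve) < fr_end - 1e-6)
    .stop_validation("input curve (ends %.1f s) does not cover the frame span (ends %.1f s)",
                     .tac_end(input_curve), fr_end)
  t0 <- min(frames$start[1], input_curve$start[1])
  g <- .fine_grid(t0, fr_end, frames, input_curve, dt)
  fw <- lapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    j <- which(g >= s - 1e-9 & g <= e + 1e-9)
    h <- diff(g[j])
    w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid node weights
    list(idx = j, w = w / (e - s))
  })
  list(g = g, ca = .input_at(input_curve, g), frames = frames, fw = fw)
}

.frame_average_pre <- function(pc, y) {
  vapply(pc$fw, function(f) sum(f$w * y[f$idx]), numeric(1))
}

.onetc_eval <- function(pc, k1, k2, vb = 0) {
  ct <- (k1 / 60) * .expconv_plin(pc$g, pc$ca, k2 / 60)
  if (vb != 0) ct <- ct + vb * pc$ca
  .frame_average_pre(pc, ct)
}

#' One-tissue compartment forward model
#'
#' Computes the frame-averaged tissue curve of the one-tissue compartment
#' model
#' \deqn{C_T(t) = K_1 \, (C_a \ast e^{-k_2 t})(t) + v_b\, C_a(t),}
#' with the arterial input \eqn{C_a} taken as piecewise linear between the
#' midpoints of its frames (constant beyond the first/last midpoint).  The
#' exponential convolution is evaluated analytically per fine-grid interval.
#'
#' @param k1 influx rate constant, mL min^-1 (mL tissue)^-1 (`>= 0`).
#' @param k2 efflux rate constant, min^-1 (`>= 0`).
#' @param input an [input_function] (or bare [tac]) covering the frame span.
#' @param frames a [tac] or data frame with `start`/`duration` columns (s)
#'   defining the output frames.
#' @param vb blood volume fraction in `[0, 1)`; default 0.
#' @param dt fine-grid step for the convolution (s).
#' @return A [tac] of frame-averaged model values.
#' @seealso [onetc_fit()]
#' @export
#' @examples
#' frm <- data.frame(start = seq(0, 115, 5), duration = 5)
#' aif <- sim_input_function(frm)
#' onetc_forward(k1 = 0.36, k2 = 0.9, input = aif, frames = frm)
onetc_forward <- function(k1, k2, input, frames, vb = 0, dt = 0.1) {
  cv <- if (inherits(input, "input_function")) input$curve else input
  stopifnot(inherits(cv, "tac"))
  if (!is.finite(k1) || !is.finite(k2) || k1 < 0 || k2 < 0 || vb < 0 || vb >= 1)
    .stop_validation("onetc_forward: need k1 >= 0, k2 >= 0, 0 <= vb < 1")
  frames <- as.data.frame(frames)[c("start", "duration")]
  pc <- .onetc_precompute(cv, frames, dt)
  tac(frames$start, frames$duration, .onetc_eval(pc, k1, k2, vb))
}

#' Fit the one-tissue compartment model to a tissue curve
#'
#' Weighted least-squares fit of \eqn{K_1, k_2} (and optionally the blood
#' volume fraction \eqn{v_b}) to a frame-averaged tissue time-activity curve
#' given an arterial input function.  The objective is minimised by bounded
#' local optimisation (`L-BFGS-B`) restarted from a deterministic 3x3 grid of
#' starting values with \eqn{K_1 \in [0, 3]}, \eqn{k_2 \in [0, 5]} min^-1;
#' the best converged run is kept.
#'
#' @param tissue a [tac] of tissue activity (>= 4 frames).
#' @param input an [input_function] covering the tissue frame span.
#' @param weights `"uniform"` (default) or `"duration"`
#'   (frame-duration-proportional), or a numeric vector of per-frame weights.
#' @param fit_vb also estimate the blood volume fraction (default `FALSE`).
#' @param dt fine-grid step for the model evaluation (s).
#' @return An object of class `"onetc_fit"` with components `coefficients`
#'   (`k1`, `k2`, `vb`), `wrss` (achieved weighted residual sum of squares),
#'   `converged`, `fitted.values`, `residuals`, `tissue`, `input`.
#'   Supports `coef()`, `print()`, `summary()`, `predict()`, `fitted()`,
#'   `residuals()` and `plot()`.
#' @export
#' @examples
#' frm <- data.frame(start = seq(0, 115, 5), duration = 5)
#' aif <- sim_input_function(frm)
#' ct <- onetc_forward(0.36, 0.9, aif, frm)
#' coef(onetc_fit(ct, aif))
onetc_fit <- function(tissue, input, weights = c("uniform", "duration"),
                      fit_vb = FALSE, dt = 0.1) {
  stopifnot(inherits(tissue, "tac"), inherits(input, "input_function"))
  if (nrow(tissue) < 4L) .stop_validation("onetc_fit: need at least 4 frames")
  if (any(!is.finite(tissue$value)) || any(!is.finite(input$curve$value)))
    .stop_validation("onetc_fit: non-finite curve values")
  if (max(abs(input$curve$value)) <= 0)
    .stop_compute("onetc_fit: all-zero input function")
  w <- if (is.numeric(weights)) {
    rep_len(weights, nrow(tissue))
  } else {
    switch(match.arg(weights), uniform = rep(1, nrow(tissue)),
           duration = tissue$duration)
  }
  cl <- match.call()
  frames <- as.data.frame(tissue)[c("start", "duration")]
  pc <- .onetc_precompute(input$curve, frames, dt)

  model_fun <- function(p) .onetc_eval(pc, p[1], p[2], if (fit_vb) p[3] else 0)

  if (max(abs(tissue$value)) == 0) {
    # a flat-zero curve is fit exactly by K1 = 0
    fit <- list(par = c(0, 0, 0), value = 0, convergence = 0L)
  } else {
    obj <- function(p) sum(w * (tissue$value - model_fun(p))^2)
    starts <- expand.grid(k1 = c(0.1, 0.5, 2), k2 = c(0.2, 1, 3))
    lower <- c(0, 0); upper <- c(3, 5)
    if (fit_vb) { lower <- c(lower, 0); upper <- c(upper, 0.95) }
    runs <- lapply(seq_len(nrow(starts)), function(i) {
      p0 <- c(starts$k1[i], starts$k2[i], if (fit_vb) 0.05)
      tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 500, factr = 1e4)),
               error = function(e) NULL)
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs)) .stop_compute("onetc_fit: all optimizer starts failed")
    fit <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    if (length(fit$par) == 2L) fit$par <- c(fit$par, 0)
  }

  fitted <- model_fun(fit$par)
  structure(list(coefficients = c(k1 = fit$par[1], k2 = fit$par[2], vb = fit$par[3]),
                 wrss = fit$value, converged = fit$convergence == 0L,
                 fitted.values = fitted, residuals = tissue$value - fitted,
                 weights = w, tissue = tissue, input = input,
                 fit_vb = fit_vb, dt = dt, call = cl),
            class = "onetc_fit")
}

#' @export
print.onetc_fit <- function(x, digits = 4, ...) {
  cat("One-tissue compartment fit\n")
  cat(sprintf("  K1 = %.*g mL/min/mL, k2 = %.*g /min", digits,
              x$coefficients["k1"], digits, x$coefficients["k2"]))
  if (x$fit_vb) cat(sprintf(", vb = %.*g", digits, x$coefficients["vb"]))
  cat(sprintf("\n  WRSS = %.*g, converged: %s\n", digits, x$wrss, x$converged))
  invisible(x)
}

#' @export
coef.onetc_fit <- function(object, ...) object$coefficients

#' @export
fitted.onetc_fit <- function(object, ...) object$fitted.values

#' @export
residuals.onetc_fit <- function(object, ...) object$residuals

#' @export
summary.onetc_fit <- function(object, ...) {
  n <- nrow(object$tissue)
  p <- if (object$fit_vb) 3L else 2L
  out <- list(coefficients = object$coefficients, wrss = object$wrss,
              converged = object$converged, n_frames = n, df = n - p,
              rmse = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.onetc_fit"
  out
}

#' @export
print.summary.onetc_fit <- function(x, ...) {
  cat("One-tissue compartment fit\n")
  print(round(x$coefficients, 5))
  cat(sprintf("frames: %d, WRSS: %.5g, RMSE: %.5g, converged: %s\n",
              x$n_frames, x$wrss, x$rmse, x$converged))
  invisible(x)
}

#' @param object,newframes a fitted `"onetc_fit"` and optional new output
#'   frames (`start`/`duration` data frame); defaults to the fitted frames.
#' @rdname onetc_fit
#' @export
predict.onetc_fit <- function(object, newframes = NULL, ...) {
  frames <- if (is.null(newframes)) object$tissue else newframes
  onetc_forward(object$coefficients["k1"], object$coefficients["k2"],
                object$input, frames, vb = object$coefficients["vb"],
                dt = object$dt)
}

#' @export
plot.onetc_fit <- function(x, ...) {
  t_mid <- .tac_mid(x$tissue)
  graphics::plot(t_mid, x$tissue$value, xlab = "time (s)",
                 ylab = "activity concentration", pch = 16, ...)
  graphics::lines(t_mid, x$fitted.values, col = 2)
  graphics::legend("topright", c("measured", "1TC fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Extract an image-derived input function by cluster analysis
#'
#' Voxel time-activity curves inside the body mask are partitioned with
#' k-means; the blood-pool cluster is taken as the cluster whose mean curve
#' peaks earliest (ties broken towards the higher peak), reflecting that the
#' arterial bolus arrives before any tissue uptake.  The returned input
#' function is the mean curve of that cluster with zero delay and dispersion.
#'
#' @param dynamic a 4-D array (x, y, z, frame) of activity concentrations.
#' @param frames frame definition (`start`/`duration` data frame, s).
#' @param mask logical 3-D body mask; default all voxels.
#' @param n_clusters number of k-means clusters (`>= 2`; default 3).
#' @param seed RNG seed for the k-means initialisation (clustering is
#'   reproducible for a fixed seed).
#' @return An [input_function] with `delay = 0`, `dispersion_tau = 0`.
#' @export
extract_idif <- function(dynamic, frames, mask = NULL, n_clusters = 3, seed = 1) {
  d <- dim(dynamic)
  stopifnot(length(d) == 4L)
  frames <- as.data.frame(frames)[c("start", "duration")]
  if (nrow(frames) != d[4])
    .stop_validation("extract_idif: %d frames but %d volumes", nrow(frames), d[4])
  if (n_clusters < 2) .stop_validation("extract_idif: need n_clusters >= 2")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!any(mask)) .stop_validation("extract_idif: empty body mask")
  m <- matrix(dynamic, ncol = d[4])[as.vector(mask), , drop = FALSE]
  if (nrow(unique(m)) < n_clusters)
    .stop_compute("extract_idif: fewer distinct voxel TAC profiles (%d) than clusters (%d)",
                  nrow(unique(m)), n_clusters)
  km <- .with_seed(seed,
                   stats::kmeans(m, centers = n_clusters, nstart = 5, iter.max = 100))
  centers <- km$centers
  peak_frame <- apply(centers, 1, which.max)
  peak_val <- apply(centers, 1, max)
  blood <- order(peak_frame, -peak_val)[1]
  input_function(tac(frames$start, frames$duration, centers[blood, ]),
                 delay = 0, dispersion_tau = 0)
}

# shift x (sampled on grid t, piecewise linear) later by delay, then convolve
# with the unit-area kernel (1/tau) exp(-t/tau); tau ~ 0 is the identity
.shift_disperse <- function(t, xfun, delay, tau) {
  xs <- xfun(t - delay)
  if (tau < 1e-8) return(xs)
  .expconv_plin(t, xs, 1 / tau) / tau
}

#' Delay- and dispersion-correct a remote input function
#'
#' Aligns a remote (e.g. cardiac) image-derived input function to a local
#' (e.g. pelvic) blood reference curve: the remote curve is shifted by a
#' delay \eqn{\Delta t} and convolved with a mono-exponential dispersion
#' kernel \eqn{(1/\tau) e^{-t/\tau}}, and \eqn{(\Delta t, \tau)} are chosen
#' to minimise the squared mismatch to the local reference over the fitting
#' window.  The mismatch is evaluated in frame space — the transformed remote
#' curve is frame-averaged onto the reference frames before comparison, since
#' the reference values are themselves frame averages.  The delay is searched
#' on a dense grid with \eqn{\tau} profiled by 1-D optimisation at each
#' delay, which is deterministic and robust for this two-parameter problem.
#'
#' @param remote an [input_function] (the curve to be corrected).
#' @param local_reference a [tac]: the blood curve at the site of interest.
#' @param delay_range search interval for the delay (s).
#' @param delay_step delay grid step (s).
#' @param tau_max upper bound of the dispersion time constant search (s).
#' @param window optional `c(t0, t1)` fitting window (s); default the full
#'   overlap of the two curves.
#' @param dt fine-grid step (s).
#' @return An [input_function]: the corrected remote curve frame-averaged
#'   onto the frames of `local_reference`, with `delay` and `dispersion_tau`
#'   set to the estimates.  Attribute `"boundary"` is `TRUE` (with a warning)
#'   when the optimum sits on the edge of the search ranges.
#' @export
delay_dispersion_correct <- function(remote, local_reference,
                                     delay_range = c(-10, 20), delay_step = 0.5,
                                     tau_max = 20, window = NULL, dt = 0.1) {
  stopifnot(inherits(remote, "input_function"), inherits(local_reference, "tac"))
  rc <- remote$curve
  t0 <- max(rc$start[1], local_reference$start[1])
  t1 <- min(.tac_end(rc), .tac_end(local_reference))
  if (t1 - t0 < 4 * dt)
    .stop_validation("delay_dispersion_correct: curves do not overlap")
  if (is.null(window)) window <- c(t0, t1)
  frames <- as.data.frame(local_reference)[c("start", "duration")]
  keep <- frames$start >= t0 - 1e-9 & frames$start + frames$duration <= t1 + 1e-9
  frames <- frames[keep, ]
  loc_val <- local_reference$value[keep]
  mid <- frames$start + frames$duration / 2
  in_win <- mid >= window[1] - 1e-9 & mid <= window[2] + 1e-9
  if (sum(in_win) < 4)
    .stop_validation("delay_dispersion_correct: fitting window too narrow")
  g <- .fine_grid(t0, t1, frames, rc, dt)
  fw <- lapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    j <- which(g >= s - 1e-9 & g <= e + 1e-9)
    h <- diff(g[j])
    list(idx = j, w = (c(h / 2, 0) + c(0, h / 2)) / (e - s))
  })
  rfun <- function(t) .input_at(rc, t)
  frame_model <- function(delay, tau) {
    y <- .shift_disperse(g, rfun, delay, tau)
    vapply(fw, function(f) sum(f$w * y[f$idx]), numeric(1))
  }

  delays <- seq(delay_range[1], delay_range[2], by = delay_step)
  sse_tau <- function(tau, delay)
    sum((frame_model(delay, tau)[in_win] - loc_val[in_win])^2)
  best <- list(sse = Inf)
  for (dl in delays) {
    o <- stats::optimize(sse_tau, c(0, tau_max), delay = dl, tol = 1e-3)
    cand <- if (o$objective < (s0 <- sse_tau(0, dl)))
      list(tau = o$minimum, sse = o$objective) else list(tau = 0, sse = s0)
    if (cand$sse < best$sse) best <- c(cand, delay = dl)
  }
  boundary <- best$delay <= delay_range[1] + 1e-9 ||
    best$delay >= delay_range[2] - 1e-9 || best$tau >= tau_max - 1e-3
  if (boundary)
    warning("delay/dispersion estimate at the edge of its search range",
            call. = FALSE)
  out <- input_function(tac(frames$start, frames$duration,
                            frame_model(best$delay, best$tau)),
                        delay = best$delay, dispersion_tau = best$tau)
  attr(out, "boundary") <- boundary
  out
}
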