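# Shared fixtures and independent oracles used across the test files.

# Table-1 K1 columns, hard-coded independently of the bundled CSV so the
# fixture file itself is under test
k1_test_col <- c(0.36, 0.27, 0.05, 0.12, 0.22, 0.23, 0.23, 0.08, 0.13, 0.05, 0.43)
k1_retest_col <- c(0.34, 0.25, 0.05, 0.10, 0.16, 0.29, 0.26, 0.09, 0.12, 0.05, 0.40)

# short dynamic schedule used by most kinetics tests
short_frames <- function() default_frame_schedule()

std_aif <- function(frames = short_frames()) sim_input_function(frames)

# independent one-way ANOVA ICC oracle via lm(), distinct from the
# closed-form implementation in the package
icc_anova_oracle <- function(test, retest) {
  v <- c(log(test), log(retest))
  g <- factor(rep(seq_along(test), 2))
  a <- anova(stats::lm(v ~ g))
  msb <- a[1, "Mean Sq"]
  msw <- a[2, "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# fine-grid numerical convolution oracle for the 1TC model: rectangle-rule
# convolution of the midpoint-interpolated input, deliberately independent
# of the package's analytic per-interval solution
onetc_quadrature_oracle <- function(k1, k2, input, frames, dt = 0.005) {
  cv <- input$curve
  tg <- seq(0, max(frames$start + frames$duration), by = dt)
  ca <- approx(cv$start + cv$duration / 2, cv$value, xout = tg, rule = 2)$y
  k1s <- k1 / 60; k2s <- k2 / 60
  conv <- numeric(length(tg))
  decay <- exp(-k2s * dt)
  acc <- 0
  for (i in seq_along(tg)[-1]) {
    acc <- acc * decay + ca[i] * dt
    conv[i] <- acc
  }
  ct <- k1s * conv
  vapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    mean(ct[tg >= s & tg <= e])
  }, numeric(1))
}

# construct a "local" reference curve from a remote input function by
# shifting and dispersing its continuous representation, then frame
# averaging -- the self-consistency construction for the delay/dispersion
# tests
make_dispersed_local <- function(remote, delay, tau, frames = short_frames(),
                                 noise_sd = 0, seed = NULL) {
  g <- sort(unique(c(seq(0, max(frames$start + frames$duration), by = 0.05),
                     frames$start, frames$start + frames$duration)))
  rfun <- function(t) approx(remote$curve$start + remote$curve$duration / 2,
                             remote$curve$value, xout = t - delay, rule = 2)$y
  y <- rfun(g)
  if (tau > 0) {
    # independent discrete convolution with the exponential kernel
    dt <- diff(g)
    out <- numeric(length(g))
    for (i in seq_along(g)[-1])
      out[i] <- out[i - 1] * exp(-dt[i - 1] / tau) +
        y[i] * (1 - exp(-dt[i - 1] / tau))
    y <- out
  }
  avg <- vapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    sel <- g >= s & g <= e
    mean(y[sel])
  }, numeric(1))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    avg <- avg * (1 + rnorm(length(avg), 0, noise_sd))
  }
  tac(frames$start, frames$duration, avg)
}

# a tiny valid paired table for error-path tests
tiny_table <- function(n = 3) sim_paired_table(n_lesions = n, seed = 99)
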