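test_that("forward model limiting cases have their closed forms", {
  frm <- short_frames()
  aif <- std_aif(frm)
  # K1 = 0 -> flat zero
  expect_true(all(onetc_forward(0, 0.5, aif, frm)$value == 0))
  # k2 = 0, constant input: C_T is K1 * t (t in minutes), so the frame
  # covering 55-60 s averages K1 * (57.5 / 60)
  const <- input_function(tac(seq(0, 55, 5), 5, rep(1, 12)))
  frm1 <- data.frame(start = seq(0, 55, 5), duration = 5)
  ct <- onetc_forward(0.3, 0, const, frm1)
  expect_equal(ct$value[12], 0.3 * 57.5 / 60, tolerance = 1e-10)
  # homogeneity: doubling K1 doubles the curve at vb = 0
  a <- onetc_forward(0.2, 0.9, aif, frm)$value
  b <- onetc_forward(0.4, 0.9, aif, frm)$value
  expect_equal(b, 2 * a, tolerance = 1e-12)
  # input shorter than the frames -> domain error
  short_in <- input_function(tac(seq(0, 55, 5), 5, rep(1, 12)))
  expect_error(onetc_forward(0.3, 0.5, short_in, frm), "cover")
})

test_that("forward model agrees with an independent fine-grid convolution oracle", {
  frm <- short_frames()
  aif <- std_aif(frm)
  model <- onetc_forward(0.36, 0.9, aif, frm)$value
  oracle <- onetc_quadrature_oracle(0.36, 0.9, aif, frm)
  expect_lt(max(abs(model - oracle)) / max(oracle), 0.005)
})

test_that("noiseless fits recover the generating parameters", {
  frm <- short_frames()
  aif <- std_aif(frm)
  for (k1 in c(0.05, 0.22, 0.43)) {
    fit <- onetc_fit(onetc_forward(k1, 0.9, aif, frm), aif)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)["k1"]), k1, tolerance = 1e-3 / k1)
    expect_equal(unname(coef(fit)["k2"]), 0.9, tolerance = 1e-2)
  }
  # flat-zero tissue curve fits K1 = 0 exactly
  zero <- tac(frm$start, frm$duration, rep(0, nrow(frm)))
  expect_equal(unname(coef(onetc_fit(zero, aif))["k1"]), 0)
  # all-zero input is rejected
  no_input <- input_function(tac(frm$start, frm$duration, rep(0, nrow(frm))))
  curve <- onetc_forward(0.2, 0.9, aif, frm)
  expect_error(onetc_fit(curve, no_input), "all-zero input")
  expect_error(onetc_fit(tac(0:3, 1, c(1, NA, 1, 1)), aif), "finite|non-finite")
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  frm <- short_frames()
  aif <- std_aif(frm)
  obs <- onetc_forward(0.25, 0.8, aif, frm)
  fit <- onetc_fit(obs, aif)
  expect_named(coef(fit), c("k1", "k2", "vb"))
  expect_equal(fitted(fit) + residuals(fit), obs$value)
  expect_equal(predict(fit)$value, fitted(fit), tolerance = 1e-12)
  late <- data.frame(start = c(0, 60), duration = c(60, 60))
  expect_equal(nrow(predict(fit, late)), 2L)
  s <- summary(fit)
  expect_equal(s$df, nrow(frm) - 2)
  expect_output(print(fit), "One-tissue compartment")
})

test_that("cluster IDIF extraction separates the blood pool", {
  # noiseless phantom: three identical-profile groups -> exact separation
  ph <- sim_phantom(noise_cov = 0, seed = 1)
  idif <- extract_idif(ph$volume, ph$frames, n_clusters = 3, seed = 2)
  expect_lt(max(abs(idif$curve$value - ph$input$curve$value)), 1e-6)
  expect_equal(idif$delay, 0)
  expect_equal(idif$dispersion_tau, 0)
  # selection rule: blood is chosen for its earlier peak even when a tissue
  # cluster has the higher amplitude
  frm <- data.frame(start = seq(0, 45, 5), duration = 5)
  early <- c(0, 5, 1, 0.5, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)      # early low peak
  late <- c(0, 0.5, 2, 5, 9, 10, 9.5, 9, 8.5, 8)              # late high peak
  vol <- array(0, c(4, 2, 1, 10))
  for (f in 1:10) { vol[1:2, , 1, f] <- early[f]; vol[3:4, , 1, f] <- late[f] }
  idif2 <- extract_idif(vol, frm, n_clusters = 2, seed = 1)
  expect_equal(idif2$curve$value, early)
  # degenerate clustering: fewer distinct profiles than clusters
  expect_error(extract_idif(vol, frm, n_clusters = 5, seed = 1),
               "distinct")
})

test_that("IDIF from a noisy phantom still supports accurate K1 fitting", {
  ph <- sim_phantom(noise_cov = 0.05, seed = 21)
  idif <- extract_idif(ph$volume, ph$frames, n_clusters = 3, seed = 2)
  truth_peak <- which.max(ph$input$curve$value)
  expect_lte(abs(which.max(idif$curve$value) - truth_peak), 1)
  nt <- nrow(ph$frames)
  tum_tac <- tac(ph$frames$start, ph$frames$duration,
                 colMeans(matrix(ph$volume, ncol = nt)[as.vector(ph$region_map == "tumor"), ]))
  fit <- onetc_fit(tum_tac, idif)
  expect_equal(unname(coef(fit)["k1"]), 0.36, tolerance = 0.10)
})

test_that("delay/dispersion correction recovers a constructed shift and smear", {
  frm <- short_frames()
  aif <- std_aif(frm)
  # identity: aligning a curve to itself
  self <- delay_dispersion_correct(aif, aif$curve)
  expect_lt(abs(self$delay), 0.5)
  expect_lt(self$dispersion_tau, 0.5)
  # noiseless construction with delay 4 s, tau 6 s
  loc <- make_dispersed_local(aif, delay = 4, tau = 6)
  corr <- delay_dispersion_correct(aif, loc)
  expect_lt(abs(corr$delay - 4), 0.5)
  expect_lt(abs(corr$dispersion_tau - 6), 0.5)
  # corrected curve sits on the local reference
  expect_lt(sqrt(mean((corr$curve$value - loc$value)^2)),
            0.02 * sqrt(mean(loc$value^2)))
  # non-overlapping curves -> domain error
  late <- tac(1000 + frm$start, frm$duration, seq_len(nrow(frm)))
  expect_error(delay_dispersion_correct(aif, late), "overlap")
})

test_that("delay/dispersion correction tolerates measurement noise", {
  frm <- short_frames()
  aif <- std_aif(frm)
  loc <- make_dispersed_local(aif, delay = 4, tau = 6, noise_sd = 0.05, seed = 31)
  clean <- make_dispersed_local(aif, delay = 4, tau = 6)
  corr <- delay_dispersion_correct(aif, loc)
  expect_lt(abs(corr$delay - 4), 1.5)
  expect_lt(abs(corr$dispersion_tau - 6), 1.5)
  rmse <- sqrt(mean((corr$curve$value - clean$value)^2))
  expect_lt(rmse, 0.10 * sqrt(mean(clean$value^2)))
})

test_that("the dispersion operator conserves area and reduces to identity", {
  frm <- short_frames()
  aif <- std_aif(frm)
  # padded curve: activity has returned near zero by the end of the window
  corr <- delay_dispersion_correct(aif, make_dispersed_local(aif, 0, 8))
  area <- function(cv) sum(cv$value * cv$duration)
  expect_equal(area(corr$curve), area(aif$curve), tolerance = 0.01)
  # tau -> 0, delay -> 0 leaves the curve unchanged
  g <- seq(0, 100, 0.1)
  rfun <- function(t) approx(seq(0, 100, 1), dgamma(seq(0, 100, 1) / 10, 3),
                             xout = t, rule = 2)$y
  y0 <- rbflow:::.shift_disperse(g, rfun, 0, 0)
  expect_equal(y0, rfun(g))
  y_small <- rbflow:::.shift_disperse(g, rfun, 0, 1e-4)
  expect_equal(y_small, rfun(g), tolerance = 1e-3)
})
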