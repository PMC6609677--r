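test_that("log differences and the within-subject SD follow their closed forms", {
  expect_equal(log_paired_diffs(cbind(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  expect_equal(log_paired_diffs(cbind(1, 2)), log(2))
  # first Table-1 K1 pair: ln(0.34/0.36)
  d <- log_paired_diffs(cbind(k1_test_col, k1_retest_col))
  expect_equal(d[1], -0.0571584138, tolerance = 1e-9)
  expect_error(log_paired_diffs(cbind(c(1, 0), c(1, 1))), "> 0")

  expect_equal(within_subject_sd(c(0, 0, 0)), 0)
  expect_equal(within_subject_sd(c(log(2), -log(2))), log(2) / sqrt(2))
  # hand-summation oracle on the Table-1 K1 differences
  expect_equal(within_subject_sd(d), 0.1040361147, tolerance = 1e-9)
  expect_error(within_subject_sd(0.1), "n >= 2")
})

test_that("the repeatability coefficient back-transforms the within-subject SD", {
  expect_equal(repeatability_percent(0), 0)
  expect_equal(repeatability_percent(0.1), 100 * (exp(1.96 * sqrt(2) * 0.1) - 1))
  expect_equal(repeatability_percent(0.1), 31.94, tolerance = 1e-3)
  # monotone in sigma
  s <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(repeatability_percent(s)) > 0))
})

test_that("one-way ICC matches a brute-force ANOVA oracle", {
  # identical replicates across varying lesions -> 1
  x <- c(0.2, 0.5, 1.1, 2.4)
  expect_equal(icc_oneway(cbind(x, x)), 1)
  # constant table -> undefined
  expect_error(icc_oneway(cbind(rep(2, 4), rep(2, 4))), "undefined")
  # random small tables against the independent lm() decomposition
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    te <- exp(rnorm(n, 0, 0.8) + rnorm(n, 0, 0.2))
    re <- te * exp(rnorm(n, 0, 0.2))
    expect_equal(icc_oneway(cbind(te, re)), icc_anova_oracle(te, re),
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman ratio limits bracket the mean ratio and cover ~95%", {
  ident <- bland_altman(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$mean_ratio, 1)
  expect_equal(ident$loa_ratio_low, 1)
  expect_equal(ident$loa_ratio_high, 1)
  # Table-1 K1: mean ratio from the hand-summation oracle
  ba <- bland_altman(cbind(k1_test_col, k1_retest_col))
  expect_equal(ba$mean_ratio, 0.9717634863, tolerance = 1e-9)
  expect_true(ba$loa_ratio_low <= ba$mean_ratio &&
                ba$mean_ratio <= ba$loa_ratio_high)
  # Monte-Carlo coverage of the limits on a large log-normal sample
  set.seed(77)
  n <- 2000
  lvl <- rnorm(n, 0, 0.5)
  te <- exp(lvl + rnorm(n, 0, 0.15))
  re <- exp(lvl + rnorm(n, 0, 0.15))
  cov <- bland_altman(cbind(te, re))
  ratio <- re / te
  inside <- mean(ratio >= cov$loa_ratio_low & ratio <= cov$loa_ratio_high)
  expect_equal(inside, 0.95, tolerance = 0.015 / 0.95)
})

test_that("Q-Q coordinates use (i - 0.5)/n plotting positions", {
  q3 <- qq_normal_coords(c(1, -1, 0))
  expect_equal(q3$observed, c(-1, 0, 1))
  expect_equal(q3$theoretical[2], 0)
  q4 <- qq_normal_coords(rnorm(4))
  expect_equal(q4$theoretical, qnorm(c(0.125, 0.375, 0.625, 0.875)))
  expect_error(qq_normal_coords(c(1, 2)), "n >= 3")
  # slope of the Q-Q line estimates the sample SD
  set.seed(5)
  d <- rnorm(4000, 0, 0.3)
  co <- qq_normal_coords(d)
  slope <- coef(lm(observed ~ theoretical, data = co))[2]
  expect_equal(unname(slope), sd(d), tolerance = 0.05)
})

test_that("the repeatability report runs the full chain per measure", {
  rep_tab <- repeatability(table1_fixture())
  expect_equal(nrow(rep_tab), 4)
  expect_true(all(rep_tab$n_lesions == 11))
  expect_true(all(rep_tab$loa_ratio_low <= rep_tab$mean_ratio &
                    rep_tab$mean_ratio <= rep_tab$loa_ratio_high))
  expect_true(all(rep_tab$sigma_w_log >= 0 & rep_tab$repeatability_percent >= 0))
  # a zero-within-noise table has RC = 0 and ICC = 1 for every measure
  perfect <- sim_paired_table(8, sigma_within = 0, seed = 6)
  rp <- repeatability(perfect)
  expect_equal(rp$repeatability_percent, rep(0, 4))
  expect_equal(rp$icc, rep(1, 4))
  expect_output(print(rep_tab), "repeatability")
})

test_that("agreement statistics are scale invariant and symmetric under label swap", {
  tab <- table1_fixture()
  for (m in c("k1", "suv_peak")) {
    pr <- extract_pairs(tab, m)
    base_res <- c(within_subject_sd(log_paired_diffs(pr)),
                  icc_oneway(pr),
                  unlist(bland_altman(pr)))
    # multiplying every measurement by a positive constant changes nothing
    scaled <- cbind(17.3 * pr$test, 17.3 * pr$retest)
    scaled_res <- c(within_subject_sd(log_paired_diffs(scaled)),
                    icc_oneway(scaled),
                    unlist(bland_altman(scaled)))
    expect_equal(scaled_res, base_res, tolerance = 1e-12)
    # swapping test/retest labels negates the mean log difference, inverts
    # and swaps the LoA, and leaves sigma_w and the ICC unchanged
    sw <- cbind(pr$retest, pr$test)
    expect_equal(within_subject_sd(log_paired_diffs(sw)),
                 within_subject_sd(log_paired_diffs(pr)), tolerance = 1e-12)
    expect_equal(icc_oneway(sw), icc_oneway(pr), tolerance = 1e-12)
    ba <- bland_altman(pr); bs <- bland_altman(sw)
    expect_equal(bs$mean_log_diff, -ba$mean_log_diff, tolerance = 1e-12)
    expect_equal(bs$loa_ratio_low, 1 / ba$loa_ratio_high, tolerance = 1e-12)
    expect_equal(bs$loa_ratio_high, 1 / ba$loa_ratio_low, tolerance = 1e-12)
  }
  # ICC is invariant to adding a constant on the log scale
  pr <- extract_pairs(tab, "k1")
  shifted <- exp(log(cbind(pr$test, pr$retest)) + 2.5)
  expect_equal(icc_oneway(shifted), icc_oneway(pr), tolerance = 1e-12)
})
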