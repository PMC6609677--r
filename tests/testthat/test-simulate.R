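test_that("paired-table generator honours the log-normal model", {
  # zero within-lesion SD: test equals retest
  t0 <- sim_paired_table(n_lesions = 5, sigma_within = 0, seed = 3)
  for (m in c("k1", "suv_max", "suv_mean", "suv_peak")) {
    pr <- extract_pairs(t0, m)
    expect_equal(pr$test, pr$retest)
  }
  expect_equal(nrow(sim_paired_table(n_lesions = 11, seed = 2)), 22)
  # bit-reproducible under a fixed seed
  expect_identical(sim_paired_table(7, seed = 11), sim_paired_table(7, seed = 11))
  expect_false(identical(sim_paired_table(7, seed = 11), sim_paired_table(7, seed = 12)))
})

test_that("the within-lesion log-SD is recovered from a large generated sample", {
  big <- sim_paired_table(n_lesions = 500, sigma_within = 0.10, seed = 42)
  d <- log_paired_diffs(extract_pairs(big, "k1"))
  expect_equal(within_subject_sd(d), 0.10, tolerance = 0.01 / 0.10)
})

test_that("scaling exp(mu) scales values but leaves log-scale spreads unchanged", {
  a <- sim_paired_table(20, mu_log = log(0.2), seed = 8)
  b <- sim_paired_table(20, mu_log = log(0.2) + log(7), seed = 8)
  pa <- extract_pairs(a, "k1"); pb <- extract_pairs(b, "k1")
  expect_equal(pb$test, 7 * pa$test, tolerance = 1e-12)
  expect_equal(within_subject_sd(log_paired_diffs(pb)),
               within_subject_sd(log_paired_diffs(pa)), tolerance = 1e-12)
})

test_that("the simulated input function has the required shape", {
  frm <- short_frames()
  z <- sim_input_function(frm, peak_amplitude = 0)
  expect_true(all(z$curve$value == 0))
  f30 <- sim_input_function(frm, peak_time = 30)
  pk <- which.max(f30$curve$value)
  expect_true(frm$start[pk] <= 30 && 30 <= frm$start[pk] + frm$duration[pk])
  expect_true(all(f30$curve$value >= 0))
  # single global maximum
  expect_equal(sum(f30$curve$value == max(f30$curve$value)), 1L)
  expect_error(sim_input_function(frm, peak_amplitude = -1), "amplitude")
  expect_error(sim_input_function(frm, peak_time = 1000), "peak time")
})

test_that("frame averaging matches a 100x finer quadrature of the same curve", {
  frm <- short_frames()
  coarse <- sim_input_function(frm, nsub = 40)$curve$value
  fine <- sim_input_function(frm, nsub = 4000)$curve$value
  expect_lt(max(abs(coarse - fine) / max(fine)), 0.01)
  keep <- fine > 1e-3 * max(fine)
  expect_lt(max(abs(coarse[keep] - fine[keep]) / fine[keep]), 0.01)
})

test_that("phantom voxels follow the forward model of their region", {
  ph <- sim_phantom(noise_cov = 0, seed = 1)
  frm <- ph$frames
  expect_identical(dim(ph$volume), c(12L, 12L, 6L, nrow(frm)))
  # zero noise: every tumor voxel TAC equals the 1TC forward curve exactly
  truth_curve <- onetc_forward(0.36, 0.9, ph$input, frm)$value
  tum <- which(ph$region_map == "tumor", arr.ind = TRUE)
  for (r in c(1, nrow(tum)))
    expect_equal(ph$volume[tum[r, 1], tum[r, 2], tum[r, 3], ], truth_curve)
  # blood voxels carry the input curve
  bl <- which(ph$region_map == "blood", arr.ind = TRUE)[1, ]
  expect_equal(ph$volume[bl[1], bl[2], bl[3], ], ph$input$curve$value)
  # regions with different kinetics give different TACs
  bg <- which(ph$region_map == "background", arr.ind = TRUE)[1, ]
  expect_false(isTRUE(all.equal(ph$volume[bg[1], bg[2], bg[3], ], truth_curve)))
  # unassigned region label -> spec error
  expect_error(sim_phantom(regions = list(blood = list(blood = TRUE)),
                           noise_cov = 0),
               "no kinetics")
})

test_that("phantom noise has the requested fractional SD and a fixed seed reproduces it", {
  ph <- sim_phantom(noise_cov = 0.05, seed = 7)
  ph2 <- sim_phantom(noise_cov = 0.05, seed = 7)
  expect_identical(ph$volume, ph2$volume)
  bg <- ph$region_map == "background"
  clean <- sim_phantom(noise_cov = 0, seed = 7)
  nt <- dim(ph$volume)[4]
  m <- matrix(ph$volume, ncol = nt)[as.vector(bg), ]
  m0 <- matrix(clean$volume, ncol = nt)[as.vector(bg), ]
  # use late frames where the background signal is well away from zero
  late <- (nt - 5):nt
  frac_sd <- apply(m[, late] / m0[, late], 2, sd)
  expect_true(all(abs(frac_sd - 0.05) < 0.01))
})

test_that("phantoms round-trip through NIfTI + JSON sidecars", {
  dir <- withr::local_tempdir()
  ph <- sim_phantom(noise_cov = 0.05, seed = 3)
  paths <- write_phantom(ph, file.path(dir, "ph"))
  expect_true(all(file.exists(paths)))
  back <- read_phantom(file.path(dir, "ph"))
  expect_equal(back$volume, unclass(ph$volume), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$region_map, ph$region_map)
  expect_equal(back$frames$start, ph$frames$start)
  expect_equal(back$input$curve$value, ph$input$curve$value, tolerance = 1e-9)
})

test_that("static volumes place spheres with analytic volumes, later spheres winning", {
  # no spheres -> constant
  flat <- sim_static_volume(c(8, 8, 8), background = 2)
  expect_true(all(flat == 2))
  # 10 mm sphere on 2 mm voxels: voxel count within 10% of (4/3) pi 5^3
  v <- sim_static_volume(c(16, 16, 16), vox_mm = c(2, 2, 2), background = 1,
                         spheres = list(list(center = c(16, 16, 16),
                                             radius = 10, level = 8)))
  n_in <- sum(v == 8)
  expect_equal(n_in, 4 / 3 * pi * 5^3, tolerance = 0.10)
  # nested spheres: the later (inner) level wins
  v2 <- sim_static_volume(c(16, 16, 16), vox_mm = c(2, 2, 2), background = 1,
                          spheres = list(list(center = c(16, 16, 16), radius = 10, level = 4),
                                         list(center = c(16, 16, 16), radius = 4, level = 9)))
  expect_equal(v2[8, 8, 8], 9)
  expect_true(any(v2 == 4))
  expect_error(sim_static_volume(c(8, 8, 8), spheres = list(
    list(center = c(2, 2, 2), radius = 50, level = 1))), "outside")
})
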