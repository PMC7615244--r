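test_that("sim1 returns the optimum together with its signal map", {
  out <- run_sim1(fix$subs$large_cylinders, scanner_constraints(600, 45),
                  b = 8, dirs = fix$dirs30, n_grid = 12, refine = FALSE)
  expect_s3_class(out$optimum, "tdr_optimisation")
  expect_true(all(c("delta", "Delta", "G", "signal") %in% names(out$signal_map)))
  expect_true(all(out$signal_map$G <= 600 + 1e-9))
  expect_true(all(out$signal_map$delta + out$signal_map$Delta <= 45 + 1e-9))
})

test_that("sim2 maps TDR over size grids, masking inadmissible gamma cells", {
  grid <- run_sim2(fix$w_s1, fix$w_s2o, "cylinder",
                   means = c(1, 2, 5.33, 16), sds = c(0.3, 3, 9),
                   dirs = fix$dirs30, n_bins = 30)
  expect_equal(nrow(grid), 12L)
  # heavy-tailed cells whose truncated mean shifts >10% are masked
  expect_true(any(!grid$admissible))
  expect_true(all(is.na(grid$tdr[!grid$admissible])))
  expect_true(all(!is.na(grid$tdr[grid$admissible])))
  # TDR grows with the distribution mean over the sensitive range
  t_small <- grid$tdr[grid$mean == 1 & grid$sd == 0.3]
  t_large <- grid$tdr[grid$mean == 5.33 & grid$sd == 3]
  expect_gt(t_large, 10 * max(t_small, 0.001))
  # narrow small-diameter cells sit below the resolution limit
  expect_lt(abs(t_small), 0.02)
  expect_lt(abs(grid$tdr[grid$mean == 2 & grid$sd == 0.3]), 0.02)
  # mismatched b-values are rejected
  expect_error(run_sim2(fix$w_s1, sde_waveform(14, 27.5, b = 20), "cylinder"),
               "same b-value")
})

test_that("sim3 produces accuracy/precision curves and a CoV minimum", {
  out <- run_sim3(fix$w_s1, fix$w_s2o, noise_spec(20, 300, seed = 77),
                  dirs = fix$dirs60)
  expect_setequal(unique(out$curves$config),
                  c("bundles1", "bundles2", "bundles3", "spheres"))
  sph <- out$curves[out$curves$config == "spheres", ]
  # spheres: flat in M both noise-free and noisy
  expect_lt(diff(range(sph$noise_free)), 1e-9)
  expect_lt(diff(range(sph$ensemble_mean)) / sph$noise_free[1], 0.12)
  one <- out$curves[out$curves$config == "bundles1", ]
  expect_lt(one$ensemble_mean[60], one$noise_free[60])
  expect_true(out$M_min >= 1 && out$M_min <= 60)
  expect_equal(nrow(out$cov), 60L)
})

test_that("the phantom pipeline reproduces direct TDR computation voxelwise", {
  labels <- matrix(c("large_cylinders", "small_cylinders",
                     "large_cylinders", NA), 2, 2)
  subs <- preset_substrates()
  ph <- generate_phantom(labels, subs, fix$w_s1, fix$w_s2o, fix$dirs30,
                         snr = Inf)
  m <- tdr_map(ph)
  direct_large <- tdr(substrate_shell(subs$large_cylinders, fix$w_s1, fix$dirs30),
                      substrate_shell(subs$large_cylinders, fix$w_s2o, fix$dirs30))
  expect_equal(m[1, 1], direct_large, tolerance = 1e-12)
  expect_equal(m[1, 1], m[1, 2], tolerance = 1e-12)
  expect_true(is.na(m[2, 2]))
  # noise-free map is identical for any M (noise-free TDR_M constant)
  expect_equal(tdr_map(ph, M = 6)[1, 1], m[1, 1], tolerance = 0.02)
  # under noise the large-cylinder ROI keeps higher contrast than the small
  ph20 <- generate_phantom(matrix(rep(c("large_cylinders", "small_cylinders"),
                                      each = 8), 4, 4),
                           subs, fix$w_s1, fix$w_s2o, fix$dirs30,
                           snr = 20, seed = 5)
  m12 <- tdr_map(ph20, M = 6)
  roi_large <- mean(m12[, 1:2])
  roi_small <- mean(m12[, 3:4])
  expect_gt(roi_large, roi_small)
  expect_identical(
    tdr_map(generate_phantom(labels, subs, fix$w_s1, fix$w_s2o, fix$dirs30,
                             snr = 20, seed = 9), M = 10),
    tdr_map(generate_phantom(labels, subs, fix$w_s1, fix$w_s2o, fix$dirs30,
                             snr = 20, seed = 9), M = 10))
  expect_error(generate_phantom(matrix("nope", 1, 1), subs, fix$w_s1,
                                fix$w_s2o, fix$dirs30),
               "undefined substrates")
})
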