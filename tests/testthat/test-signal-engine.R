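test_that("vanishing pores produce no dephasing", {
  w <- fix$w_s1
  expect_equal(cylinder_perp_attenuation(0.05, w), 1, tolerance = 1e-6)
  expect_equal(sphere_attenuation(0.05, w), 1, tolerance = 1e-6)
  expect_true(all(cylinder_perp_attenuation(c(1, 3, 8), w) > 0))
  expect_true(all(cylinder_perp_attenuation(c(1, 3, 8), w) <= 1))
})

test_that("perpendicular attenuation decreases monotonically with diameter", {
  # the illustration settings: Delta = 21 ms, delta = 9 ms, G = 276.8 mT/m
  w <- sde_waveform(9, 21, G = 276.8)
  expect_equal(w$b, 8, tolerance = 1e-3)
  d <- seq(1, 10, by = 0.5)
  s <- cylinder_perp_attenuation(d, w)
  expect_true(all(diff(s) < 0))
  # and the TDR against its long-Delta partner rises with pore size
  w2 <- sde_waveform(9, 55, G = 162.9)
  s2 <- cylinder_perp_attenuation(d, w2)
  expect_true(all(diff((s2 - s) / s2) > 0))
})

test_that("sphere attenuation is independent of gradient direction", {
  sub <- fix$subs$small_spheres
  sh <- substrate_shell(sub, fix$w_s2o, fix$dirs30)
  expect_equal(diff(range(sh$signals)), 0)
  expect_equal(sh$signals[1],
               sum(discretise(sub$distribution, "sphere")$weights *
                     sphere_attenuation(discretise(sub$distribution, "sphere")$diameters,
                                        fix$w_s2o)),
               tolerance = 1e-12)
})

test_that("cylinder signal composes free parallel and restricted transverse diffusion", {
  w <- fix$w_s1
  ax <- c(1, 0, 0)
  expect_equal(cylinder_signal(5, ax, ax, w), exp(-w$b * 2), tolerance = 1e-12)
  expect_equal(cylinder_signal(5, ax, c(0, 1, 0), w),
               cylinder_perp_attenuation(5, w), tolerance = 1e-12)
  s45 <- cylinder_signal(5, ax, c(1, 1, 0) / sqrt(2), w)
  expect_gt(s45, exp(-w$b * 2))
  expect_lt(s45, cylinder_perp_attenuation(5, w))
})

test_that("equal-b waveforms give identical signal for Gaussian (free) diffusion", {
  # parallel to the axis the signal is purely Gaussian: exp(-b D)
  w1 <- sde_waveform(6.9, 8.9, b = 8)
  w2 <- sde_waveform(14.1, 31, b = 8)
  ax <- c(0, 0, 1)
  s1 <- cylinder_signal(4, ax, ax, w1)
  s2 <- cylinder_signal(4, ax, ax, w2)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(tdr(s1, s2), 0, tolerance = 1e-12)
})

test_that("long-pulse limit scales as r^4 g^2 delta", {
  # small pores, delta = Delta (merged-pulse regime), D delta / R^2 >> 1
  G <- 400
  lnS <- function(d, delta, G)
    -log(cylinder_perp_attenuation(d, sde_waveform(delta, delta, G = G)))
  slope_r <- log(lnS(1.3, 20, G) / lnS(1, 20, G)) / log(1.3)
  expect_lt(abs(slope_r - 4) / 4, 0.05)
  slope_g <- log(lnS(1, 20, 500) / lnS(1, 20, 400)) / log(500 / 400)
  expect_lt(abs(slope_g - 2) / 2, 0.05)
  slope_delta <- log(lnS(1, 30, G) / lnS(1, 20, G)) / log(30 / 20)
  expect_lt(abs(slope_delta - 1), 0.05)
})

test_that("substrate shells mix bundles and collapse to parallel cylinders at high kappa", {
  dirs <- fix$dirs30
  sub_par <- fix$subs$large_cylinders
  sh_par <- substrate_shell(sub_par, fix$w_s1, dirs)
  # the dispersion-free limit: signals converge to the parallel bundle as
  # kappa grows (compared where the parallel signal is not noise-level;
  # at b = 8 even small tilts leak fast axial diffusion into near-axis
  # directions, so convergence is slow in kappa)
  rel_dev <- function(kappa) {
    sh <- substrate_shell(substrate("cylinder", sub_par$distribution,
                                    kappa = kappa),
                          fix$w_s1, dirs, n_watson = 600)
    keep <- sh_par$signals > 0.05
    max(abs(sh$signals[keep] - sh_par$signals[keep]) / sh_par$signals[keep])
  }
  d6 <- rel_dev(6); d100 <- rel_dev(100); d3000 <- rel_dev(3000)
  expect_lt(d3000, 0.01)
  expect_lt(d100, d6)
  expect_lt(d3000, d100)
  # two orthogonal bundles = average of the two single-bundle shells
  sub2 <- substrate("cylinder", sub_par$distribution,
                    bundle_axes = fibre_configuration(2))
  shx <- substrate_shell(substrate("cylinder", sub_par$distribution,
                                   bundle_axes = list(c(1, 0, 0))), fix$w_s1, dirs)
  shy <- substrate_shell(substrate("cylinder", sub_par$distribution,
                                   bundle_axes = list(c(0, 1, 0))), fix$w_s1, dirs)
  sh2 <- substrate_shell(sub2, fix$w_s1, dirs)
  expect_equal(sh2$signals, (shx$signals + shy$signals) / 2, tolerance = 1e-12)
  expect_true(all(sh2$signals > 0 & sh2$signals <= 1))
})

test_that("shell signals validate their direction sets", {
  w <- fix$w_s1
  expect_error(shell_signals(w, fix$dirs30, rep(0.5, 29)), "match")
  expect_error(shell_signals(w, fix$dirs30 * 2, rep(0.5, 30)), "unit")
})
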