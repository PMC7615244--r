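test_that("spherical mean and TDR basics", {
  expect_equal(spherical_mean(rep(0.7, 12)), 0.7)
  expect_equal(tdr(0.5, 0.5), 0)
  expect_equal(tdr(0.06, 0.14), (0.14 - 0.06) / 0.14)
  expect_lt(tdr(0.2, 0.1), 0)  # negative TDR is returned, not clipped
  expect_error(tdr(0.5, 0), "degenerate")
  expect_error(spherical_mean(numeric(0)), "empty")
  sh <- substrate_shell(fix$subs$large_cylinders, fix$w_s1, fix$dirs30)
  expect_equal(spherical_mean(sh), sum(sh$signals) / 30)
})

test_that("sorted-subset TDR matches hand evaluation and the full-set identity", {
  s1 <- c(0.6, 0.3, 0.1)
  s2 <- c(0.9, 0.5, 0.1)
  expect_equal(tdr_subset(s1, s2, 2), (1.4 - 0.9) / 1.4)
  expect_equal(tdr_subset(s1, s2, 3), tdr(mean(s1), mean(s2)))
  expect_error(tdr_subset(s1, s2, 4), "M must")
  expect_error(tdr_subset(s1, c(0.9, 0.5), 1), "share")
  curve <- tdr_subset_curve(s1, s2)
  expect_equal(curve[2], tdr_subset(s1, s2, 2))
  expect_length(curve, 3)
})

test_that("TDR is invariant to common rescaling and to permutation at M = N", {
  sh1 <- substrate_shell(fix$subs$large_cylinders, fix$w_s1, fix$dirs60)
  sh2 <- substrate_shell(fix$subs$large_cylinders, fix$w_s2o, fix$dirs60)
  t0 <- tdr(sh1, sh2)
  expect_equal(tdr(0.37 * sh1$signals, 0.37 * sh2$signals), t0, tolerance = 1e-12)
  p <- sample(60)
  expect_equal(tdr_subset(sh1$signals[p], sh2$signals[p], 60), t0,
               tolerance = 1e-12)
})

test_that("noise-free subset TDR is constant in M for any bundle configuration", {
  for (k in 1:3) {
    sub <- substrate("cylinder", fix$subs$large_cylinders$distribution,
                     bundle_axes = fibre_configuration(k))
    s1 <- substrate_shell(sub, fix$w_s1, fix$dirs60)
    s2 <- substrate_shell(sub, fix$w_s2o, fix$dirs60)
    curve <- tdr_subset_curve(s1, s2)
    expect_lt(diff(range(curve)), 0.02 * abs(curve[60]))
  }
})

test_that("Rician noise has the documented floor and respects snr = Inf", {
  s <- rep(0.4, 100)
  expect_identical(add_rician_noise(s, Inf), s)
  # zero signal rises to the Rician floor sigma * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 2e5), snr = 20, seed = 7)
  expect_equal(mean(z), (1 / 20) * sqrt(pi / 2), tolerance = 0.01)
  # reproducible given a seed, and applied to shell objects
  sh <- substrate_shell(fix$subs$large_cylinders, fix$w_s1, fix$dirs30)
  a <- add_rician_noise(sh, 20, seed = 3)
  b <- add_rician_noise(sh, 20, seed = 3)
  expect_equal(a$signals, b$signals)
  expect_s3_class(a, "shell_signals")
})

test_that("Rician ensembles are biased low at large M while Gaussian noise is unbiased", {
  sub <- fix$subs$large_cylinders
  s1 <- substrate_shell(sub, fix$w_s1, fix$dirs60)
  s2 <- substrate_shell(sub, fix$w_s2o, fix$dirs60)
  nf <- tdr(s1, s2)
  ric <- tdr_noise_ensemble(s1, s2, noise_spec(20, 2000, seed = 21))
  expect_lt(ric$ensemble_mean[60], nf)
  # accuracy degrades as more (low-signal) directions are included
  expect_lt(ric$ensemble_mean[60], ric$ensemble_mean[12])
  # precision improves with more measurements
  expect_lt(ric$ensemble_sd[60], ric$ensemble_sd[6])
  gau <- tdr_noise_ensemble(s1, s2, noise_spec(20, 4000, seed = 22),
                            noise = "gaussian")
  se60 <- gau$ensemble_sd[60] / sqrt(gau$n_instances)
  expect_lt(abs(gau$ensemble_mean[60] - nf), 4 * se60)
})

test_that("cross-configuration CoV is ~0 without noise and 0 for identical configs", {
  sub <- fix$subs$large_cylinders
  pair <- list(s1 = substrate_shell(sub, fix$w_s1, fix$dirs60),
               s2 = substrate_shell(sub, fix$w_s2o, fix$dirs60))
  ident <- cov_across_configs(list(pair, pair, pair),
                              noise_spec(Inf, 1, seed = 1), method = "means")
  expect_true(all(ident$curve$cov < 1e-12))
  # noise-free across 1/2/3 bundles: same size distribution, CoV ~ 0
  pairs <- lapply(1:3, function(k) {
    s <- substrate("cylinder", sub$distribution,
                   bundle_axes = fibre_configuration(k))
    list(s1 = substrate_shell(s, fix$w_s1, fix$dirs60),
         s2 = substrate_shell(s, fix$w_s2o, fix$dirs60))
  })
  nf <- cov_across_configs(pairs, noise_spec(Inf, 1, seed = 1), method = "means")
  expect_lt(max(nf$curve$cov), 0.01)
})
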