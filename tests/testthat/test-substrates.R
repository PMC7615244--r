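test_that("preset substrates carry the reference size distributions", {
  subs <- preset_substrates()
  expect_named(subs, c("small_cylinders", "large_cylinders",
                       "small_spheres", "large_spheres"))
  expect_equal(subs$large_cylinders$distribution$mean, 5.33)
  expect_equal(subs$large_cylinders$distribution$sd, 3.00)
  expect_equal(subs$small_cylinders$distribution$mean, 1.93)
  expect_equal(subs$small_spheres$distribution$mean, 7)
  expect_equal(subs$large_spheres$distribution$mean, 15)
  for (s in subs) expect_equal(s$diffusivity, 2)
})

test_that("gamma shape/scale are recovered exactly from mean and sd", {
  d <- diameter_distribution("gamma", 5.33, 3)
  gp <- tdrmri:::.gamma_pars(d)
  expect_equal(gp$shape * gp$scale, 5.33)
  expect_equal(sqrt(gp$shape) * gp$scale, 3)
})

test_that("discretisation produces normalised volume-weighted bins on the truncated support", {
  wd <- discretise(diameter_distribution("gamma", 5.33, 3), "cylinder")
  expect_equal(sum(wd$weights), 1, tolerance = 1e-12)
  expect_true(all(wd$diameters > 0 & wd$diameters <= 20))
  # volume weighting shifts mass to the tail relative to the number density
  expect_gt(sum(wd$diameters * wd$weights), 5.33)
  # point mass
  expect_equal(discretise(diameter_distribution("delta", 5), "cylinder"),
               list(diameters = 5, weights = 1))
  # sphere weighting is d^3: heavier tail than the cylinder weighting
  ws <- discretise(diameter_distribution("gamma", 5.33, 3), "sphere")
  expect_gt(sum(ws$diameters * ws$weights), sum(wd$diameters * wd$weights))
})

test_that("discretisation moments are stable when the bin count doubles", {
  for (geom in c("cylinder", "sphere")) {
    d <- diameter_distribution(if (geom == "cylinder") "gamma" else "normal",
                               5.33, 3)
    a <- discretise(d, geom, n_bins = 50)
    b <- discretise(d, geom, n_bins = 100)
    m_a <- sum(a$diameters * a$weights)
    m_b <- sum(b$diameters * b$weights)
    expect_lt(abs(m_a - m_b) / m_b, 0.005)
  }
})

test_that("truncation admissibility flags distributions whose mean shifts >10%", {
  expect_true(truncation_admissible(diameter_distribution("gamma", 5.33, 3)))
  expect_true(truncation_admissible(diameter_distribution("gamma", 1.93, 0.81)))
  # a huge-tailed distribution loses most of its mean to truncation
  expect_false(truncation_admissible(diameter_distribution("gamma", 18, 10)))
  expect_true(truncation_admissible(diameter_distribution("normal", 15, 0.5)))
})

test_that("fibre configurations are mutually orthogonal unit axes", {
  expect_equal(fibre_configuration(1), list(c(1, 0, 0)))
  ax3 <- fibre_configuration(3)
  for (i in 1:3) expect_equal(sum(ax3[[i]]^2), 1)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(sum(ax3[[i]] * ax3[[j]]), 0)
  expect_error(fibre_configuration(4), "unsupported")
})

test_that("Watson orientation weights concentrate and are antipodally symmetric", {
  wo <- watson_orientations(100, mean_axis = c(0, 0, 1), n_samples = 400)
  expect_equal(sum(wo$weights), 1, tolerance = 1e-12)
  ang <- acos(pmin(1, abs(wo$orientations[, 3]))) * 180 / pi
  expect_gt(sum(wo$weights[ang < 15]), 0.9)
  # density is even in (mu . u): flipping an orientation leaves its weight
  mu <- c(0, 0, 1)
  w_u <- exp(100 * ((wo$orientations %*% mu)^2 - 1))
  w_minus <- exp(100 * (((-wo$orientations) %*% mu)^2 - 1))
  expect_equal(w_u, w_minus)
  # low concentration spreads the weight out
  wo1 <- watson_orientations(1, n_samples = 400)
  ang1 <- acos(pmin(1, abs(wo1$orientations[, 3]))) * 180 / pi
  expect_lt(sum(wo1$weights[ang1 < 15]), 0.5)
  # sampling mode is reproducible given a seed
  a <- watson_orientations(6, n_samples = 50, method = "sample", seed = 9)
  b <- watson_orientations(6, n_samples = 50, method = "sample", seed = 9)
  expect_equal(a, b)
})
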