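test_that("bone phantom geometry follows the requested hole taper", {
  ph <- make_bone_phantom(c(64, 64, 64), 0.25, 2000, 1200, texture = 0, seed = 0)
  # 2000 um / 250 um = 8 voxels across the top hole, ~5 at the bottom
  top <- ph$mu[, , 64]; bot <- ph$mu[, , 1]
  hx <- round(ph$hole_center[1]); hy <- round(ph$hole_center[2])
  near_hole <- abs(seq_len(64) - hx) <= 6   # stay inside the bone
  expect_equal(sum(top[, hy] == 0 & near_hole), 8, tolerance = 1)
  width_bot <- sum(bot[, hy] == 0 & near_hole)
  expect_true(width_bot %in% 4:5)
  # hole voxels empty, shell at full attenuation
  expect_equal(top[hx, hy], 0)
  expect_equal(max(ph$mu), 0.1)
  # solid phantom when both diameters are zero
  ps <- make_bone_phantom(c(16, 16, 8), 0.5, 0, 0, texture = 0)
  interior <- ps$mu[8, 8, ]
  expect_true(all(interior > 0))
  # scatter mass decreases monotonically with hole size
  mass <- vapply(c(0, 1000, 2000, 3000), function(d) {
    p <- make_bone_phantom(c(32, 32, 16), 0.25, d, d, texture = 0)
    sum(p$rho_e) * 0.25^3
  }, numeric(1))
  expect_true(all(diff(mass) < 0))
  expect_error(make_bone_phantom(c(16, 16, 8), 0.25, 9000, 1200),
               class = "invalid_argument")
})

test_that("Compton shift follows lambda' = lambda + lambda_C (1 - cos theta)", {
  lc <- 2.42631023867
  expect_equal(compton_wavelength(20, 0), 20)
  expect_equal(compton_wavelength(20, 90), 20 + lc)
  expect_equal(compton_wavelength(20, 180), 20 + 2 * lc)
  expect_error(compton_wavelength(-1, 90), class = "invalid_argument")
})

test_that("Klein-Nishina limits and angle dependence hold", {
  r_e2 <- (2.8179403262e-15)^2
  # forward scattering: exactly r_e^2
  expect_equal(klein_nishina(20, 0), r_e2, tolerance = 1e-12)
  # long-wavelength (Thomson) limit: (r_e^2/2)(1 + cos^2 theta)
  for (th in c(0, 30, 90, 137)) {
    expect_equal(klein_nishina(1e9, th),
                 r_e2 / 2 * (1 + cos(th * pi / 180)^2), tolerance = 1e-6)
  }
  # 80 keV: 90 degrees scatters less than 30 degrees
  l80 <- energy_to_wavelength_pm(80)
  expect_lt(klein_nishina(l80, 90), klein_nishina(l80, 30))
  # maximal at theta = 0 and symmetric under theta -> -theta
  th <- seq(-180, 180, by = 15)
  kn <- klein_nishina(energy_to_wavelength_pm(60), th)
  expect_equal(which.max(kn), which(th == 0))
  expect_equal(kn, rev(kn))
})

test_that("scatter response reduces to hand integrals in simple media", {
  # no attenuation: uniform slab of unit scatter density, thickness t
  ph <- make_bone_phantom(c(8, 8, 4), 0.5, 0, 0, texture = 0)
  ph$mu[] <- 0; ph$rho_e[] <- 0
  ph$rho_e[, 3:6, ] <- 1   # slab of 4 voxels along the beam
  r <- scatter_response_map(ph, scatter_geometry(60, 90))
  kn <- klein_nishina(energy_to_wavelength_pm(60), 90) / (2.8179403262e-15)^2
  expect_equal(max(abs(r$values - 4 * 0.5 * kn)), 0, tolerance = 1e-12)
  # attenuating medium: single bright voxel, verified against a
  # brute-force ray marcher at 10x finer step
  ph2 <- make_bone_phantom(c(16, 16, 4), 0.5, 0, 0, texture = 0)
  ph2$mu[] <- 0.08; ph2$rho_e[] <- 0
  ph2$rho_e[9, 7, 2] <- 1
  r2 <- scatter_response_map(ph2, scatter_geometry(60, 90))
  fine <- scatter_response_map(ph2, scatter_geometry(60, 90),
                               exit_step_vox = 0.05)
  expect_equal(r2$values[9, 2], fine$values[9, 2], tolerance = 0.05)
  # analytic: T_in over 6 upstream voxels, T_out roughly 7.5 voxels to
  # the +x boundary
  t_in <- exp(-0.08 * 6 * 0.5)
  expect_equal(r2$values[9, 2] / (0.5 * kn * t_in * ph2$rho_e[9, 7, 2]),
               exp(-0.08 * 7.5 * 0.5), tolerance = 0.05)
})

test_that("self-attenuation is monotone and rotation wraps cleanly", {
  ph <- make_bone_phantom(c(16, 16, 8), 0.5, 1500, 1000, texture = 0)
  r1 <- scatter_response_map(ph, scatter_geometry())
  ph2 <- ph; ph2$mu <- 2 * ph$mu
  r2 <- scatter_response_map(ph2, scatter_geometry())
  expect_true(all(r2$values <= r1$values + 1e-12))
  ra <- scatter_response_map(ph, scatter_geometry(rotation_angle_deg = 0))
  rb <- scatter_response_map(ph, scatter_geometry(rotation_angle_deg = 360))
  expect_equal(ra$values, rb$values, tolerance = 1e-6)
})

test_that("transmission projection is Beer-Lambert", {
  ph <- make_bone_phantom(c(12, 12, 6), 0.5, 0, 0, texture = 0)
  ph$mu[] <- 0
  expect_true(all(transmission_projection(ph)$values == 1))
  ph$mu[] <- 0.07
  expect_equal(max(abs(transmission_projection(ph)$values -
                         exp(-0.07 * 12 * 0.5))), 0, tolerance = 1e-12)
  # the tapered hole transmits more than solid bone
  phh <- make_bone_phantom(c(32, 32, 16), 0.25, 2000, 2000, texture = 0)
  tp <- transmission_projection(phh)$values
  hx <- round(phh$hole_center[1])
  expect_gt(tp[hx, 8], tp[hx - 6, 8])
})

test_that("bucket signals are exact pattern-response inner products", {
  A <- toy_system(12, c(4, 4), seed = 2)
  x <- matrix(seq(0, 1, length.out = 16), 4, 4)
  S <- bucket_signals(A, x)
  # brute-force double loop oracle
  ref <- numeric(12)
  for (k in 1:12) for (i in 1:16) ref[k] <- ref[k] + A$values[k, i] * x[i]
  expect_equal(S$values, ref, tolerance = 1e-12)
  # identity measurement returns the flattened response
  Ai <- A; Ai$values <- diag(16); Ai$pattern_shape <- c(4, 4)
  expect_equal(bucket_signals(Ai, x)$values, as.numeric(x))
  # single all-ones row sums the response
  A1 <- A; A1$values <- matrix(1, 1, 16)
  expect_equal(bucket_signals(A1, x)$values, sum(x))
  # linearity in noiseless mode
  x2 <- matrix(runif(16), 4, 4)
  s12 <- bucket_signals(A, x + x2)$values
  expect_equal(s12, bucket_signals(A, x)$values + bucket_signals(A, x2)$values,
               tolerance = 1e-10 * max(abs(s12)))
  # Poisson draws: seeded, reproducible, non-negative
  sp1 <- bucket_signals(A, x, noise = "poisson", scale = 1e4, seed = 5)
  sp2 <- bucket_signals(A, x, noise = "poisson", scale = 1e4, seed = 5)
  expect_identical(sp1$values, sp2$values)
  expect_true(all(sp1$values >= 0))
  expect_error(bucket_signals(A, matrix(1, 3, 3)), class = "invalid_argument")
})

test_that("photon budget bookkeeping multiplies runs by primaries", {
  expect_identical(photon_budget(2000, 1e6), 2e9)
  expect_error(photon_budget(-1, 10), class = "invalid_argument")
})
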