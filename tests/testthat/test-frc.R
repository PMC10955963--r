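test_that("FRC of an image with itself is unity on every ring", {
  img <- with_seed_test(4, matrix(rnorm(48 * 48), 48, 48))
  fr <- frc_curve(img, img, pixel_um = 100)
  expect_true(all(abs(fr$frc - 1) < 1e-9))
  # invariant to positive rescaling of either input
  fr2 <- frc_curve(img * 13.7, img, pixel_um = 100)
  expect_equal(fr2$frc, fr$frc, tolerance = 1e-12)
  # frequency axis ends at Nyquist
  expect_equal(max(fr$freqs), 1 / (2 * 100))
  expect_true(all(diff(fr$freqs) > 0))
  expect_error(frc_curve(img, img[1:24, ], 100), class = "invalid_argument")
  expect_error(frc_curve(img[1:8, 1:8], img[1:8, 1:8], 100),
               class = "invalid_argument")
})

test_that("independent white noise decorrelates ring by ring", {
  n1 <- with_seed_test(7, matrix(rnorm(64 * 64), 64, 64))
  n2 <- with_seed_test(8, matrix(rnorm(64 * 64), 64, 64))
  fr <- frc_curve(n1, n2, pixel_um = 108)
  expect_lt(mean(abs(fr$frc[fr$n_per_ring >= 100])), 0.2)
  # noisy copies of one scene: high correlation at low frequency only
  base <- disk_scene(64, 64)
  a <- base + with_seed_test(9, matrix(rnorm(4096, sd = 0.1), 64, 64))
  b <- base + with_seed_test(10, matrix(rnorm(4096, sd = 0.1), 64, 64))
  fr2 <- frc_curve(a, b, pixel_um = 108)
  lo <- mean(fr2$frc[1:5]); hi <- mean(tail(fr2$frc, 5))
  expect_gt(lo, 0.9)
  expect_lt(hi, 0.5)
})

test_that("half-bit threshold decreases with ring occupancy and stays in
          (0, 1]", {
  hb <- halfbit_threshold(1:2000)
  expect_true(all(diff(hb) < 0))
  expect_true(all(hb > 0 & hb <= 1))
  expect_error(halfbit_threshold(0), class = "invalid_argument")
})

test_that("cutoff interpolation follows the first threshold crossing", {
  co <- cutoff_frequency(list(freqs = c(0.001, 0.002, 0.003),
                              frc = c(0.9, 0.8, 0.3),
                              halfbit = rep(0.5, 3)))
  expect_equal(co$frequency_per_um, 0.0026, tolerance = 1e-12)
  expect_false(co$no_crossing)
  # crossing exactly at a ring centre
  co2 <- cutoff_frequency(list(freqs = c(0.001, 0.002, 0.003),
                               frc = c(0.9, 0.5, 0.3),
                               halfbit = rep(0.5, 3)))
  expect_equal(co2$frequency_per_um, 0.002)
  # curve that never crosses reports Nyquist with the flag set
  co3 <- cutoff_frequency(list(freqs = c(0.001, 0.002, 0.003),
                               frc = rep(1, 3), halfbit = rep(0.9, 3)))
  expect_equal(co3$frequency_per_um, 0.003)
  expect_true(co3$no_crossing)
})

test_that("cutoff frequency converts to resolution as 1 / (2 f_c)", {
  expect_equal(resolution_from_cutoff(0.001), 500)
  expect_equal(resolution_from_cutoff(1 / (2 * 100)), 100)  # Nyquist of 100 um px
  expect_equal(resolution_from_cutoff(0.002), 250)
  expect_error(resolution_from_cutoff(0), class = "invalid_argument")
})

test_that("image metrics agree with independent formulas", {
  truth <- disk_scene(16, 16)
  m0 <- image_metrics(truth, truth)
  expect_equal(m0$pearson, 1)
  expect_equal(m0$rmse, 0)
  expect_equal(m0$psnr, 200)  # capped sentinel for a perfect match
  m1 <- image_metrics(truth + 0.7, truth)
  expect_equal(m1$pearson, 1)
  expect_equal(m1$rmse, 0.7, tolerance = 1e-12)
  noisy <- truth + with_seed_test(11, matrix(rnorm(256, sd = 0.2), 16, 16))
  m2 <- image_metrics(noisy, truth)
  expect_equal(m2$rmse, sqrt(mean((noisy - truth)^2)))
  expect_equal(m2$pearson,
               sum((noisy - mean(noisy)) * (truth - mean(truth))) /
                 sqrt(sum((noisy - mean(noisy))^2) * sum((truth - mean(truth))^2)))
  expect_equal(m2$psnr, 20 * log10(diff(range(truth)) / m2$rmse))
  expect_error(image_metrics(truth, matrix(1, 16, 16)),
               class = "degenerate_input")
})
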