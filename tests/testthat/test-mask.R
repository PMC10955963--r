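test_that("mask generation is Bernoulli, balanced and reproducible", {
  m1 <- generate_mask(128, 128, 108.1, seed = 42)
  m2 <- generate_mask(128, 128, 108.1, seed = 42)
  expect_identical(m1$grid, m2$grid)
  expect_true(all(m1$grid %in% c(0L, 1L)))
  # transmission-absorption ratio 1:1 within 2 points for >= 1e4 pixels
  expect_lt(abs(mean(m1$grid) - 0.5), 0.02)
  expect_false(identical(m1$grid, generate_mask(128, 128, 108.1, seed = 43)$grid))
  # duty = 1 forces every element on
  expect_true(all(generate_mask(4, 4, 100, duty = 1, seed = 0)$grid == 1))
  # direct count on a 64 x 64 instance
  m3 <- generate_mask(64, 64, 100, seed = 7)
  expect_gte(mean(m3$grid), 0.48)
  expect_lte(mean(m3$grid), 0.52)
  expect_error(generate_mask(0, 10, 100), class = "invalid_argument")
  expect_error(generate_mask(10, 10, -1), class = "invalid_argument")
  expect_error(generate_mask(10, 10, 100, duty = 0), class = "invalid_argument")
})

test_that("pattern extraction windows are faithful, unique and capacity-checked", {
  m <- generate_mask(64, 64, 100, seed = 3)
  A <- extract_patterns(m, 50, c(16, 16), seed = 9)
  expect_equal(dim(A$values), c(50, 256))
  expect_true(all(A$values %in% c(0, 1)))
  expect_equal(A$sampling_rate, 50 / 256)
  # offsets unique and every row re-readable from the mask
  expect_equal(nrow(unique(A$offsets)), 50)
  for (k in c(1, 17, 50)) {
    r <- A$offsets[k, 1]; c_ <- A$offsets[k, 2]
    expect_equal(A$values[k, ],
                 as.double(m$grid[r:(r + 15), c_:(c_ + 15)]))
  }
  # reproducibility
  expect_identical(A$values, extract_patterns(m, 50, c(16, 16), seed = 9)$values)
  # full-size window admits exactly one placement
  expect_error(extract_patterns(m, 2, c(64, 64)), class = "capacity")
  expect_error(extract_patterns(m, 1, c(65, 64)), class = "out_of_bounds")
  # explicit offsets: direct flattening of a 2x2 identity-like grid
  m2 <- m; m2$grid <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  A2 <- extract_patterns(m2, 1, c(2, 2), offsets = list(c(1, 1)))
  expect_equal(as.numeric(A2$values), c(1, 0, 0, 1))
})

test_that("mean transmission of duty-0.5 pattern rows stays near one half", {
  m <- generate_mask(256, 256, 100, seed = 12)
  A <- extract_patterns(m, 40, c(32, 32), seed = 13)  # 1024-px patterns
  expect_true(all(rowMeans(A$values) > 0.45 & rowMeans(A$values) < 0.55))
})

test_that("autocorrelation width matches analytic cases", {
  # solid square of side d: triangular autocorrelation, FWHM = d
  m <- generate_mask(128, 128, 10, seed = 0)
  g <- matrix(0L, 128, 128); g[33:64, 33:64] <- 1L
  m$grid <- g
  expect_equal(autocorrelation_width(m), 32 * 10, tolerance = 0.1)
  # i.i.d. Bernoulli(0.5): delta-like peak, FWHM within 1-2 px
  mw <- generate_mask(256, 256, 108, seed = 7)
  w <- autocorrelation_width(mw)
  expect_gte(w, 108); expect_lte(w, 216)
  # checkerboard: c(0)=1, c(1)=-1 after mean subtraction, so the
  # half-maximum crossing sits at lag 1/4 and the FWHM at half a pixel
  mc <- generate_mask(64, 64, 108, seed = 0)
  mc$grid <- outer(1:64, 1:64, function(i, j) (i + j) %% 2L)
  expect_equal(autocorrelation_width(mc), 0.5 * 108, tolerance = 0.02)
  # degenerate constant mask
  m0 <- generate_mask(16, 16, 100, duty = 1, seed = 0)
  expect_error(autocorrelation_width(m0), class = "degenerate_input")
})

test_that("direct and FFT autocorrelation estimators agree", {
  m <- generate_mask(96, 96, 50, seed = 21)
  g <- m$grid - mean(m$grid)
  d <- scatterct:::acorr_direct_h(g, 20)
  f <- scatterct:::acorr_fft_h(g, 20)
  expect_lt(max(abs(d - f) / d[1]), 1e-8)
})

test_that("autocorrelation width in um is stable under pixel upsampling", {
  m <- generate_mask(64, 64, 200, seed = 5)
  g <- matrix(0L, 64, 64); g[17:32, 17:32] <- 1L
  m$grid <- g
  w1 <- autocorrelation_width(m)
  up <- generate_mask(128, 128, 100, seed = 5)
  up$grid <- g[rep(1:64, each = 2), rep(1:64, each = 2)]
  w2 <- autocorrelation_width(up)
  expect_lt(abs(w1 - w2), 200)  # within one coarse pixel
})

test_that("sampling rate is the pattern-to-pixel ratio", {
  expect_equal(sampling_rate(3468, 16384), 3468 / 16384)
  # 3468/16384 = 0.21167..., printed as 0.211 (truncated) in the
  # reference acquisition profile
  expect_equal(trunc(sampling_rate(3468, 16384) * 1000) / 1000, 0.211)
  expect_equal(sampling_rate(16384, 16384), 1)
  expect_equal(sampling_rate(0, 100), 0)
  expect_error(sampling_rate(10, 0), class = "invalid_argument")
})
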