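test_that("linear solvers invert exact systems", {
  A <- toy_system(64, c(8, 8), seed = 1)
  x_true <- with_seed_test(11, matrix(runif(64), 8, 8))
  S <- bucket_signals(A, x_true)
  rel <- function(img) sqrt(sum((img - x_true)^2) / sum(x_true^2))
  expect_lt(rel(reconstruct_linear(A, S, "pinv")$image), 1e-8)
  expect_lt(rel(reconstruct_linear(A, S, "cgls", max_iter = 300)$image), 1e-8)
  # identity system reshapes S
  Ai <- A; Ai$values <- diag(64)
  expect_equal(reconstruct_linear(Ai, as.numeric(x_true), "pinv")$image, x_true,
               tolerance = 1e-10)
  # overdetermined 200 x 64: matches an independent normal-equations solve
  Ao <- toy_system(200, c(8, 8), seed = 4)
  So <- bucket_signals(Ao, x_true)
  xo <- reconstruct_linear(Ao, So, "cgls", max_iter = 300)$image
  expect_lt(sqrt(sum((xo - x_true)^2) / sum(x_true^2)), 1e-6)
  xn <- solve(crossprod(Ao$values), crossprod(Ao$values, So$values))
  expect_equal(as.numeric(xo), as.numeric(xn), tolerance = 1e-6)
  expect_error(reconstruct_linear(A, 1:10), class = "invalid_argument")
  Az <- A; Az$values[] <- 0
  expect_error(reconstruct_linear(Az, S), class = "degenerate_system")
})

test_that("anisotropic TV matches hand evaluation and is homogeneous", {
  expect_equal(tv_norm(matrix(5, 4, 4)), 0)
  # two vertical unit steps, no horizontal variation (columns 0,0 / 1,1)
  expect_equal(tv_norm(matrix(c(0, 1, 0, 1), 2, 2)), 2)
  img <- with_seed_test(3, matrix(rnorm(64), 8, 8))
  expect_equal(tv_norm(-2.5 * img), 2.5 * tv_norm(img))
  expect_error(tv_norm(matrix(1, 1, 5)), class = "invalid_argument")
})

test_that("TV least squares descends monotonically and matches the linear
          solution when unregularised", {
  A <- toy_system(64, c(8, 8), seed = 2)
  x_true <- disk_scene(8, 8)
  S <- bucket_signals(A, x_true)
  r0 <- reconstruct_tv_least_squares(A, S, tau = 0, n_steps = 60)
  rl <- reconstruct_linear(A, S, "cgls", max_iter = 300)
  expect_equal(as.numeric(r0$image), as.numeric(rl$image), tolerance = 1e-4)
  rt <- reconstruct_tv_least_squares(A, S, tau = 1e-3, n_steps = 80)
  expect_true(all(diff(rt$loss_history) <= 1e-10))
})

test_that("TV regularisation beats plain least squares on noisy undersampled
          data", {
  A <- toy_system(round(0.25 * 1024), c(32, 32), seed = 8, mask_px = 256)
  x_true <- disk_scene(32, 32)
  S <- bucket_signals(A, x_true, noise = "poisson", scale = 1e4, seed = 9)
  rl <- reconstruct_linear(A, S, "cgls")
  rt <- reconstruct_tv_least_squares(A, S, n_steps = 200)
  err <- function(img) {
    z <- function(v) (v - mean(v)) / sd(v)
    sqrt(mean((z(as.numeric(img)) - z(as.numeric(x_true)))^2))
  }
  expect_lt(err(rt$image), err(rl$image))
})

test_that("power-of-two resize preserves total intensity", {
  img <- with_seed_test(5, matrix(runif(184 * 163), 184, 163))
  out <- resize_to_pow2(img, c(128, 128))
  expect_equal(dim(out), c(128L, 128L))
  expect_equal(sum(out), sum(img), tolerance = 1e-10)
  expect_identical(resize_to_pow2(img[1:64, 1:64], c(64, 64)), img[1:64, 1:64])
  expect_error(resize_to_pow2(img, c(100, 128)), class = "invalid_argument")
})
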