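test_that("the 28-angle acquisition list is fixed, unique and ordered as
          acquired", {
  a <- paper_angle_list()
  expect_length(a, 28)
  expect_equal(a[1], 0)
  expect_equal(a[1:8], c(0, 180, 90, 270, 45, 225, 315, 135))
  expect_equal(anyDuplicated(a), 0)
  expect_true(all(a >= 0 & a < 360))
})

test_that("negative transmission inverts contrast and rejects flat images", {
  img <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(negative_transmission(img), 1 - img)
  expect_error(negative_transmission(matrix(1, 4, 4)),
               class = "degenerate_input")
  # involution up to affine rescale
  img2 <- with_seed_test(2, matrix(runif(64, 1, 5), 8, 8))
  twice <- negative_transmission(negative_transmission(img2))
  expect_equal(pearson(twice, img2), 1, tolerance = 1e-12)
})

test_that("modality combination is a convex blend of normalised stacks", {
  imgs <- with_seed_test(3, replicate(4, matrix(runif(256), 16, 16),
                                      simplify = FALSE))
  ang <- c(0, 45, 90, 135)
  s1 <- projection_stack(imgs, ang, "transmission-negative", 100)
  s2 <- projection_stack(lapply(imgs, function(i) i * 3 + 1), ang,
                         "scatter", 100)
  cb <- combine_modalities(s1, s2)
  # identical (up to affine) stacks blend to the normalised stack itself
  n1 <- scatterct:::robust_norm(imgs[[1]])
  expect_equal(cb$images[[1]], n1, tolerance = 1e-12)
  # weights (1, 0) return the first stack alone
  cb10 <- combine_modalities(s1, s2, weights = c(1, 0))
  expect_equal(cb10$images[[2]], scatterct:::robust_norm(imgs[[2]]))
  # convexity: output between the two normalised inputs pixelwise
  s3 <- projection_stack(with_seed_test(4, replicate(4,
          matrix(runif(256), 16, 16), simplify = FALSE)), ang, "scatter", 100)
  cb2 <- combine_modalities(s1, s3)
  for (k in 1:4) {
    a <- scatterct:::robust_norm(s1$images[[k]])
    b <- scatterct:::robust_norm(s3$images[[k]])
    expect_true(all(cb2$images[[k]] >= pmin(a, b) - 1e-12))
    expect_true(all(cb2$images[[k]] <= pmax(a, b) + 1e-12))
  }
  s_bad <- projection_stack(imgs, ang + 1, "scatter", 100)
  expect_error(combine_modalities(s1, s_bad), class = "invalid_argument")
})

test_that("the parallel projector matches a brute-force ray marcher", {
  v <- with_seed_test(5, array(runif(8 * 8 * 2), c(8, 8, 2)))
  vol <- volume(v, 1000)  # 1 mm voxels so integrals are in voxel units
  for (ang in c(0, 33.7, 120)) {
    ps <- forward_project(vol, ang)
    M_img <- ps$images[[1]]
    th <- (ang %% 360) * pi / 180
    eu <- c(cos(th), -sin(th)); ev <- c(sin(th), cos(th)); cc <- 4.5
    for (u_idx in c(2, 5, 7)) {
      u <- u_idx - cc
      ts <- seq(-12, 12, by = 5e-4)
      ref <- sum(vapply(ts, function(t) {
        bilinear_at(v[, , 1], u * eu[1] + t * ev[1] + cc,
                    u * eu[2] + t * ev[2] + cc)
      }, numeric(1))) * 5e-4
      expect_equal(M_img[u_idx, 1], ref, tolerance = 1e-5)
    }
  }
})

test_that("projector conserves mass and matches rotational symmetry", {
  v <- array(0, c(9, 9, 3)); v[5, 5, 2] <- 1
  ps <- forward_project(volume(v, 1000), c(0, 33.7, 260))
  for (im in ps$images) expect_equal(sum(im), 1, tolerance = 0.03)
  # uniform cylinder projects identically at 0 and 90 degrees
  ph <- make_bone_phantom(c(24, 24, 6), 0.5, 0, 0, texture = 0)
  pc <- forward_project(volume(ph$rho_e, 500), c(0, 90))
  expect_equal(pc$images[[1]], pc$images[[2]], tolerance = 1e-10)
  # adjoint identity <P v, s> = <v, P' s>
  M <- scatterct:::projection_matrix(12, 77.3)
  set.seed(6); vv <- rnorm(144); ss <- rnorm(12)
  expect_equal(sum((M %*% vv) * ss), sum(vv * as.numeric(Matrix::crossprod(M, ss))),
               tolerance = 1e-10)
})

test_that("projector angle convention matches the phantom rotation", {
  ph <- make_bone_phantom(c(32, 32, 8), 0.25, 2000, 1200, texture = 0, seed = 1)
  for (ang in c(30, 215)) {
    path_phys <- -log(transmission_projection(ph, ang)$values) # mu line integrals
    fp <- forward_project(volume(ph$mu, 250), ang)$images[[1]]
    expect_gt(cor(as.numeric(path_phys), as.numeric(fp)), 0.98)
  }
})

test_that("SART-TV reconstructs point and extended phantoms", {
  # zero data give a zero volume
  z <- projection_stack(list(matrix(0, 8, 4), matrix(0, 8, 4)), c(0, 90),
                        "transmission", 100)
  expect_true(all(sart_tv(z, sart_params(n_iterations = 3))$values == 0))
  # single voxel: argmax recovered over the 28-angle list
  v <- array(0, c(16, 16, 4)); v[6, 11, 2] <- 1
  ps <- forward_project(volume(v, 250), paper_angle_list())
  rec <- sart_tv(ps, sart_params(n_iterations = 30, tv_lambda = 0.1,
                                 tv_iter = 5))
  expect_equal(which.max(rec$values), which.max(v))
  expect_true(all(rec$values >= 0))
})

test_that("SART-TV residuals shrink and the round trip closes", {
  ph <- make_bone_phantom(c(32, 32, 32), 0.25, 2000, 1200, texture = 0, seed = 1)
  vt <- volume(ph$rho_e, 250)
  ps <- forward_project(vt, paper_angle_list())
  resid <- function(vol) {
    pr <- forward_project(vol, paper_angle_list())
    sqrt(sum((unlist(pr$images) - unlist(ps$images))^2) /
           sum(unlist(ps$images)^2))
  }
  sp <- sart_params(n_iterations = 1, tv_lambda = 0.05, tv_iter = 3)
  vol_k <- NULL
  res_hist <- numeric(10)
  vcur <- sart_tv(ps, sp)
  res_hist[1] <- resid(vcur)
  for (k in 2:10) {
    vcur <- sart_tv(ps, sart_params(n_iterations = k, tv_lambda = 0.05,
                                    tv_iter = 3))
    res_hist[k] <- resid(vcur)
  }
  expect_true(all(diff(res_hist) <= 1e-8))
  # 50 iterations: projections reproduced within 5 %
  rec <- sart_tv(ps, sart_params(n_iterations = 50, tv_lambda = 0.1,
                                 tv_iter = 5))
  expect_lt(resid(rec), 0.05)
  expect_gt(pearson(rec$values, ph$rho_e), 0.95)
  # tapered hole: top measured wider than bottom
  tw <- hole_taper_widths(rec, ph)
  expect_gt(tw$top_um, tw$bottom_um)
  # angle order invariance within 1 %
  perm <- c(3, 1, 7, 15, 2, 20, 28, 5, 11, 17, 25, 6, 14, 22, 4, 12, 18, 26,
            8, 16, 23, 9, 13, 24, 10, 19, 21, 27)
  ps_p <- projection_stack(ps$images[perm], ps$angles_deg[perm],
                           "transmission", 250)
  rec_p <- sart_tv(ps_p, sart_params(n_iterations = 50, tv_lambda = 0.1,
                                     tv_iter = 5))
  expect_lt(sqrt(sum((rec_p$values - rec$values)^2) / sum(rec$values^2)), 0.01)
})
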