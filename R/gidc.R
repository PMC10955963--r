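# Untrained-network (deep-image-prior) ghost-imaging reconstruction.
#
# The solver optimises the weights phi of a small randomly initialised
# convolutional network T_phi so that its output f = T_phi(x0)
# satisfies the measurement physics:
#   phi* = argmin_phi |A T_phi(x0) - S|^2 + tau * TV[T_phi(x0)]
# where x0 is the linear (CGLS) reconstruction fed as network input.
# No training data is involved; the network structure itself acts as
# the image prior, and the TV term enforces piecewise smoothness.
#
# Architecture (a design choice of this package): a three-scale
# encoder-decoder (full, 1/2 and 1/4 resolution) with a skip
# connection at the middle scale, 16 base channels, 3x3 convolutions,
# leaky-ReLU activations, mean-pool down / nearest-neighbour up, and a
# final 1x1 projection. The output is synthesised entirely by the
# decoder — there is no passthrough of the input image — so the
# network's spectral bias (low frequencies fit first) acts as the
# image prior that suppresses the noise the linear reconstruction
# carries. All convolutions are evaluated as im2col matrix products;
# gradients are computed analytically and weights updated with Adam
# under a short linear warm-up.

#' Parameters of the untrained-network solver
#'
#' Defaults mirror the reference acquisition profile: learning rate
#' 0.002, TV strength `10^-3.9`, 1501 optimisation steps, 128 x 128
#' image. A lighter profile (64 x 64 or 32 x 32, a few hundred steps)
#' is appropriate for tests and small simulations.
#'
#' @param learning_rate Adam step size (> 0).
#' @param tv_strength TV regularisation weight tau (>= 0).
#' @param n_steps optimisation step count (>= 1).
#' @param image_shape `(height, width)`; both must be powers of two —
#'   the solver only reconstructs power-of-two grids.
#' @param seed integer seed for the network weight initialisation.
#' @param n_channels base channel count of the network (default 16).
#' @return a `gidc_params` list.
#' @export
gidc_params <- function(learning_rate = 0.002, tv_strength = 10^-3.9,
                        n_steps = 1501L, image_shape = c(128L, 128L),
                        seed = 0L, n_channels = 16L) {
  assert_pos(learning_rate, "learning_rate")
  if (tv_strength < 0) sct_stop("invalid_argument", "tv_strength must be >= 0")
  if (n_steps < 1) sct_stop("invalid_argument", "n_steps must be >= 1")
  image_shape <- as.integer(image_shape)
  if (!is_pow2(image_shape[1]) || !is_pow2(image_shape[2])) {
    sct_stop("invalid_argument",
             "image_shape dimensions must be powers of two (got %d x %d)",
             image_shape[1], image_shape[2])
  }
  structure(
    list(learning_rate = learning_rate, tv_strength = tv_strength,
         n_steps = as.integer(n_steps), image_shape = image_shape,
         seed = as.integer(seed), n_channels = as.integer(n_channels)),
    class = "gidc_params"
  )
}

# ---- conv-net plumbing -----------------------------------------------------

# index tables for 'same' 3x3 convolution on an H x W grid
#' @noRd
conv_indices <- function(H, W) {
  Hp <- H + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    idx[, k] <- (i + di + 1L) + (j + dj) * Hp
  }
  interior <- (i + 1L) + j * Hp
  list(idx = idx, interior = interior, npad = Hp * (W + 2L))
}

#' @noRd
im2col <- function(F, ci) {
  HW <- nrow(F); C <- ncol(F)
  out <- matrix(0, HW, 9L * C)
  Fp <- numeric(ci$npad)
  for (c in seq_len(C)) {
    Fp[] <- 0
    Fp[ci$interior] <- F[, c]
    out[, (c - 1L) * 9L + 1:9] <- matrix(Fp[ci$idx], HW, 9L)
  }
  out
}

#' @noRd
col2im_grad <- function(dXcol, ci, C) {
  HW <- nrow(dXcol)
  dF <- matrix(0, HW, C)
  dFp <- numeric(ci$npad)
  for (c in seq_len(C)) {
    dFp[] <- 0
    for (k in 1:9) {
      tgt <- ci$idx[, k]
      dFp[tgt] <- dFp[tgt] + dXcol[, (c - 1L) * 9L + k]
    }
    dF[, c] <- dFp[ci$interior]
  }
  dF
}

#' @noRd
lrelu <- function(x, a = 0.1) ifelse(x > 0, x, a * x)
#' @noRd
lrelu_grad <- function(x, a = 0.1) ifelse(x > 0, 1, a)

# 2x2 mean-pool index table: rows = coarse pixels, 4 fine children
#' @noRd
pool_indices <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  ii <- 2L * i2 - 1L; jj <- 2L * j2 - 1L
  cbind((ii) + (jj - 1L) * H,
        (ii + 1L) + (jj - 1L) * H,
        (ii) + (jj) * H,
        (ii + 1L) + (jj) * H)
}

# sparse 2x bilinear upsampling operator (fine HW x coarse H2W2);
# bilinear interpolation biases the decoder toward smooth outputs,
# which is the working part of the untrained-network prior
#' @noRd
upsample_matrix <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  up1d <- function(n_f, n_c) {
    cc <- (seq_len(n_f) + 0.5) / 2   # coarse coordinate of fine centres
    lo <- pmin(pmax(floor(cc), 1L), n_c)
    hi <- pmin(lo + 1L, n_c)
    whi <- pmin(pmax(cc - lo, 0), 1)
    Matrix::sparseMatrix(i = c(seq_len(n_f), seq_len(n_f)),
                         j = c(lo, hi), x = c(1 - whi, whi),
                         dims = c(n_f, n_c))
  }
  Matrix::kronecker(up1d(W, W2), up1d(H, H2))
}

#' @noRd
gidc_geometry <- function(h, w) {
  list(s1 = conv_indices(h, w),
       s2 = conv_indices(h %/% 2L, w %/% 2L),
       s4 = conv_indices(h %/% 4L, w %/% 4L),
       pool1 = pool_indices(h, w),
       pool2 = pool_indices(h %/% 2L, w %/% 2L),
       up2 = upsample_matrix(h %/% 2L, w %/% 2L),   # 1/4 -> 1/2
       up1 = upsample_matrix(h, w))                 # 1/2 -> full
}

#' @noRd
gidc_init_weights <- function(C, seed) {
  he <- function(fan_in, n_out) {
    matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
  }
  with_seed(seed, list(
    W1 = he(9 * 1, C), b1 = numeric(C),      # full res, encoder
    W2 = he(9 * C, C), b2 = numeric(C),      # 1/2 res, encoder
    W3 = he(9 * C, C), b3 = numeric(C),      # 1/4 res, bottleneck
    W4 = he(9 * 2 * C, C), b4 = numeric(C),  # 1/2 res, decoder + skip
    W5 = he(9 * C, C), b5 = numeric(C),      # full res, decoder
    W6 = matrix(0, C, 1), b6 = numeric(1)    # 1x1 projection, zero init
  ))
}

# forward pass; returns output vector and caches for backprop
#' @noRd
gidc_forward <- function(par, x0, geomc) {
  ca <- list()
  F0 <- matrix(x0, ncol = 1)
  ca$X1 <- im2col(F0, geomc$s1)
  ca$Z1 <- sweep(ca$X1 %*% par$W1, 2, par$b1, `+`)
  A1 <- lrelu(ca$Z1)
  P1 <- (A1[geomc$pool1[, 1], ] + A1[geomc$pool1[, 2], ] +
         A1[geomc$pool1[, 3], ] + A1[geomc$pool1[, 4], ]) / 4
  ca$X2 <- im2col(P1, geomc$s2)
  ca$Z2 <- sweep(ca$X2 %*% par$W2, 2, par$b2, `+`)
  A2 <- lrelu(ca$Z2)                                   # skip source, 1/2 res
  P2 <- (A2[geomc$pool2[, 1], ] + A2[geomc$pool2[, 2], ] +
         A2[geomc$pool2[, 3], ] + A2[geomc$pool2[, 4], ]) / 4
  ca$X3 <- im2col(P2, geomc$s4)
  ca$Z3 <- sweep(ca$X3 %*% par$W3, 2, par$b3, `+`)
  A3 <- lrelu(ca$Z3)
  U2 <- as.matrix(geomc$up2 %*% A3)                    # to 1/2 res
  ca$X4 <- im2col(cbind(U2, A2), geomc$s2)
  ca$Z4 <- sweep(ca$X4 %*% par$W4, 2, par$b4, `+`)
  A4 <- lrelu(ca$Z4)
  U1 <- as.matrix(geomc$up1 %*% A4)                    # to full res
  ca$X5 <- im2col(U1, geomc$s1)
  ca$Z5 <- sweep(ca$X5 %*% par$W5, 2, par$b5, `+`)
  ca$A5 <- lrelu(ca$Z5)
  out <- as.numeric(ca$A5 %*% par$W6) + par$b6
  list(out = out, cache = ca)
}

# backward pass; dout is the loss gradient w.r.t. the output vector
#' @noRd
gidc_backward <- function(par, ca, dout, geomc) {
  C <- ncol(par$W1)
  g <- list()
  dOut <- matrix(dout, ncol = 1)
  g$W6 <- crossprod(ca$A5, dOut)
  g$b6 <- sum(dOut)
  dA5 <- dOut %*% t(par$W6)
  dZ5 <- dA5 * lrelu_grad(ca$Z5)
  g$W5 <- crossprod(ca$X5, dZ5)
  g$b5 <- colSums(dZ5)
  dU1 <- col2im_grad(dZ5 %*% t(par$W5), geomc$s1, C)
  dA4 <- as.matrix(Matrix::crossprod(geomc$up1, dU1))  # upsample adjoint
  dZ4 <- dA4 * lrelu_grad(ca$Z4)
  g$W4 <- crossprod(ca$X4, dZ4)
  g$b4 <- colSums(dZ4)
  dcat <- col2im_grad(dZ4 %*% t(par$W4), geomc$s2, 2L * C)
  dU2 <- dcat[, seq_len(C), drop = FALSE]
  dA2 <- dcat[, C + seq_len(C), drop = FALSE]
  dA3 <- as.matrix(Matrix::crossprod(geomc$up2, dU2))
  dZ3 <- dA3 * lrelu_grad(ca$Z3)
  g$W3 <- crossprod(ca$X3, dZ3)
  g$b3 <- colSums(dZ3)
  dP2 <- col2im_grad(dZ3 %*% t(par$W3), geomc$s4, C)
  dA2p <- matrix(0, nrow(ca$Z2), C)
  for (k in 1:4) dA2p[geomc$pool2[, k], ] <- dA2p[geomc$pool2[, k], ] + dP2 / 4
  dA2 <- dA2 + dA2p
  dZ2 <- dA2 * lrelu_grad(ca$Z2)
  g$W2 <- crossprod(ca$X2, dZ2)
  g$b2 <- colSums(dZ2)
  dP1 <- col2im_grad(dZ2 %*% t(par$W2), geomc$s2, C)
  dA1p <- matrix(0, nrow(ca$Z1), C)
  for (k in 1:4) dA1p[geomc$pool1[, k], ] <- dA1p[geomc$pool1[, k], ] + dP1 / 4
  dZ1 <- dA1p * lrelu_grad(ca$Z1)
  g$W1 <- crossprod(ca$X1, dZ1)
  g$b1 <- colSums(dZ1)
  g
}

#' Untrained-network ghost-imaging reconstruction
#'
#' Recovers the response map from `(A, S)` by optimising a small
#' randomly initialised convolutional network whose output must
#' reproduce the bucket signals through the measurement physics, plus
#' an anisotropic TV penalty (see the package vignette for the
#' objective and architecture). The network input is the linear (CGLS)
#' reconstruction, or `init` if supplied. The returned image is the
#' best-loss iterate over the run, and the whole optimisation is
#' bit-reproducible for a fixed `params$seed`.
#'
#' The recorded loss is `sum((A f - S)^2) + tau * TV(f)` on the
#' mean-centred system in normalised units (bucket fluctuations at
#' unit maximum, image in units of the linear reconstruction's
#' maximum).
#'
#' @inheritParams reconstruct_linear
#' @param params a [gidc_params()].
#' @param init optional `sct_recon` (or matrix) used as network input
#'   instead of the CGLS reconstruction.
#' @return an `sct_recon` with `method = "gidc"`, full `loss_history`
#'   and the step index of the returned (best) iterate.
#' @export
#' @examples
#' m <- generate_mask(64, 64, 100, seed = 1)
#' A <- extract_patterns(m, 64, c(8, 8), seed = 2)
#' x_true <- matrix(rep(c(0, 1), each = 32), 8, 8)
#' S <- bucket_signals(A, x_true)
#' rec <- reconstruct_gidc(A, S, gidc_params(image_shape = c(8, 8), n_steps = 50))
reconstruct_gidc <- function(A, S, params, init = NULL, center = TRUE) {
  stopifnot(inherits(params, "gidc_params"))
  s_raw <- check_system(A, S)
  h <- params$image_shape[1]; w <- params$image_shape[2]
  if (h * w != ncol(A$values)) {
    sct_stop("invalid_argument",
             "image_shape %d x %d inconsistent with A (%d columns)",
             h, w, ncol(A$values))
  }

  sys <- center_system(A$values, s_raw, center, dc_weight = "unit")
  Ac <- sys$A; sc <- sys$s
  m <- nrow(Ac)

  x0m <- if (is.null(init)) {
    reconstruct_linear(A, S, "cgls", max_iter = 100L, center = center)$image
  } else if (inherits(init, "sct_recon")) init$image else as.matrix(init)

  # normalised solving units: bucket fluctuations scaled to unit
  # maximum, the image expressed in units of the linear
  # reconstruction's maximum (so f is O(1)), and the operator rescaled
  # to keep A f = S consistent. In these units the summed data term
  # and tau * TV balance at realistic noise levels for the default
  # tv_strength; see the methods vignette.
  q <- sys$fluct_scale
  x_unit <- max(abs(x0m))
  if (x_unit == 0) x_unit <- 1
  sn <- sc / q
  An <- Ac * (x_unit / q)
  x0 <- as.numeric(x0m) / x_unit

  if (h < 8 || w < 8) {
    sct_stop("invalid_argument", "image_shape must be at least 8 x 8")
  }
  geomc <- gidc_geometry(h, w)
  par <- gidc_init_weights(params$n_channels, params$seed)

  # Adam state
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- params$learning_rate; tau <- params$tv_strength

  loss_hist <- numeric(params$n_steps)
  best_loss <- Inf; best_img <- matrix(x0, h, w); best_step <- 0L
  last_finite <- 0L

  for (step in seq_len(params$n_steps)) {
    fw <- gidc_forward(par, x0, geomc)
    f <- fw$out
    r <- as.numeric(An %*% f) - sn
    fm <- matrix(f, h, w)
    loss <- sum(r^2) + tau * tv_norm(fm)
    if (!is.finite(loss)) {
      sct_stop("optimization_failure",
               "loss became non-finite at step %d (last finite step %d)",
               step, last_finite)
    }
    last_finite <- step
    loss_hist[step] <- loss
    if (loss < best_loss) {
      best_loss <- loss; best_img <- fm; best_step <- step
    }
    dout <- 2 * as.numeric(crossprod(An, r)) +
      tau * as.numeric(tv_grad(fm))
    g <- gidc_backward(par, fw$cache, dout, geomc)
    # linear warm-up tames Adam's unit-size first steps; cosine decay
    # settles the late phase so the best iterate is a stable one
    lr_t <- lr * min(1, step / 50) *
      (0.1 + 0.9 * (1 + cos(pi * step / params$n_steps)) / 2)
    for (nm in names(par)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^step)
      vhat <- vel[[nm]] / (1 - b2^step)
      par[[nm]] <- par[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
    }
  }

  img <- best_img * x_unit
  new_reconstruction(img, loss_hist, "gidc",
                     list(best_step = best_step, params = params,
                          tv_flavor = "anisotropic-l1"))
}
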