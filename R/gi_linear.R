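# Ghost-imaging inversion: recover the response map x from (A, S).
#
# All solvers share the differential-measurement preprocessing standard
# in GI: the measurement matrix is centred per pixel (column means
# removed) and the bucket vector centred to zero mean, which decouples
# the DC term the binary patterns share from the pattern fluctuations.
# Because ||Ax - S||^2 = ||Ac x - sc||^2 + m * (a_bar . x - s_bar)^2
# (the centred residual is orthogonal to the all-ones vector), the
# centred system augmented with one scaled mean row sqrt(m) * a_bar is
# exactly equivalent to the raw least-squares problem while being much
# better conditioned; that augmented form is what the solvers use.

#' @noRd
new_reconstruction <- function(image, loss_history, method, extra = list()) {
  structure(
    c(list(image = image, loss_history = loss_history, method = method), extra),
    class = "sct_recon"
  )
}

#' @export
print.sct_recon <- function(x, ...) {
  cat(sprintf("<sct_recon> %d x %d, method %s, final loss %.4g\n",
              nrow(x$image), ncol(x$image), x$method,
              if (length(x$loss_history)) tail(x$loss_history, 1) else NA))
  invisible(x)
}

#' @noRd
as_bucket_values <- function(S) {
  if (inherits(S, "sct_buckets")) S$values else as.numeric(S)
}

#' @noRd
check_system <- function(A, S) {
  stopifnot(inherits(A, "sct_patterns"))
  s <- as_bucket_values(S)
  if (nrow(A$values) != length(s)) {
    sct_stop("invalid_argument", "A has %d rows but S has %d values",
             nrow(A$values), length(s))
  }
  if (all(A$values == 0)) sct_stop("degenerate_system", "measurement matrix is all zero")
  s
}

# centred system plus the scaled mean row: same least-squares solution
# as the raw system, better conditioned
# dc_weight "full" (sqrt(m), exactly the raw least-squares problem;
# used by the linear solvers) or "unit" (the mean equation counts as
# one ordinary measurement; used by the regularised solvers, where a
# dominant DC row would otherwise swamp the optimisation)
#' @noRd
center_system <- function(Av, s, center, dc_weight = c("full", "unit")) {
  dc_weight <- match.arg(dc_weight)
  if (!center) {
    return(list(A = Av, s = s, fluct_scale = max(abs(s), 1e-300)))
  }
  m <- nrow(Av)
  wdc <- if (dc_weight == "full") sqrt(m) else 1
  cm <- colMeans(Av)
  Ac <- rbind(sweep(Av, 2, cm), wdc * cm)
  sc <- c(s - mean(s), wdc * mean(s))
  # scale of the differential (centred) part of the signal, excluding
  # the appended DC row — the natural unit for regularisation weights
  list(A = Ac, s = sc, fluct_scale = max(abs(s - mean(s)), 1e-300))
}

#' Linear ghost-imaging reconstruction
#'
#' Solves `A x = S` for the response map by dense minimum-norm least
#' squares (`"pinv"`, SVD with relative tolerance on singular values)
#' or conjugate gradients on the normal equations (`"cgls"`), stopping
#' when the relative residual `||Ax - S|| / ||S||` falls below `tol`
#' or after `max_iter` iterations.
#'
#' @param A an `sct_patterns`.
#' @param S an `sct_buckets` or numeric vector, length `nrow(A$values)`.
#' @param method `"pinv"` or `"cgls"`.
#' @param max_iter CGLS iteration cap.
#' @param tol relative residual target.
#' @param center mean-centre A and S before solving (differential GI);
#'   default `TRUE`. The image mean is restored afterwards.
#' @return an `sct_recon`; `loss_history` holds per-iteration relative
#'   residuals (a single value for `"pinv"`).
#' @export
#' @examples
#' m <- generate_mask(64, 64, 100, seed = 1)
#' A <- extract_patterns(m, 64, c(8, 8), seed = 2)
#' x_true <- matrix(runif(64), 8, 8)
#' S <- bucket_signals(A, x_true)
#' rec <- reconstruct_linear(A, S, "cgls")
reconstruct_linear <- function(A, S, method = c("cgls", "pinv"),
                               max_iter = 200L, tol = 1e-10, center = TRUE) {
  method <- match.arg(method)
  s_raw <- check_system(A, S)
  sys <- center_system(A$values, s_raw, center)
  Ac <- sys$A; sc <- sys$s
  s_norm <- sqrt(sum(s_raw^2)); if (s_norm == 0) s_norm <- 1

  if (method == "pinv") {
    sv <- svd(Ac)
    keep <- sv$d > max(dim(Ac)) * .Machine$double.eps * sv$d[1]
    x <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], sc)) / sv$d[keep])
    x <- as.numeric(x)
    loss <- sqrt(sum((A$values %*% x - s_raw)^2)) / s_norm
    return(new_reconstruction(matrix(x, A$pattern_shape[1], A$pattern_shape[2]),
                              loss, "pinv"))
  }

  # CGLS on the centred system
  x <- numeric(ncol(Ac))
  r <- sc
  p <- g <- as.numeric(crossprod(Ac, r))
  gg <- sum(g^2)
  sc_norm <- sqrt(sum(sc^2)); if (sc_norm == 0) sc_norm <- 1
  loss <- numeric(0)
  for (it in seq_len(max_iter)) {
    q <- as.numeric(Ac %*% p)
    qq <- sum(q^2)
    if (qq == 0) break
    alpha <- gg / qq
    x <- x + alpha * p
    r <- r - alpha * q
    loss <- c(loss, sqrt(sum(r^2)) / sc_norm)
    if (tail(loss, 1) <= tol) break
    g <- as.numeric(crossprod(Ac, r))
    gg_new <- sum(g^2)
    p <- g + (gg_new / gg) * p
    gg <- gg_new
  }
  new_reconstruction(matrix(x, A$pattern_shape[1], A$pattern_shape[2]),
                     loss, "cgls")
}

#' Anisotropic total variation of an image
#'
#' Sum of absolute forward differences along both axes (no
#' wraparound). Penalising this favours piecewise-constant images.
#'
#' @param image numeric matrix, at least 2 x 2.
#' @return scalar TV value.
#' @export
#' @examples
#' tv_norm(matrix(c(0, 0, 1, 1), 2, 2))
tv_norm <- function(image) {
  image <- as.matrix(image)
  if (nrow(image) < 2 || ncol(image) < 2) {
    sct_stop("invalid_argument", "image must be at least 2x2")
  }
  sum(abs(image[-1, ] - image[-nrow(image), ])) +
    sum(abs(image[, -1] - image[, -ncol(image)]))
}

# gradient of the eps-smoothed anisotropic TV
#' @noRd
tv_grad <- function(img, eps = 1e-8) {
  nr <- nrow(img); nc <- ncol(img)
  g <- matrix(0, nr, nc)
  dv <- img[-1, , drop = FALSE] - img[-nr, , drop = FALSE]
  wv <- dv / sqrt(dv^2 + eps^2)
  g[-1, ] <- g[-1, , drop = FALSE] + wv
  g[-nr, ] <- g[-nr, , drop = FALSE] - wv
  dh <- img[, -1, drop = FALSE] - img[, -nc, drop = FALSE]
  wh <- dh / sqrt(dh^2 + eps^2)
  g[, -1] <- g[, -1, drop = FALSE] + wh
  g[, -nc] <- g[, -nc, drop = FALSE] - wh
  g
}

# anisotropic TV proximal operator via fixed-point dual iterations
# (Chambolle-style projected gradient on the dual), deterministic
#' @noRd
tv_prox <- function(img, weight, n_inner = 30L) {
  if (weight <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  pv <- matrix(0, nr - 1, nc)
  ph <- matrix(0, nr, nc - 1)
  tau_d <- 0.25
  for (i in seq_len(n_inner)) {
    # divergence of dual field
    div <- matrix(0, nr, nc)
    div[-nr, ] <- div[-nr, , drop = FALSE] - pv
    div[-1, ] <- div[-1, , drop = FALSE] + pv
    div[, -nc] <- div[, -nc, drop = FALSE] - ph
    div[, -1] <- div[, -1, drop = FALSE] + ph
    u <- img - weight * div
    gv <- u[-1, , drop = FALSE] - u[-nr, , drop = FALSE]
    gh <- u[, -1, drop = FALSE] - u[, -nc, drop = FALSE]
    pv <- pmax(pmin(pv + tau_d * gv / weight, 1), -1)
    ph <- pmax(pmin(ph + tau_d * gh / weight, 1), -1)
  }
  div <- matrix(0, nr, nc)
  div[-nr, ] <- div[-nr, , drop = FALSE] - pv
  div[-1, ] <- div[-1, , drop = FALSE] + pv
  div[, -nc] <- div[, -nc, drop = FALSE] - ph
  div[, -1] <- div[, -1, drop = FALSE] + ph
  img - weight * div
}

#' TV-regularised least-squares reconstruction
#'
#' Network-free TV baseline: monotone-FISTA proximal-gradient
#' minimisation of the same objective the untrained-network solver
#' uses, `sum((A f - S)^2) + tau * TV(f)` on the centred system in
#' normalised units (bucket fluctuations at unit maximum, image in
#' units of the linear reconstruction's maximum, operator rescaled
#' accordingly — so `tau` is directly comparable between the two
#' solvers), directly over pixels. The gradient step uses `step`
#' (default `1 / (2 sigma_max^2)` of the normalised operator, from a
#' power iteration); the TV proximal step uses dual iterations. Accepted iterates never increase the
#' objective, so the recorded loss history is non-increasing. Fully
#' deterministic.
#'
#' @inheritParams reconstruct_linear
#' @param tau TV regularisation weight (>= 0); default `10^-3.9`.
#' @param n_steps number of outer proximal-gradient steps.
#' @param step gradient step size; `NULL` for the spectral default.
#' @param init starting image: `"cgls"` (default, warm start at the
#'   linear reconstruction), `"zero"`, or a numeric matrix.
#' @return an `sct_recon`; `loss_history` holds the normalised
#'   objective per step.
#' @export
reconstruct_tv_least_squares <- function(A, S, tau = 10^-3.9, n_steps = 150L,
                                         step = NULL, center = TRUE,
                                         init = "cgls") {
  s_raw <- check_system(A, S)
  if (tau < 0) sct_stop("invalid_argument", "tau must be >= 0")
  sys <- center_system(A$values, s_raw, center, dc_weight = "unit")
  h <- A$pattern_shape[1]; w <- A$pattern_shape[2]

  x0 <- if (is.matrix(init)) {
    init
  } else if (identical(init, "cgls")) {
    reconstruct_linear(A, S, "cgls", max_iter = 200L, center = center)$image
  } else {
    matrix(0, h, w)
  }
  q <- sys$fluct_scale
  x_unit <- max(abs(x0))
  if (x_unit == 0) x_unit <- 1
  An <- sys$A * (x_unit / q)
  sn <- sys$s / q

  if (is.null(step)) {
    # power iteration for sigma_max^2 (deterministic start)
    v <- rep(1 / sqrt(ncol(An)), ncol(An))
    for (i in 1:30) {
      v <- as.numeric(crossprod(An, An %*% v))
      v <- v / sqrt(sum(v^2))
    }
    L <- sum((An %*% v)^2)
    step <- 1 / (2 * L)
  }

  obj <- function(xm) {
    sum((An %*% as.numeric(xm) - sn)^2) + tau * tv_norm(xm)
  }
  # monotone FISTA: accelerated proximal gradient whose accepted
  # iterate never increases the objective
  x <- x0 / x_unit
  y <- x
  f <- obj(x)
  tk <- 1
  loss <- numeric(n_steps)
  for (it in seq_len(n_steps)) {
    grad <- 2 * as.numeric(crossprod(An, An %*% as.numeric(y) - sn))
    z <- matrix(as.numeric(y) - step * grad, h, w)
    if (tau > 0) z <- tv_prox(z, step * tau)
    fz <- obj(z)
    x_new <- if (fz <= f) z else x
    f <- min(fz, f)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + (tk / t_new) * (z - x_new) +
      ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    loss[it] <- f
  }
  new_reconstruction(x * x_unit, loss, "tv-least-squares",
                     list(tau = tau))
}

#' Area-weighted resize to a power-of-two grid
#'
#' Resamples an image onto a power-of-two grid (as required by the
#' untrained-network solver) by exact pixel-area overlap weighting:
#' each input pixel's value is distributed over the output pixels in
#' proportion to the overlapped area, so the total intensity is
#' preserved exactly.
#'
#' @param image numeric matrix.
#' @param target integer `(height, width)`, both powers of two.
#' @return resized matrix of dimension `target`.
#' @export
#' @examples
#' img <- matrix(runif(184 * 163), 184, 163)
#' out <- resize_to_pow2(img, c(128, 128))
#' all.equal(sum(img), sum(out))
resize_to_pow2 <- function(image, target) {
  image <- as.matrix(image)
  target <- as.integer(target)
  if (length(target) != 2 || !is_pow2(target[1]) || !is_pow2(target[2])) {
    sct_stop("invalid_argument", "target dimensions must be powers of two")
  }
  if (all(dim(image) == target)) return(image)
  M1 <- overlap_matrix(target[1], nrow(image))
  M2 <- overlap_matrix(target[2], ncol(image))
  M1 %*% image %*% t(M2)
}

# n_out x n_in matrix of fractional overlaps; columns sum to 1 so the
# image total is conserved
#' @noRd
overlap_matrix <- function(n_out, n_in) {
  e_in <- seq(0, 1, length.out = n_in + 1)
  e_out <- seq(0, 1, length.out = n_out + 1)
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_in)) {
    lo <- e_in[i]; hi <- e_in[i + 1]
    j0 <- max(1L, findInterval(lo, e_out, rightmost.closed = TRUE))
    j1 <- min(n_out, findInterval(hi, e_out, rightmost.closed = TRUE))
    for (j in j0:j1) {
      ov <- min(hi, e_out[j + 1]) - max(lo, e_out[j])
      if (ov > 0) M[j, i] <- ov / (hi - lo)
    }
  }
  M
}
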