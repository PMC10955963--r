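# Parallel-beam tomography: projector, SART-TV, modality handling.
#
# Geometry convention: volumes are (nx, ny, nz) with z the rotation
# axis; each z slice is projected independently onto a 1D detector of
# nx bins. The projector angle convention matches rotate_phantom():
# forward_project(v, a) of an unrotated volume approximates the +y
# line-integral projection of the volume rotated by `a` degrees.
# Line integrals are exact for the bilinear interpolant of the slice
# (per-cell Simpson quadrature), so the adjoint is exactly t(P).

.proj_cache <- new.env(parent = emptyenv())

#' The 28-angle projection list of the reference acquisition
#'
#' The fixed, deliberately interleaved order of object rotations used
#' to acquire 28 projections (coarse bisection first, then finer and
#' asymmetric fill-in angles).
#'
#' @return numeric vector of 28 angles in degrees, in acquisition order.
#' @export
#' @examples
#' length(paper_angle_list())
paper_angle_list <- function() {
  c(0, 180, 90, 270, 45, 225, 315, 135,
    22.5, 202.5, 67.5, 247.5, 112.5, 292.5, 157.5, 337.5,
    355, 175, 348, 168, 353, 173, 5, 185, 12, 192, 300, 120)
}

#' Projection stack
#'
#' Container for per-angle 2D images of one modality.
#'
#' @param images list of numeric matrices, all of one shape
#'   (detector-u x z rows/cols).
#' @param angles_deg numeric vector of angles in `[0, 360)`, one per
#'   image.
#' @param modality one of `"transmission"`, `"transmission-negative"`,
#'   `"scatter"`, `"combined"`.
#' @param pixel_um detector pixel size in um.
#' @return an `sct_projstack`.
#' @export
projection_stack <- function(images, angles_deg,
                             modality = c("transmission", "transmission-negative",
                                          "scatter", "combined"),
                             pixel_um = NA_real_) {
  modality <- match.arg(modality)
  if (length(images) != length(angles_deg)) {
    sct_stop("invalid_argument", "images and angles_deg lengths differ")
  }
  if (any(angles_deg < 0 | angles_deg >= 360)) {
    sct_stop("invalid_argument", "angles must lie in [0, 360)")
  }
  d1 <- dim(images[[1]])
  if (!all(vapply(images, function(im) identical(dim(im), d1), logical(1)))) {
    sct_stop("invalid_argument", "all images must share one shape")
  }
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 modality = modality, pixel_um = pixel_um),
            class = "sct_projstack")
}

#' @export
print.sct_projstack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<sct_projstack> %d x %s projections, %d x %d px\n",
              length(x$images), x$modality, d[1], d[2]))
  invisible(x)
}

#' Negative transmission image
#'
#' Scatter-like contrast from a transmission radiograph: dense regions
#' become bright. Returns `max(image) - image` rescaled to `[0, 1]`.
#'
#' @param image numeric matrix with a positive maximum and non-zero
#'   dynamic range.
#' @return matrix in `[0, 1]`.
#' @export
negative_transmission <- function(image) {
  image <- as.matrix(image)
  mx <- max(image); mn <- min(image)
  if (mx <= 0) sct_stop("invalid_argument", "image must have a positive maximum")
  if (mx == mn) sct_stop("degenerate_input", "constant image has no negative")
  (mx - image) / (mx - mn)
}

# robust 1st-99th percentile normalisation to [0, 1]
#' @noRd
robust_norm <- function(img) {
  q <- quantile(img, c(0.01, 0.99), names = FALSE)
  if (q[2] == q[1]) q <- range(img)
  if (q[2] == q[1]) return(img * 0)
  (img - q[1]) / (q[2] - q[1])
}

#' Combine transmission-negative and scatter projection stacks
#'
#' Per angle, the output image is
#' `w1 * normalize(trans_neg) + w2 * normalize(scatter)`, where
#' `normalize` maps the robust 1st-99th percentile range to `[0, 1]`.
#' Default weights `(0.5, 0.5)` give the normalized average of the two
#' modalities. Stacks must be pre-aligned and share angle lists.
#'
#' @param trans_neg,scatter `sct_projstack`s with matching shapes and
#'   angles.
#' @param weights numeric `(w1, w2)`.
#' @return an `sct_projstack` with modality `"combined"`.
#' @export
combine_modalities <- function(trans_neg, scatter, weights = c(0.5, 0.5)) {
  stopifnot(inherits(trans_neg, "sct_projstack"), inherits(scatter, "sct_projstack"))
  if (!isTRUE(all.equal(trans_neg$angles_deg, scatter$angles_deg))) {
    sct_stop("invalid_argument", "angle lists differ between stacks")
  }
  if (!identical(dim(trans_neg$images[[1]]), dim(scatter$images[[1]]))) {
    sct_stop("invalid_argument", "image shapes differ between stacks")
  }
  imgs <- Map(function(a, b) {
    weights[1] * robust_norm(a) + weights[2] * robust_norm(b)
  }, trans_neg$images, scatter$images)
  projection_stack(imgs, trans_neg$angles_deg, "combined",
                   pixel_um = trans_neg$pixel_um)
}

# ---- projector --------------------------------------------------------------

# sparse matrix of exact line integrals of the bilinear slice
# interpolant: rays u = 1..n at angle `theta_deg`, slice n x n
#' @noRd
projection_matrix <- function(n, theta_deg) {
  key <- sprintf("%d_%.8f", n, theta_deg %% 360)
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  a <- (theta_deg %% 360) * pi / 180
  eu <- c(cos(a), -sin(a))     # detector axis
  ev <- c(sin(a), cos(a))      # beam direction (matches rotate_phantom)
  cc <- (n + 1) / 2
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  tmax <- n    # |t| bound: slice fits in a circle of radius ~ n/sqrt(2)
  for (u_idx in seq_len(n)) {
    u <- u_idx - cc
    p0 <- c(u * eu[1] + cc, u * eu[2] + cc)
    # breakpoints where x(t) or y(t) hits integer grid coordinates
    ts <- c(-tmax, tmax)
    for (axis in 1:2) {
      d <- ev[axis]
      if (abs(d) > 1e-12) {
        ts <- c(ts, ((0:(n + 1)) - p0[axis]) / d)
      }
    }
    ts <- sort(unique(ts))
    ts <- ts[ts >= -tmax & ts <= tmax]
    if (length(ts) < 2) next
    t0 <- ts[-length(ts)]; t1 <- ts[-1]
    keep <- (t1 - t0) > 1e-12
    t0 <- t0[keep]; t1 <- t1[keep]
    tm <- (t0 + t1) / 2
    xm <- p0[1] + tm * ev[1]; ym <- p0[2] + tm * ev[2]
    i0 <- floor(xm); j0 <- floor(ym)
    inb <- i0 >= 0 & i0 <= n & j0 >= 0 & j0 <= n
    if (!any(inb)) next
    for (s in which(inb)) {
      ia <- i0[s]; ja <- j0[s]
      tt <- c(t0[s], tm[s], t1[s])
      x <- p0[1] + tt * ev[1]; y <- p0[2] + tt * ev[2]
      wS <- (t1[s] - t0[s]) / 6 * c(1, 4, 1)
      for (ci in c(ia, ia + 1L)) {
        if (ci < 1 || ci > n) next
        hx <- 1 - abs(x - ci)
        for (cj in c(ja, ja + 1L)) {
          if (cj < 1 || cj > n) next
          hy <- 1 - abs(y - cj)
          val <- sum(wS * hx * hy)
          if (val != 0) {
            tri_i <- c(tri_i, u_idx)
            tri_j <- c(tri_j, ci + (cj - 1L) * n)
            tri_x <- c(tri_x, val)
          }
        }
      }
    }
  }
  M <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(n, n * n))
  .proj_cache[[key]] <- M
  M
}

#' Volume container
#'
#' @param values 3D numeric array `(nx, ny, nz)`.
#' @param voxel_um voxel edge length in um.
#' @return an `sct_volume`.
#' @export
volume <- function(values, voxel_um) {
  stopifnot(length(dim(values)) == 3)
  assert_pos(voxel_um, "voxel_um")
  if (any(!is.finite(values))) sct_stop("invalid_argument", "volume must be finite")
  structure(list(values = values, voxel_um = voxel_um), class = "sct_volume")
}

#' @export
print.sct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sct_volume> %d x %d x %d voxels @ %.3g um\n",
              d[1], d[2], d[3], x$voxel_um))
  invisible(x)
}

#' Parallel-beam forward projection of a volume
#'
#' Slice-by-slice line integrals of the bilinear interpolant of each
#' z slice along the rotated beam direction. The projection of the
#' unrotated volume at angle `a` matches [transmission_projection()]'s
#' path integrals of the phantom rotated to the same `a` (up to
#' interpolation differences). The backprojector used inside
#' [sart_tv()] is the exact transpose, so
#' `<P v, s> == <v, t(P) s>` to machine precision.
#'
#' @param vol an `sct_volume` with square transverse dimensions.
#' @param angles_deg projection angles in degrees.
#' @param modality stored modality tag, default `"transmission"`.
#' @return an `sct_projstack` of `(n_u x nz)` images in units of
#'   `value * mm`.
#' @export
forward_project <- function(vol, angles_deg, modality = "transmission") {
  stopifnot(inherits(vol, "sct_volume"))
  d <- dim(vol$values)
  if (d[1] != d[2]) sct_stop("invalid_argument", "transverse dimensions must be square")
  n <- d[1]; nz <- d[3]
  vmat <- matrix(vol$values, n * n, nz)
  vox_mm <- vol$voxel_um / 1000
  imgs <- lapply(angles_deg, function(a) {
    as.matrix(projection_matrix(n, a) %*% vmat) * vox_mm
  })
  projection_stack(imgs, angles_deg %% 360, modality, pixel_um = vol$voxel_um)
}

# smoothed anisotropic 3D TV gradient
#' @noRd
tv_grad3 <- function(v, eps = 1e-8) {
  g <- array(0, dim(v))
  for (axis in 1:3) {
    n <- dim(v)[axis]
    if (n < 2) next
    idx1 <- lapply(dim(v), seq_len); idx0 <- idx1
    idx1[[axis]] <- 2:n; idx0[[axis]] <- 1:(n - 1)
    d <- do.call(`[`, c(list(v), idx1)) - do.call(`[`, c(list(v), idx0))
    w <- d / sqrt(d^2 + eps^2)
    ga <- array(0, dim(v))
    ga <- do.call(`[<-`, c(list(ga), idx1, list(do.call(`[`, c(list(ga), idx1)) + w)))
    ga <- do.call(`[<-`, c(list(ga), idx0, list(do.call(`[`, c(list(ga), idx0)) - w)))
    g <- g + ga
  }
  g
}

#' SART-TV parameters
#'
#' @param n_iterations SART sweeps over all angles (>= 1).
#' @param tv_lambda TV relaxation strength: after each sweep the total
#'   TV descent length is `tv_lambda * ||SART update||` (ASD-POCS-style
#'   scaling; 0 disables TV).
#' @param tv_iter TV gradient-descent steps per sweep (>= 1).
#' @param mode only `"parallel"` beam geometry is implemented.
#' @param relaxation SART relaxation factor in (0, 2).
#' @return an `sct_sart_params`.
#' @export
sart_params <- function(n_iterations = 50L, tv_lambda = 0.2, tv_iter = 10L,
                        mode = "parallel", relaxation = 0.3) {
  if (n_iterations < 1 || tv_iter < 1) {
    sct_stop("invalid_argument", "iteration counts must be >= 1")
  }
  if (tv_lambda < 0) sct_stop("invalid_argument", "tv_lambda must be >= 0")
  if (!identical(mode, "parallel")) {
    sct_stop("invalid_argument", "only parallel mode is implemented")
  }
  structure(list(n_iterations = as.integer(n_iterations), tv_lambda = tv_lambda,
                 tv_iter = as.integer(tv_iter), mode = mode,
                 relaxation = relaxation),
            class = "sct_sart_params")
}

#' SART-TV tomographic reconstruction
#'
#' Simultaneous Algebraic Reconstruction Technique with total-variation
#' relaxation: each iteration sweeps the projection angles in the given
#' order, applying the relaxed SART update per angle, then takes
#' `tv_iter` normalised gradient-descent steps on the (smoothed)
#' anisotropic 3D TV whose total length is `tv_lambda` times the norm
#' of that sweep's SART update, and finally projects onto the
#' non-negative orthant. Deterministic for fixed inputs.
#'
#' @param projections an `sct_projstack` (values in `value * mm` units,
#'   as produced by [forward_project()]; arbitrary positive images such
#'   as scatter reconstructions are handled identically).
#' @param params an [sart_params()].
#' @param volume_shape integer `(n, n, nz)` of the output volume;
#'   defaults to the cube implied by the projection shape.
#' @return an `sct_volume` (non-negative).
#' @export
sart_tv <- function(projections, params = sart_params(), volume_shape = NULL) {
  stopifnot(inherits(projections, "sct_projstack"),
            inherits(params, "sct_sart_params"))
  if (length(projections$images) == 0) {
    sct_stop("invalid_argument", "projection stack is empty")
  }
  d <- dim(projections$images[[1]])
  n_u <- d[1]; nz <- d[2]
  if (is.null(volume_shape)) volume_shape <- c(n_u, n_u, nz)
  volume_shape <- as.integer(volume_shape)
  if (volume_shape[1] != n_u || volume_shape[2] != n_u || volume_shape[3] != nz) {
    sct_stop("invalid_argument",
             "volume_shape must be (%d, %d, %d) for these projections",
             n_u, n_u, nz)
  }
  n <- n_u
  vox_um <- if (is.finite(projections$pixel_um %||% NA_real_)) projections$pixel_um else 1000
  vox_mm <- vox_um / 1000

  angles <- projections$angles_deg
  mats <- lapply(angles, function(a) projection_matrix(n, a))
  row_sums <- lapply(mats, function(M) {
    r <- Matrix::rowSums(M); r[r == 0] <- Inf; r
  })
  col_sums <- lapply(mats, function(M) {
    cs <- Matrix::colSums(M); cs[cs == 0] <- Inf; cs
  })
  # projections in voxel-length units so M applies directly
  pmats <- lapply(projections$images, function(im) im / vox_mm)

  v <- matrix(0, n * n, nz)
  relax <- params$relaxation
  for (it in seq_len(params$n_iterations)) {
    v_before <- v
    for (a in seq_along(mats)) {
      M <- mats[[a]]
      r <- pmats[[a]] - as.matrix(M %*% v)
      upd <- as.matrix(Matrix::crossprod(M, r / row_sums[[a]])) / col_sums[[a]]
      v <- v + relax * upd
    }
    if (any(!is.finite(v))) {
      sct_stop("optimization_failure", "non-finite volume at iteration %d", it)
    }
    if (params$tv_lambda > 0) {
      dlen <- params$tv_lambda * sqrt(sum((v - v_before)^2))
      if (dlen > 0) {
        va <- array(v, c(n, n, nz))
        step_len <- dlen / params$tv_iter
        for (k in seq_len(params$tv_iter)) {
          g <- tv_grad3(va)
          gn <- sqrt(sum(g^2))
          if (gn == 0) break
          va <- va - step_len * g / gn
        }
        v <- matrix(va, n * n, nz)
      }
    }
    v[v < 0] <- 0
  }
  volume(array(v, c(n, n, nz)), vox_um)
}
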