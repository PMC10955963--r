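#' Synthetic bone phantom with a tapered through-hole
#'
#' Builds the package's standard test object: a cortical-shell bone
#' cylinder (axis along the third array dimension, the rotation axis)
#' drilled by one conical through-hole whose diameter tapers linearly
#' from `hole_top_um` at the top slice to `hole_bottom_um` at the
#' bottom, emulating a ~2000 um to ~1200 um tapered defect. The shell
#' carries the full cortical attenuation/density; the interior is
#' trabecular-like at 60 % of the cortical values with a small seeded
#' multiplicative texture so reconstructions are not trivially flat.
#'
#' @param shape integer `(nx, ny, nz)` voxel counts; `nz` is along the
#'   cylinder/rotation axis.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param hole_top_um,hole_bottom_um hole diameters (um) at the top
#'   (last z slice) and bottom (first z slice); both 0 gives a solid
#'   cylinder.
#' @param mu_bone linear attenuation coefficient of cortical bone in
#'   mm^-1 (default 0.1, roughly cortical bone at diagnostic energies).
#' @param rho_bone relative electron (scatter) density of cortical bone
#'   (default 1).
#' @param radius_frac cylinder outer radius as a fraction of the
#'   half-extent of the transverse grid (default 0.8).
#' @param texture relative amplitude of the interior density texture
#'   (default 0.05; 0 disables it).
#' @param seed RNG seed for the texture.
#' @return an object of class `sct_phantom` with 3D arrays `mu` (mm^-1)
#'   and `rho_e`, and `voxel_mm`.
#' @export
#' @examples
#' ph <- make_bone_phantom(c(32, 32, 32), voxel_mm = 0.25, seed = 1)
#' range(ph$mu)
make_bone_phantom <- function(shape, voxel_mm,
                              hole_top_um = 2000, hole_bottom_um = 1200,
                              mu_bone = 0.1, rho_bone = 1,
                              radius_frac = 0.8, texture = 0.05, seed = 0L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  assert_pos(voxel_mm, "voxel_mm")
  if (hole_top_um < 0 || hole_bottom_um < 0) {
    sct_stop("invalid_argument", "hole diameters must be >= 0")
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  extent_um <- min(nx, ny) * voxel_mm * 1000
  if (max(hole_top_um, hole_bottom_um) > extent_um) {
    sct_stop("invalid_argument",
             "hole diameter %.0f um exceeds phantom transverse extent %.0f um",
             max(hole_top_um, hole_bottom_um), extent_um)
  }

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_out <- radius_frac * (min(nx, ny) / 2)         # voxels
  r_shell <- 0.85 * r_out                          # cortical shell thickness 15 %
  xs <- seq_len(nx) - cx
  ys <- seq_len(ny) - cy
  r2 <- outer(xs^2, ys^2, `+`)                     # nx x ny squared radius
  inside <- r2 <= r_out^2
  shell <- inside & (r2 > r_shell^2)

  mu2 <- matrix(0, nx, ny)
  rho2 <- matrix(0, nx, ny)
  mu2[inside] <- 0.6 * mu_bone; mu2[shell] <- mu_bone
  rho2[inside] <- 0.6 * rho_bone; rho2[shell] <- rho_bone

  mu <- array(rep(mu2, nz), dim = shape)
  rho <- array(rep(rho2, nz), dim = shape)

  if (texture > 0) {
    tex <- with_seed(seed, array(1 + texture * rnorm(prod(shape)), dim = shape))
    tex[tex < 0.5] <- 0.5
    interior <- array(rep(inside & !shell, nz), dim = shape)
    mu[interior] <- mu[interior] * tex[interior]
    rho[interior] <- rho[interior] * tex[interior]
  }

  # conical hole: axis offset a third of the way to the rim so the
  # taper is visible away from the centre while keeping clearance from
  # the cortical shell; diameter linear in z
  if (hole_top_um > 0 || hole_bottom_um > 0) {
    hx <- cx + r_out / 3
    hy <- cy
    hr2 <- outer((seq_len(nx) - hx)^2, (seq_len(ny) - hy)^2, `+`)
    for (k in seq_len(nz)) {
      frac <- if (nz > 1) (k - 1) / (nz - 1) else 0
      d_um <- hole_bottom_um + frac * (hole_top_um - hole_bottom_um)
      r_hole <- (d_um / 1000 / voxel_mm) / 2      # voxels
      if (r_hole > 0) {
        hole <- hr2 <= r_hole^2
        muk <- mu[, , k]; rhok <- rho[, , k]
        muk[hole] <- 0; rhok[hole] <- 0
        mu[, , k] <- muk; rho[, , k] <- rhok
      }
    }
  }

  structure(
    list(mu = mu, rho_e = rho, voxel_mm = voxel_mm, seed = as.integer(seed),
         hole_top_um = hole_top_um, hole_bottom_um = hole_bottom_um,
         hole_center = c(cx + r_out / 3, cy), r_out_vox = r_out,
         r_shell_vox = r_shell),
    class = "sct_phantom"
  )
}

#' @export
print.sct_phantom <- function(x, ...) {
  d <- dim(x$mu)
  cat(sprintf("<sct_phantom> %d x %d x %d voxels @ %.3g mm, mu in [%.3g, %.3g] mm^-1\n",
              d[1], d[2], d[3], x$voxel_mm, min(x$mu), max(x$mu)))
  invisible(x)
}

#' Rotate a phantom about the vertical axis
#'
#' Resamples the voxel grids at coordinates rotated by `angle_deg`
#' (right-handed about the z axis, grid centre as pivot). Nearest-voxel
#' sampling is the deterministic default; `"trilinear"` interpolates in
#' the transverse plane.
#'
#' @param phantom an `sct_phantom`.
#' @param angle_deg rotation angle in degrees.
#' @param interp `"nearest"` or `"trilinear"`.
#' @return a rotated `sct_phantom`.
#' @export
rotate_phantom <- function(phantom, angle_deg, interp = c("nearest", "trilinear")) {
  stopifnot(inherits(phantom, "sct_phantom"))
  interp <- match.arg(interp)
  a <- (angle_deg %% 360) * pi / 180
  if (abs(a) < 1e-12) return(phantom)
  d <- dim(phantom$mu); nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- rep(seq_len(nx) - cx, times = ny)
  ys <- rep(seq_len(ny) - cy, each = nx)
  # sample source coordinates = inverse rotation of target grid
  xr <- cos(a) * xs + sin(a) * ys + cx
  yr <- -sin(a) * xs + cos(a) * ys + cy
  rot_slice <- function(sl) {
    out <- numeric(nx * ny)
    if (interp == "nearest") {
      xi <- round(xr); yi <- round(yr)
      ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
      out[ok] <- sl[cbind(xi[ok], yi[ok])]
    } else {
      x0 <- floor(xr); y0 <- floor(yr)
      fx <- xr - x0; fy <- yr - y0
      ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
      i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
      i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
      out[ok] <- sl[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
        sl[i10] * fx[ok] * (1 - fy[ok]) +
        sl[i01] * (1 - fx[ok]) * fy[ok] +
        sl[i11] * fx[ok] * fy[ok]
    }
    matrix(out, nx, ny)
  }
  mu <- phantom$mu; rho <- phantom$rho_e
  for (k in seq_len(nz)) {
    mu[, , k] <- rot_slice(phantom$mu[, , k])
    rho[, , k] <- rot_slice(phantom$rho_e[, , k])
  }
  out <- phantom
  out$mu <- mu; out$rho_e <- rho
  out
}
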