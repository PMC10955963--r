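# Physical constants (CODATA)
.r_e_m <- 2.8179403262e-15        # classical electron radius, m
.lambda_C_pm <- 2.42631023867     # electron Compton wavelength, pm
.hc_keV_pm <- 1239.84198          # h*c in keV * pm

#' Photon energy to wavelength
#'
#' @param energy_keV photon energy in keV (> 0).
#' @return wavelength in picometres.
#' @export
#' @examples
#' energy_to_wavelength_pm(60) # ~20.66 pm
energy_to_wavelength_pm <- function(energy_keV) {
  assert_pos(energy_keV, "energy_keV")
  .hc_keV_pm / energy_keV
}

#' Compton-shifted wavelength
#'
#' Wavelength of a photon after Compton scattering through `theta_deg`:
#' `lambda' = lambda + lambda_C * (1 - cos(theta))`, with `lambda_C`
#' the electron Compton wavelength (2.4263 pm).
#'
#' @param lambda_pm incident wavelength in pm (> 0).
#' @param theta_deg scattering angle in degrees.
#' @return scattered wavelength in pm.
#' @export
#' @examples
#' compton_wavelength(20.66, 90)
compton_wavelength <- function(lambda_pm, theta_deg) {
  if (any(lambda_pm <= 0)) sct_stop("invalid_argument", "lambda_pm must be > 0")
  lambda_pm + .lambda_C_pm * (1 - cos(theta_deg * pi / 180))
}

#' Klein-Nishina differential cross section
#'
#' Differential cross section for Compton scattering of an unpolarised
#' photon of wavelength `lambda` into angle `theta`:
#' `dSigma/dOmega = (1/2) r_e^2 (lambda/lambda')^2
#'   [lambda/lambda' + lambda'/lambda - sin^2(theta)]`,
#' with `lambda'` the Compton-shifted wavelength. At `theta = 0` this
#' equals `r_e^2`; in the long-wavelength limit it reduces to the
#' Thomson cross section `(r_e^2 / 2)(1 + cos^2 theta)`.
#'
#' @param lambda_pm incident wavelength in pm (> 0).
#' @param theta_deg scattering angle in degrees.
#' @return cross section in m^2 per steradian.
#' @export
#' @examples
#' klein_nishina(energy_to_wavelength_pm(80), 90)
klein_nishina <- function(lambda_pm, theta_deg) {
  if (any(lambda_pm <= 0)) sct_stop("invalid_argument", "lambda_pm must be > 0")
  lp <- compton_wavelength(lambda_pm, theta_deg)
  ratio <- lambda_pm / lp
  0.5 * .r_e_m^2 * ratio^2 *
    (ratio + 1 / ratio - sin(theta_deg * pi / 180)^2)
}

#' Scatter imaging geometry
#'
#' Bundles the beam/detector geometry for one projection. The beam runs
#' along the +y voxel axis; the single-pixel detector sits in the
#' horizontal plane at `detector_angle_deg` from the beam axis
#' (90 degrees in the experiment, where the Klein-Nishina cross section
#' is small), `detector_distance_mm` from the object (50 mm in the
#' experiment). `rotation_angle_deg` is the object rotation for the
#' current projection.
#'
#' @param photon_energy_keV incident photon energy (monoenergetic
#'   surrogate for an 80 kVp tube spectrum; default 60 keV).
#' @param detector_angle_deg scatter angle of the detector in `[0, 360]`.
#' @param detector_distance_mm object-to-detector distance.
#' @param rotation_angle_deg object rotation for this projection.
#' @return an `sct_geometry` list.
#' @export
scatter_geometry <- function(photon_energy_keV = 60,
                             detector_angle_deg = 90,
                             detector_distance_mm = 50,
                             rotation_angle_deg = 0) {
  assert_pos(photon_energy_keV, "photon_energy_keV")
  if (detector_angle_deg < 0 || detector_angle_deg > 360) {
    sct_stop("invalid_argument", "detector_angle_deg must lie in [0, 360]")
  }
  structure(
    list(photon_energy_keV = photon_energy_keV,
         detector_angle_deg = detector_angle_deg,
         detector_distance_mm = detector_distance_mm,
         rotation_angle_deg = rotation_angle_deg,
         beam_axis = c(0, 1, 0)),
    class = "sct_geometry"
  )
}

#' Single-scatter response map of a phantom
#'
#' Computes the object's scatter response `x` seen by a single-pixel
#' detector at `geom$detector_angle_deg` for one projection. The
#' phantom is rotated to `geom$rotation_angle_deg`, then for each
#' transverse beam pixel `(x, z)` the single-scatter line integral is
#' accumulated along the beam (+y):
#' `response = sum_k rho_e * T_in * KN(theta) * T_out`, where `T_in` is
#' Beer-Lambert attenuation from entry to voxel `k`, `KN` the
#' Klein-Nishina cross section at the detector angle, and `T_out`
#' attenuation along the straight exit ray toward the detector
#' (horizontal plane). Multiple scatter and solid-angle variation
#' across the object are neglected.
#'
#' @param phantom an `sct_phantom`.
#' @param geom an `sct_geometry`.
#' @param exit_step_vox step (in voxels) of the exit-ray attenuation
#'   march; 0.5 by default.
#' @param interp rotation interpolation, see [rotate_phantom()].
#' @return an `sct_response` with `values` (nx x nz matrix, beam-facing
#'   pixels), `pixel_um` and `angle_deg`.
#' @export
#' @examples
#' ph <- make_bone_phantom(c(16, 16, 8), 0.5, 0, 0, texture = 0)
#' r <- scatter_response_map(ph, scatter_geometry())
#' dim(r$values)
scatter_response_map <- function(phantom, geom, exit_step_vox = 0.5,
                                 interp = "nearest") {
  stopifnot(inherits(phantom, "sct_phantom"), inherits(geom, "sct_geometry"))
  ph <- rotate_phantom(phantom, geom$rotation_angle_deg, interp)
  d <- dim(ph$mu); nx <- d[1]; ny <- d[2]; nz <- d[3]
  vmm <- ph$voxel_mm
  kn <- klein_nishina(energy_to_wavelength_pm(geom$photon_energy_keV),
                      geom$detector_angle_deg)
  kn <- kn / .r_e_m^2   # report response in units of r_e^2 so values are O(1)

  # T_in: attenuation accumulated along +y up to (but excluding) voxel k
  mu <- ph$mu; rho <- ph$rho_e
  t_in <- array(0, d)
  acc <- matrix(0, nx, nz)
  for (j in seq_len(ny)) {
    t_in[, j, ] <- acc
    acc <- acc + mu[, j, ] * vmm
  }
  t_in <- exp(-t_in)

  l_out <- exit_path_integral(mu, geom$detector_angle_deg, exit_step_vox) * vmm
  t_out <- exp(-l_out)

  contrib <- rho * t_in * t_out * kn * vmm
  values <- apply(contrib, c(1, 3), sum)

  structure(
    list(values = values, pixel_um = vmm * 1000,
         angle_deg = geom$rotation_angle_deg,
         detector_angle_deg = geom$detector_angle_deg),
    class = "sct_response"
  )
}

# line integral of mu (in voxel-length units) from each voxel centre to
# the volume boundary along the horizontal exit direction
# (sin(theta), cos(theta), 0); midpoint rule with nearest-voxel lookup
#' @noRd
exit_path_integral <- function(mu, theta_deg, step = 0.5) {
  d <- dim(mu); nx <- d[1]; ny <- d[2]; nz <- d[3]
  a <- theta_deg * pi / 180
  dx <- sin(a); dy <- cos(a)
  n_steps <- ceiling(sqrt(nx^2 + ny^2) / step)
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  # per-step in-bounds sample indices, shared by every z slice
  idx_list <- vector("list", n_steps)
  ok_list <- vector("list", n_steps)
  n_used <- 0L
  for (s in seq_len(n_steps)) {
    t <- (s - 0.5) * step
    xi <- round(xs + t * dx); yi <- round(ys + t * dy)
    ok <- which(xi >= 1 & xi <= nx & yi >= 1 & yi <= ny)
    if (length(ok) == 0L) break
    idx_list[[s]] <- (yi[ok] - 1L) * nx + xi[ok]
    ok_list[[s]] <- ok
    n_used <- s
  }
  res <- array(0, d)
  for (k in seq_len(nz)) {
    slice <- mu[, , k]
    acc <- numeric(nx * ny)
    for (s in seq_len(n_used)) {
      w <- ok_list[[s]]
      acc[w] <- acc[w] + slice[idx_list[[s]]]
    }
    res[, , k] <- matrix(acc * step, nx, ny)
  }
  res
}

#' Parallel-beam transmission projection
#'
#' Beer-Lambert transmission image of the phantom at one rotation
#' angle: pixel `(x, z)` value `exp(-sum_y mu * voxel_mm)`. This is the
#' simulated analogue of the flat-panel transmission radiograph.
#'
#' @inheritParams scatter_response_map
#' @param rotation_angle_deg object rotation in degrees.
#' @return an `sct_response` (values in (0, 1]).
#' @export
transmission_projection <- function(phantom, rotation_angle_deg = 0,
                                    interp = "nearest") {
  stopifnot(inherits(phantom, "sct_phantom"))
  ph <- rotate_phantom(phantom, rotation_angle_deg, interp)
  path <- apply(ph$mu, c(1, 3), sum) * ph$voxel_mm
  structure(
    list(values = exp(-path), pixel_um = ph$voxel_mm * 1000,
         angle_deg = rotation_angle_deg, detector_angle_deg = NA_real_),
    class = "sct_response"
  )
}

#' @export
print.sct_response <- function(x, ...) {
  cat(sprintf("<sct_response> %d x %d px @ %.3g um, angle %.4g deg\n",
              nrow(x$values), ncol(x$values), x$pixel_um, x$angle_deg))
  invisible(x)
}

#' Simulate bucket signals S = A x
#'
#' Applies the measurement matrix to a response map: each bucket value
#' is the inner product of one illumination pattern with the object's
#' response, optionally Poisson-corrupted. With `noise = "poisson"`
#' each noiseless value `v` is replaced by a Poisson draw with mean
#' `scale * v / max(v)`, so `scale` is the expected photon count in the
#' brightest bucket — a single interpretable SNR knob.
#'
#' @param A an `sct_patterns` measurement matrix.
#' @param x an `sct_response` (or numeric matrix) whose pixel count
#'   equals `ncol(A$values)`.
#' @param noise `"none"` or `"poisson"`.
#' @param scale expected photons at the brightest bucket (Poisson only).
#' @param seed RNG seed for the noise draw.
#' @param normalize if `TRUE`, divide each bucket by the total
#'   transmitted area of its pattern (per-pattern normalisation of the
#'   measured data); default `FALSE`.
#' @return an `sct_buckets` with `values` (length `nrow(A$values)`),
#'   `angle_deg` and `noise_model`.
#' @export
#' @examples
#' m <- generate_mask(32, 32, 100, seed = 1)
#' A <- extract_patterns(m, 20, c(8, 8), seed = 2)
#' x <- matrix(runif(64), 8, 8)
#' S <- bucket_signals(A, x)
bucket_signals <- function(A, x, noise = c("none", "poisson"),
                           scale = 1e4, seed = 0L, normalize = FALSE) {
  stopifnot(inherits(A, "sct_patterns"))
  noise <- match.arg(noise)
  xv <- if (inherits(x, "sct_response")) x$values else x
  if (length(xv) != ncol(A$values)) {
    sct_stop("invalid_argument",
             "pattern matrix has %d columns but response has %d pixels",
             ncol(A$values), length(xv))
  }
  v <- as.numeric(A$values %*% as.numeric(xv))
  if (normalize) {
    area <- rowSums(A$values)
    area[area == 0] <- 1
    v <- v / area
  }
  if (noise == "poisson") {
    mx <- max(v)
    if (mx > 0) {
      v <- with_seed(seed, rpois(length(v), scale * v / mx))
    }
  }
  structure(
    list(values = v,
         angle_deg = if (inherits(x, "sct_response")) x$angle_deg else NA_real_,
         noise_model = noise, scale = if (noise == "poisson") scale else NA_real_,
         seed = as.integer(seed)),
    class = "sct_buckets"
  )
}

#' @export
print.sct_buckets <- function(x, ...) {
  cat(sprintf("<sct_buckets> %d readings, noise %s, angle %.4g deg\n",
              length(x$values), x$noise_model, x$angle_deg))
  invisible(x)
}

#' Total photon budget of a simulation campaign
#'
#' Bookkeeping helper for transport-style simulations run as repeated
#' independent realizations: total primaries = realizations x primaries
#' per realization (e.g. 2000 x 1e6 = 2e9).
#'
#' @param n_realizations number of independent runs.
#' @param primaries_per_run primary particles per run.
#' @return total number of primary particles.
#' @export
photon_budget <- function(n_realizations, primaries_per_run) {
  if (n_realizations < 0 || primaries_per_run < 0) {
    sct_stop("invalid_argument", "counts must be non-negative")
  }
  as.double(n_realizations) * as.double(primaries_per_run)
}
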