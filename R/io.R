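# File interfaces: multi-page TIFF for images/stacks/volumes with JSON
# sidecars carrying physical metadata, CSV for bucket series and FRC
# curves. TIFF pages are stored as 32-bit values normalised to [0, 1];
# the sidecar records the original value range so reads are lossless
# up to float precision. The sidecar also states the flattening
# convention (column-major) and offset base (1-based) used throughout.

#' @noRd
sidecar_path <- function(path) paste0(path, ".json")

#' @noRd
write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' @noRd
read_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

# normalise pages to [0,1] for TIFF storage; returns list(pages, lo, hi)
#' @noRd
norm_pages <- function(pages) {
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  if (hi == lo) hi <- lo + 1
  list(pages = lapply(pages, function(p) (p - lo) / (hi - lo)), lo = lo, hi = hi)
}

#' Write / read a mask as TIFF + JSON sidecar
#'
#' @param mask an `sct_mask`.
#' @param path output TIFF path; a sidecar `<path>.json` records
#'   `pitch_um`, `seed` and `duty`.
#' @return `path`, invisibly (write); an `sct_mask` (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sct_mask"))
  tiff::writeTIFF(mask$grid * 1.0, path, bits.per.sample = 8L)
  write_sidecar(path, list(type = "mask", pitch_um = mask$pitch_um,
                           seed = mask$seed, duty = mask$duty,
                           flattening = "column-major", offset_base = 1))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- read_sidecar(path)
  g <- tiff::readTIFF(path)
  structure(list(grid = round(g), pitch_um = meta$pitch_um,
                 seed = meta$seed %||% NA_integer_, duty = meta$duty %||% 0.5),
            class = "sct_mask")
}

#' Write / read a pattern stack as multi-page TIFF + JSON sidecar
#'
#' One page per pattern; the sidecar records `pitch_um`, offsets,
#' pattern shape, sampling rate and the flattening convention.
#'
#' @param patterns an `sct_patterns`.
#' @param path output TIFF path.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "sct_patterns"))
  h <- patterns$pattern_shape[1]; w <- patterns$pattern_shape[2]
  pages <- lapply(seq_len(nrow(patterns$values)), function(k) {
    matrix(patterns$values[k, ], h, w)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  write_sidecar(path, list(type = "patterns", pitch_um = patterns$pitch_um,
                           pattern_shape = patterns$pattern_shape,
                           offsets = patterns$offsets,
                           sampling_rate = patterns$sampling_rate,
                           flattening = "column-major", offset_base = 1,
                           seed = patterns$seed))
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  values <- do.call(rbind, lapply(pages, function(p) as.numeric(round(p))))
  off <- matrix(as.integer(unlist(meta$offsets)), ncol = 2)
  dimnames(off) <- list(NULL, c("row", "col"))
  structure(list(values = values,
                 pattern_shape = as.integer(meta$pattern_shape),
                 pitch_um = meta$pitch_um, offsets = off,
                 sampling_rate = nrow(values) / ncol(values),
                 flattening = "column-major",
                 seed = meta$seed %||% NA_integer_),
            class = "sct_patterns")
}

#' Write / read a phantom as multi-page float TIFF + JSON sidecar
#'
#' Pages 1..nz hold `mu` slices, pages nz+1..2nz hold `rho_e` slices,
#' normalised to `[0, 1]`; the sidecar stores the value ranges,
#' `voxel_mm` and seed so the round trip is lossless to float
#' precision.
#'
#' @param phantom an `sct_phantom`.
#' @param path output TIFF path.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "sct_phantom"))
  d <- dim(phantom$mu)
  pages <- c(lapply(seq_len(d[3]), function(k) phantom$mu[, , k]),
             lapply(seq_len(d[3]), function(k) phantom$rho_e[, , k]))
  np <- norm_pages(pages)
  tiff::writeTIFF(np$pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(type = "phantom", dim = d, voxel_mm = phantom$voxel_mm,
                           value_lo = np$lo, value_hi = np$hi,
                           seed = phantom$seed,
                           hole_top_um = phantom$hole_top_um,
                           hole_bottom_um = phantom$hole_bottom_um))
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  pages <- lapply(pages, function(p) p * (meta$value_hi - meta$value_lo) + meta$value_lo)
  mu <- array(0, d); rho <- array(0, d)
  for (k in seq_len(d[3])) {
    mu[, , k] <- pages[[k]]
    rho[, , k] <- pages[[d[3] + k]]
  }
  structure(list(mu = mu, rho_e = rho, voxel_mm = meta$voxel_mm,
                 seed = meta$seed %||% NA_integer_,
                 hole_top_um = meta$hole_top_um %||% NA_real_,
                 hole_bottom_um = meta$hole_bottom_um %||% NA_real_),
            class = "sct_phantom")
}

#' Write / read bucket series as CSV + JSON sidecar
#'
#' CSV columns `pattern_index`, `value`; the sidecar records the
#' projection angle, noise model and seed.
#'
#' @param buckets an `sct_buckets`.
#' @param path output CSV path.
#' @export
write_buckets <- function(buckets, path) {
  stopifnot(inherits(buckets, "sct_buckets"))
  write.csv(data.frame(pattern_index = seq_along(buckets$values),
                       value = buckets$values),
            path, row.names = FALSE)
  write_sidecar(path, list(type = "buckets", angle_deg = buckets$angle_deg,
                           noise_model = buckets$noise_model,
                           scale = buckets$scale, seed = buckets$seed))
  invisible(path)
}

#' @rdname write_buckets
#' @export
read_buckets <- function(path) {
  meta <- read_sidecar(path)
  df <- read.csv(path)
  structure(list(values = df$value, angle_deg = meta$angle_deg %||% NA_real_,
                 noise_model = meta$noise_model %||% "none",
                 scale = meta$scale %||% NA_real_,
                 seed = meta$seed %||% NA_integer_),
            class = "sct_buckets")
}

#' Write / read a reconstruction as float TIFF + JSON sidecar
#'
#' @param recon an `sct_recon`.
#' @param path output TIFF path.
#' @export
write_recon <- function(recon, path) {
  stopifnot(inherits(recon, "sct_recon"))
  np <- norm_pages(list(recon$image))
  tiff::writeTIFF(np$pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(type = "reconstruction", method = recon$method,
                           value_lo = np$lo, value_hi = np$hi,
                           final_loss = tail(recon$loss_history, 1)))
  invisible(path)
}

#' @rdname write_recon
#' @export
read_recon <- function(path) {
  meta <- read_sidecar(path)
  p <- tiff::readTIFF(path, all = TRUE)
  if (is.list(p)) p <- p[[1]]
  img <- p * (meta$value_hi - meta$value_lo) + meta$value_lo
  new_reconstruction(img, meta$final_loss %||% NA_real_, meta$method %||% "unknown")
}

#' Write / read a volume as multi-page float TIFF + JSON sidecar
#'
#' One page per z slice, values normalised to `[0, 1]` with the range
#' in the sidecar together with `voxel_um`.
#'
#' @param vol an `sct_volume`.
#' @param path output TIFF path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "sct_volume"))
  d <- dim(vol$values)
  np <- norm_pages(lapply(seq_len(d[3]), function(k) vol$values[, , k]))
  tiff::writeTIFF(np$pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(type = "volume", dim = d, voxel_um = vol$voxel_um,
                           value_lo = np$lo, value_hi = np$hi))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  v <- array(0, d)
  for (k in seq_len(d[3])) {
    v[, , k] <- pages[[k]] * (meta$value_hi - meta$value_lo) + meta$value_lo
  }
  volume(v, meta$voxel_um)
}

#' Write an FRC curve as CSV
#'
#' Columns `freq_per_um`, `frc`, `halfbit`, `n_per_ring`.
#'
#' @param curve an `sct_frc`.
#' @param path output CSV path.
#' @export
write_frc <- function(curve, path) {
  write.csv(data.frame(freq_per_um = curve$freqs, frc = curve$frc,
                       halfbit = curve$halfbit, n_per_ring = curve$n_per_ring),
            path, row.names = FALSE)
  invisible(path)
}

#' Export volume slices as PNG images
#'
#' Writes one greyscale PNG per slice along the chosen axis (requires
#' the `png` package).
#'
#' @param vol an `sct_volume`.
#' @param axis `"z"` (top-to-bottom tomograms) or `"y"`
#'   (front-to-back).
#' @param dir output directory, created if needed.
#' @return the written file paths, invisibly.
#' @export
export_slices <- function(vol, axis = c("z", "y"), dir) {
  stopifnot(inherits(vol, "sct_volume"))
  axis <- match.arg(axis)
  if (!requireNamespace("png", quietly = TRUE)) {
    sct_stop("missing_dependency", "the png package is required for slice export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- vol$values
  rng <- range(v); if (diff(rng) == 0) rng[2] <- rng[1] + 1
  n <- if (axis == "z") dim(v)[3] else dim(v)[2]
  paths <- character(n)
  for (k in seq_len(n)) {
    sl <- if (axis == "z") v[, , k] else v[, k, ]
    paths[k] <- file.path(dir, sprintf("slice_%s_%03d.png", axis, k))
    png::writePNG((sl - rng[1]) / (rng[2] - rng[1]), paths[k])
  }
  invisible(paths)
}
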