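# Fourier ring correlation and image-quality metrics.

#' Half-bit information threshold
#'
#' Threshold curve for Fourier ring correlation corresponding to an
#' information content of half a bit per Fourier sample in a ring of
#' `n` samples: `(0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))`.
#' Strictly decreasing in `n`, in `(0, 1]` for `n >= 1`.
#'
#' @param n_per_ring sample counts per ring (>= 1).
#' @return threshold values.
#' @export
halfbit_threshold <- function(n_per_ring) {
  if (any(n_per_ring < 1)) sct_stop("invalid_argument", "n_per_ring must be >= 1")
  (0.2071 + 1.9102 / sqrt(n_per_ring)) / (1.2071 + 0.9102 / sqrt(n_per_ring))
}

#' Fourier ring correlation of two images
#'
#' Normalised cross-correlation of the two images' Fourier transforms
#' over rings of equal spatial frequency:
#' `FRC(r) = Re(sum F1 * conj(F2)) / sqrt(sum |F1|^2 * sum |F2|^2)`.
#' The real part (not the magnitude) of the cross-spectrum is used in
#' the numerator. The DC ring is excluded; rings are 1 pixel wide by
#' default with frequencies at ring centres, the last ring at Nyquist
#' `1 / (2 * pixel_um)`. Rings with zero power in either image get
#' `frc = 0` and are flagged.
#'
#' @param image1,image2 numeric matrices of identical shape, at least
#'   16 x 16.
#' @param pixel_um pixel size in um.
#' @param ring_width_px ring width in pixels (default 1).
#' @return an `sct_frc` with `freqs` (um^-1), `frc`, `halfbit`,
#'   `n_per_ring`, `zero_power` flags and `pixel_um`.
#' @export
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' fr <- frc_curve(img, img, pixel_um = 100)
#' range(fr$frc)
frc_curve <- function(image1, image2, pixel_um, ring_width_px = 1L) {
  image1 <- as.matrix(image1); image2 <- as.matrix(image2)
  if (!identical(dim(image1), dim(image2))) {
    sct_stop("invalid_argument", "images must share one shape")
  }
  if (any(dim(image1) < 16)) {
    sct_stop("invalid_argument", "images must be at least 16 x 16")
  }
  assert_pos(pixel_um, "pixel_um")
  nr <- nrow(image1); nc <- ncol(image1)
  F1 <- fft(image1); F2 <- fft(image2)
  # centred integer frequency indices
  fr_ <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr)
  fc_ <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc)
  rad <- sqrt(outer(fr_^2, fc_^2, `+`))
  n_half <- floor(min(nr, nc) / 2)
  w <- as.integer(ring_width_px)
  ring_of <- pmin(ceiling(rad / w), n_half %/% w + 1L)
  ring_of[rad == 0] <- 0L     # DC excluded
  n_rings <- n_half %/% w
  rvec <- as.integer(ring_of)
  sel <- rvec >= 1L & rvec <= n_rings
  cr <- Re(F1 * Conj(F2))[sel]
  p1 <- (Mod(F1)^2)[sel]; p2 <- (Mod(F2)^2)[sel]
  rs <- rvec[sel]
  agg <- rowsum(cbind(cr, p1, p2, 1), rs)
  ridx <- as.integer(rownames(agg))
  cross <- num1 <- num2 <- cnt <- numeric(n_rings)
  cross[ridx] <- agg[, 1]; num1[ridx] <- agg[, 2]
  num2[ridx] <- agg[, 3]; cnt[ridx] <- agg[, 4]
  zero_power <- num1 == 0 | num2 == 0
  frc <- numeric(n_rings)
  ok <- !zero_power
  frc[ok] <- cross[ok] / sqrt(num1[ok] * num2[ok])
  # ring r covers radii ((r-1)w, rw]; frequency reported at the outer
  # edge rw so the last ring sits exactly at Nyquist
  freqs <- (seq_len(n_rings) * w) / (min(nr, nc) * pixel_um)
  structure(
    list(freqs = freqs, frc = frc, halfbit = halfbit_threshold(pmax(cnt, 1)),
         n_per_ring = cnt, zero_power = zero_power, pixel_um = pixel_um),
    class = "sct_frc"
  )
}

#' @export
print.sct_frc <- function(x, ...) {
  cat(sprintf("<sct_frc> %d rings up to %.4g um^-1\n",
              length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Cutoff frequency of an FRC curve
#'
#' Frequency of the first crossing where the FRC drops below the
#' half-bit threshold, linearly interpolated between adjacent rings.
#' If the curve never crosses, the Nyquist frequency is returned with
#' `no_crossing = TRUE`.
#'
#' @param curve an `sct_frc`, or a list with `freqs`, `frc`, `halfbit`.
#' @return list with `frequency_per_um` and `no_crossing`.
#' @export
#' @examples
#' cutoff_frequency(list(freqs = c(0.001, 0.002, 0.003),
#'                       frc = c(0.9, 0.8, 0.3), halfbit = rep(0.5, 3)))
cutoff_frequency <- function(curve) {
  f <- curve$freqs; frc <- curve$frc; hb <- curve$halfbit
  if (length(f) == 0) sct_stop("invalid_argument", "empty FRC curve")
  d <- frc - hb
  if (d[1] < 0) return(list(frequency_per_um = f[1], no_crossing = FALSE))
  for (k in seq_len(length(d) - 1)) {
    if (d[k] >= 0 && d[k + 1] < 0) {
      t <- d[k] / (d[k] - d[k + 1])
      return(list(frequency_per_um = f[k] + t * (f[k + 1] - f[k]),
                  no_crossing = FALSE))
    }
    if (d[k + 1] == 0) {
      return(list(frequency_per_um = f[k + 1], no_crossing = FALSE))
    }
  }
  list(frequency_per_um = tail(f, 1), no_crossing = TRUE)
}

#' Spatial resolution from an FRC cutoff frequency
#'
#' Converts a cutoff frequency to a spatial resolution length via
#' `1 / (2 * f_c)`: a cutoff of 0.001 um^-1 corresponds to 500 um.
#'
#' @param f_c cutoff frequency in um^-1 (> 0).
#' @return resolution in um.
#' @export
#' @examples
#' resolution_from_cutoff(0.001)
resolution_from_cutoff <- function(f_c) {
  if (!is.numeric(f_c) || any(f_c <= 0)) {
    sct_stop("invalid_argument", "cutoff frequency must be > 0")
  }
  1 / (2 * f_c)
}

#' Standard image-quality metrics
#'
#' Pearson correlation, root-mean-square error and peak
#' signal-to-noise ratio (relative to the truth's dynamic range) of a
#' reconstruction against a reference. A perfect reconstruction has
#' infinite PSNR, reported as the capped sentinel 200 dB.
#'
#' @param recon,truth numeric arrays of identical shape; `truth` must
#'   be non-constant.
#' @return list with `pearson`, `rmse`, `psnr`.
#' @export
image_metrics <- function(recon, truth) {
  if (!identical(dim(recon) %||% length(recon), dim(truth) %||% length(truth))) {
    sct_stop("invalid_argument", "shapes differ")
  }
  r <- as.numeric(recon); t_ <- as.numeric(truth)
  if (sd(t_) == 0) sct_stop("degenerate_input", "constant truth: pearson undefined")
  rmse <- sqrt(mean((r - t_)^2))
  rng <- diff(range(t_))
  psnr <- if (rmse == 0) 200 else min(200, 20 * log10(rng / rmse))
  list(pearson = cor(r, t_), rmse = rmse, psnr = psnr)
}
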