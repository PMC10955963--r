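#' Generate a random binary transmission mask
#'
#' The physical mask is a large binary transmission map: each pixel
#' either transmits (1) or absorbs (0) the beam. Pixels are i.i.d.
#' Bernoulli(`duty`); the experimental design uses a 1:1
#' transmission-absorption ratio, i.e. `duty = 0.5`.
#'
#' @param height_px,width_px mask dimensions in pixels (>= 1).
#' @param pitch_um physical pixel pitch in micrometres (> 0). The
#'   reference mask is 1480 x 1480 pixels over 160 mm, i.e. a pitch of
#'   about 108 um.
#' @param duty transmitting fraction in (0, 1]; default 0.5.
#' @param seed integer RNG seed; the mask is bit-reproducible for a
#'   fixed seed.
#' @return an object of class `sct_mask` with fields `grid` (0/1 integer
#'   matrix, `height_px` x `width_px`), `pitch_um` and `seed`.
#' @export
#' @examples
#' m <- generate_mask(64, 64, pitch_um = 108.1, seed = 1)
#' mean(m$grid)
generate_mask <- function(height_px, width_px, pitch_um, duty = 0.5, seed = 0L) {
  if (!is.numeric(height_px) || !is.numeric(width_px) ||
      height_px < 1 || width_px < 1 ||
      height_px != round(height_px) || width_px != round(width_px)) {
    sct_stop("invalid_argument", "mask dimensions must be positive integers")
  }
  assert_pos(pitch_um, "pitch_um")
  if (!is.numeric(duty) || duty <= 0 || duty > 1) {
    sct_stop("invalid_argument", "duty must lie in (0, 1]")
  }
  height_px <- as.integer(height_px); width_px <- as.integer(width_px)
  grid <- with_seed(seed, {
    matrix(rbinom(height_px * width_px, 1L, duty), height_px, width_px)
  })
  structure(
    list(grid = grid, pitch_um = pitch_um, seed = as.integer(seed),
         duty = duty),
    class = "sct_mask"
  )
}

#' @export
print.sct_mask <- function(x, ...) {
  cat(sprintf("<sct_mask> %d x %d px, pitch %.3g um, duty %.3g, seed %d\n",
              nrow(x$grid), ncol(x$grid), x$pitch_um, mean(x$grid), x$seed))
  invisible(x)
}

#' Extract illumination patterns from a mask
#'
#' The experiment translates one large pre-characterised mask between
#' exposures; each stop presents a different window of the mask to the
#' object. This function emulates that by cutting `n_patterns` windows
#' of size `pattern_shape` out of the mask and stacking their flattened
#' pixels as the rows of the measurement matrix `A`.
#'
#' Flattening is column-major (R native); offsets are 1-based
#' `(row, col)` positions of the window's top-left pixel and are
#' recorded in the result so every row can be re-read from the mask.
#'
#' @param mask an `sct_mask`.
#' @param n_patterns number of patterns (rows of `A`).
#' @param pattern_shape integer `(height, width)` of each window.
#' @param offsets optional list/matrix of explicit 1-based
#'   `(row, col)` offsets; overrides `strategy`.
#' @param strategy `"random-shift"` (offsets drawn without replacement
#'   from all valid positions, seeded) or `"tile"` (non-overlapping
#'   raster tiles).
#' @param seed RNG seed for `"random-shift"`.
#' @return an object of class `sct_patterns` with fields `values`
#'   (`m x n` 0/1 matrix), `pattern_shape`, `pitch_um`, `offsets`
#'   (`m x 2` matrix) and `sampling_rate`.
#' @export
#' @examples
#' m <- generate_mask(64, 64, 100, seed = 1)
#' A <- extract_patterns(m, 10, c(16, 16), seed = 2)
#' dim(A$values)
extract_patterns <- function(mask, n_patterns, pattern_shape,
                             offsets = NULL, strategy = c("random-shift", "tile"),
                             seed = 0L) {
  stopifnot(inherits(mask, "sct_mask"))
  strategy <- match.arg(strategy)
  h <- as.integer(pattern_shape[1]); w <- as.integer(pattern_shape[2])
  H <- nrow(mask$grid); W <- ncol(mask$grid)
  if (h < 1 || w < 1) sct_stop("invalid_argument", "pattern_shape must be positive")
  if (h > H || w > W) {
    sct_stop("out_of_bounds", "pattern window %dx%d exceeds mask %dx%d", h, w, H, W)
  }
  if (!is.null(offsets)) {
    off <- matrix(as.integer(unlist(offsets)), ncol = 2, byrow = is.list(offsets))
    n_patterns <- nrow(off)
    if (any(off[, 1] < 1 | off[, 2] < 1 | off[, 1] + h - 1L > H | off[, 2] + w - 1L > W)) {
      sct_stop("out_of_bounds", "an offset places the window outside the mask")
    }
  } else if (strategy == "random-shift") {
    n_valid <- as.double(H - h + 1L) * as.double(W - w + 1L)
    if (n_patterns > n_valid) {
      sct_stop("capacity", "requested %d patterns but only %.0f unique offsets exist",
               n_patterns, n_valid)
    }
    ids <- with_seed(seed, sample.int(n_valid, n_patterns, replace = FALSE))
    off <- cbind((ids - 1L) %% (H - h + 1L) + 1L,
                 (ids - 1L) %/% (H - h + 1L) + 1L)
  } else { # tile
    nr <- H %/% h; nc <- W %/% w
    if (n_patterns > nr * nc) {
      sct_stop("capacity", "requested %d tiles but only %d fit", n_patterns, nr * nc)
    }
    grid_off <- expand.grid(row = (seq_len(nr) - 1L) * h + 1L,
                            col = (seq_len(nc) - 1L) * w + 1L)
    off <- as.matrix(grid_off[seq_len(n_patterns), , drop = FALSE])
  }
  if (n_patterns < 1) sct_stop("invalid_argument", "n_patterns must be >= 1")

  n <- h * w
  values <- matrix(0, nrow(off), n)
  g <- mask$grid
  for (k in seq_len(nrow(off))) {
    values[k, ] <- as.double(g[off[k, 1]:(off[k, 1] + h - 1L),
                               off[k, 2]:(off[k, 2] + w - 1L)])
  }
  dimnames(off) <- list(NULL, c("row", "col"))
  structure(
    list(values = values, pattern_shape = c(h, w), pitch_um = mask$pitch_um,
         offsets = off, sampling_rate = nrow(off) / n,
         flattening = "column-major", seed = as.integer(seed)),
    class = "sct_patterns"
  )
}

#' @export
print.sct_patterns <- function(x, ...) {
  cat(sprintf("<sct_patterns> %d patterns of %d x %d px (rate %.4g), pitch %.3g um\n",
              nrow(x$values), x$pattern_shape[1], x$pattern_shape[2],
              x$sampling_rate, x$pitch_um))
  invisible(x)
}

#' Sampling rate of a ghost-imaging measurement
#'
#' Number of illumination patterns divided by the number of
#' reconstructed pixels; below 1 the inverse problem `Ax = S` is
#' underdetermined. The reference acquisition uses 3468 patterns for a
#' 128 x 128 = 16384-pixel image, a rate of about 0.211.
#'
#' @param n_patterns number of patterns (>= 0).
#' @param n_pixels number of image pixels (>= 1).
#' @return `n_patterns / n_pixels`.
#' @export
#' @examples
#' sampling_rate(3468, 128 * 128)
sampling_rate <- function(n_patterns, n_pixels) {
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L || n_pixels < 1) {
    sct_stop("invalid_argument", "n_pixels must be >= 1")
  }
  if (!is.numeric(n_patterns) || n_patterns < 0) {
    sct_stop("invalid_argument", "n_patterns must be >= 0")
  }
  n_patterns / n_pixels
}

#' Autocorrelation width of a mask
#'
#' The finest feature the illumination can encode is set by the width
#' of the mask's spatial autocorrelation peak. Computes the
#' mean-subtracted autocorrelation along the horizontal axis through
#' the central peak, normalised to 1 at zero lag, and returns its full
#' width at half maximum in micrometres (linear interpolation between
#' integer lags).
#'
#' For masks up to 512 x 512 the lag sums are accumulated by direct
#' shifted products; larger masks use a row-wise FFT. The two
#' estimators agree to 1e-8 where both apply.
#'
#' @param mask an `sct_mask` with at least 2 pixels per axis.
#' @param max_lag_px largest horizontal lag examined (default 64 or the
#'   mask width - 1, whichever is smaller).
#' @return FWHM of the central autocorrelation peak, in um.
#' @export
#' @examples
#' m <- generate_mask(256, 256, pitch_um = 108, seed = 3)
#' autocorrelation_width(m)
autocorrelation_width <- function(mask, max_lag_px = 64L) {
  stopifnot(inherits(mask, "sct_mask"))
  g <- mask$grid
  if (nrow(g) < 2 || ncol(g) < 2) {
    sct_stop("invalid_argument", "mask must be at least 2x2")
  }
  g <- g - mean(g)
  if (sum(g * g) == 0) {
    sct_stop("degenerate_input", "constant mask has no autocorrelation peak")
  }
  max_lag <- min(as.integer(max_lag_px), ncol(g) - 1L)
  ac <- if (length(g) <= 512L * 512L) {
    acorr_direct_h(g, max_lag)
  } else {
    acorr_fft_h(g, max_lag)
  }
  ac <- ac / ac[1]
  # first crossing of 0.5 moving outward from lag 0
  half_lag <- NA_real_
  for (k in seq_len(max_lag)) {
    if (ac[k + 1] < 0.5) {
      half_lag <- (k - 1) + (ac[k] - 0.5) / (ac[k] - ac[k + 1])
      break
    }
  }
  if (is.na(half_lag)) {
    sct_stop("degenerate_input",
             "autocorrelation does not fall below half maximum within %d lags", max_lag)
  }
  2 * half_lag * mask$pitch_um
}

# horizontal-lag autocorrelation by direct shifted products
#' @noRd
acorr_direct_h <- function(g, max_lag) {
  W <- ncol(g)
  vapply(0:max_lag, function(dx) {
    sum(g[, seq_len(W - dx)] * g[, seq_len(W - dx) + dx])
  }, numeric(1))
}

# horizontal-lag autocorrelation via row-wise FFT (zero-padded, linear)
#' @noRd
acorr_fft_h <- function(g, max_lag) {
  W <- ncol(g)
  L <- 2^ceiling(log2(2 * W))
  gp <- matrix(0, nrow(g), L)
  gp[, seq_len(W)] <- g
  Fp <- t(apply(gp, 1, fft))
  P <- Fp * Conj(Fp)
  ac_rows <- t(apply(P, 1, function(r) Re(fft(r, inverse = TRUE)))) / L
  colSums(ac_rows)[seq_len(max_lag + 1L)]
}
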