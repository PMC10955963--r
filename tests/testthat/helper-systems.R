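# Shared fixtures, all generated in code.

# small measurement system with a known response
toy_system <- function(n_patterns, shape, seed = 1, mask_px = 128) {
  m <- generate_mask(mask_px, mask_px, 100, seed = seed)
  extract_patterns(m, n_patterns, shape, seed = seed + 1)
}

# piecewise-constant disk scene on an h x w grid
disk_scene <- function(h, w, r_frac = 1 / 3, lo = 0.3, hi = 1.3) {
  outer(seq_len(h), seq_len(w), function(i, j) {
    ifelse((i - h / 2)^2 + (j - w / 2)^2 < (r_frac * h)^2, hi, lo)
  })
}

# the standard seeded noisy benchmark: bone-phantom scatter response at
# 64 x 64, sampling rate 0.211, Poisson noise at 1e4 photons
bench_64 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_bone_phantom(c(64, 64, 64), 0.125, 2000, 1200, seed = 1)
      resp <- scatter_response_map(ph, scatter_geometry())
      m <- generate_mask(256, 256, 125, seed = 5)
      A <- extract_patterns(m, round(0.211 * 4096), c(64, 64), seed = 6)
      cache <<- list(A = A, resp = resp, x_true = resp$values)
    }
    cache
  }
})

# independent bilinear interpolation (used by brute-force ray oracles)
bilinear_at <- function(img, x, y) {
  n1 <- nrow(img); n2 <- ncol(img)
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  g <- function(i, j) if (i >= 1 && i <= n1 && j >= 1 && j <= n2) img[i, j] else 0
  g(i0, j0) * (1 - fx) * (1 - fy) + g(i0 + 1, j0) * fx * (1 - fy) +
    g(i0, j0 + 1) * (1 - fx) * fy + g(i0 + 1, j0 + 1) * fx * fy
}

pearson <- function(a, b) cor(as.numeric(a), as.numeric(b))

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)
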