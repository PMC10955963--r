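# End-to-end pipeline: config handling, seeds, the simulate ->
# reconstruct -> CT -> metrics chain, and canonical test fixtures.

#' Default pipeline configuration
#'
#' Two named presets are shipped. `"paper"` mirrors the reference
#' acquisition profile: 1480 x 1480 mask (108.1 um pitch, duty 0.5),
#' 128 x 128 patterns, 3468 samplings (rate 0.211), the 28-angle list,
#' untrained-network solver at learning rate 0.002, TV strength
#' `10^-3.9`, 1501 steps, and 500 SART iterations. `"desk"` is the
#' small profile used by the test-suite and examples: 32^3 phantom
#' (0.25 mm voxels), 128 x 128 mask, 32 x 32 patterns at the same
#' 0.211 sampling rate, 8 angles, 600 solver steps and 40 SART
#' iterations.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param master_seed integer master seed; every stochastic stage
#'   derives its own seed from it via [derive_seed()].
#' @param output_root output directory for [run_pipeline()].
#' @return a nested configuration list (class `sct_config`).
#' @export
default_config <- function(profile = c("desk", "paper"), master_seed = 1L,
                           output_root = tempfile("scatterct_run_")) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  n_px <- if (desk) 32L else 128L
  n_pat <- if (desk) round(0.211 * n_px^2) else 3468L
  cfg <- list(
    profile = profile,
    master_seed = as.integer(master_seed),
    output_root = output_root,
    mask = list(height_px = if (desk) 128L else 1480L,
                width_px = if (desk) 128L else 1480L,
                pitch_um = if (desk) 250 else 108.1, duty = 0.5),
    patterns = list(n_patterns = n_pat, pattern_shape = c(n_px, n_px),
                    strategy = "random-shift"),
    phantom = list(shape = if (desk) c(32L, 32L, 32L) else c(128L, 128L, 128L),
                   voxel_mm = 0.25, hole_top_um = 2000, hole_bottom_um = 1200,
                   mu_bone = 0.1, rho_bone = 1, texture = 0.05),
    geometry = list(photon_energy_keV = 60, detector_angle_deg = 90,
                    detector_distance_mm = 50),
    noise = list(model = "poisson", scale = 1e4),
    solver = list(method = "gidc", learning_rate = 0.002,
                  tv_strength = 10^-3.9,
                  n_steps = if (desk) 600L else 1501L),
    ct = list(n_iterations = if (desk) 40L else 500L, tv_lambda = 0.2,
              tv_iter = 10L, relaxation = 0.3, mode = "parallel"),
    angles = if (desk) paper_angle_list()[1:8] else "paper"
  )
  class(cfg) <- c("sct_config", "list")
  cfg
}

#' Load / save a pipeline configuration as YAML
#'
#' The round trip `load_config(save_config(cfg))` reproduces the
#' configuration exactly. The angle entry may be the keyword
#' `"paper"`, which expands to [paper_angle_list()] at run time.
#'
#' @param config an `sct_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  writeLines(yaml::as.yaml(unclass(config), precision = 22), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("sct_config", "list")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks presence and basic sanity of every block; signals a
#' `config_error` with the offending field on failure.
#'
#' @param config configuration list.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  need <- c("master_seed", "mask", "patterns", "phantom", "geometry",
            "noise", "solver", "ct", "angles", "output_root")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    sct_stop("config_error", "config is missing fields: %s",
             paste(missing, collapse = ", "))
  }
  ps <- config$patterns$pattern_shape
  if (config$patterns$n_patterns < 1) {
    sct_stop("config_error", "patterns.n_patterns must be >= 1")
  }
  if (length(ps) != 2 || any(ps < 2)) {
    sct_stop("config_error", "patterns.pattern_shape must be two values >= 2")
  }
  if (!identical(config$angles, "paper") && !is.numeric(config$angles)) {
    sct_stop("config_error", "angles must be numeric or the keyword 'paper'")
  }
  if (!config$noise$model %in% c("none", "poisson")) {
    sct_stop("config_error", "noise.model must be 'none' or 'poisson'")
  }
  if (!config$solver$method %in% c("gidc", "cgls", "pinv", "tvls")) {
    sct_stop("config_error", "solver.method must be gidc/cgls/pinv/tvls")
  }
  invisible(config)
}

#' Order-independent configuration hash
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation of
#' the configuration; semantically equal configs hash equal regardless
#' of key order.
#'
#' @param config configuration list.
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(unclass(config)), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
config_angles <- function(config) {
  if (identical(config$angles, "paper")) paper_angle_list() else as.numeric(config$angles)
}

# measure the hole dip width (full width at half depth) of a profile
# across the hole centre in one z slice of a volume; axis 1 profiles
# along x at the hole's y, axis 2 along y at the hole's x
#' @noRd
dip_width_vox <- function(vol_values, z, hole_center, r_shell_vox, axis = 1L) {
  n <- dim(vol_values)[1]
  if (axis == 1L) {
    cy <- round(hole_center[2])
    prof <- vol_values[, cy, z]
    centre <- (n + 1) / 2
    hx <- hole_center[1]
  } else {
    cxr <- round(hole_center[1])
    prof <- vol_values[cxr, , z]
    centre <- hole_center[2]
    hx <- hole_center[2]
  }
  cx <- centre
  band <- which(abs(seq_len(n) - cx) <= r_shell_vox * 0.95)
  prof <- prof[band]
  xs <- band
  di <- which.min(abs(xs - hx))
  # search the actual minimum near the nominal hole centre
  near <- which(abs(xs - hx) <= max(3, r_shell_vox / 3))
  di <- near[which.min(prof[near])]
  baseline <- median(prof[abs(xs - xs[di]) > r_shell_vox / 2.5])
  depth <- baseline - prof[di]
  if (!is.finite(depth) || depth <= 0) return(NA_real_)
  level <- baseline - depth / 2
  # walk outward from the minimum to the half-depth crossings; if the
  # dip is truncated by the band edge, clamp there
  left <- di
  while (left > 1 && prof[left] < level) left <- left - 1
  right <- di
  while (right < length(prof) && prof[right] < level) right <- right + 1
  xl <- if (left == di) {
    xs[di] - 0.5
  } else if (prof[left] < level) {
    xs[left]
  } else {
    xs[left] + (level - prof[left]) / (prof[left + 1] - prof[left])
  }
  xr <- if (right == di) {
    xs[di] + 0.5
  } else if (prof[right] < level) {
    xs[right]
  } else {
    xs[right] - (level - prof[right]) / (prof[right - 1] - prof[right])
  }
  xr - xl
}

#' Measured hole taper of a reconstructed volume
#'
#' Measures the full width at half depth of the hole's intensity dip
#' near the top and bottom of the volume, using the known hole
#' position of the phantom the volume reconstructs. Each end's width
#' is the median over `n_slices` tomogram slices and both transverse
#' profile directions, which keeps the estimate stable against
#' per-slice reconstruction noise.
#'
#' @param vol an `sct_volume`.
#' @param phantom the `sct_phantom` the volume was reconstructed from
#'   (provides the hole position and shell radius).
#' @param margin slices to skip at each end (default 2).
#' @param n_slices slices aggregated per end (default 3).
#' @return list with `top_um`, `bottom_um` widths.
#' @export
hole_taper_widths <- function(vol, phantom, margin = 2L, n_slices = 3L) {
  stopifnot(inherits(vol, "sct_volume"), inherits(phantom, "sct_phantom"))
  nz <- dim(vol$values)[3]
  end_width <- function(zs) {
    w <- c(vapply(zs, function(z) {
      dip_width_vox(vol$values, z, phantom$hole_center,
                    phantom$r_shell_vox, axis = 1L)
    }, numeric(1)),
    vapply(zs, function(z) {
      dip_width_vox(vol$values, z, phantom$hole_center,
                    phantom$r_shell_vox, axis = 2L)
    }, numeric(1)))
    median(w, na.rm = TRUE)
  }
  z_bot <- (1L + margin):min(nz, margin + n_slices)
  z_top <- max(1L, nz - margin - n_slices + 1L):(nz - margin)
  list(top_um = end_width(z_top) * vol$voxel_um,
       bottom_um = end_width(z_bot) * vol$voxel_um)
}

#' @noRd
solve_angle <- function(A, S, config, gidc_seed) {
  meth <- config$solver$method
  ps <- as.integer(config$patterns$pattern_shape)
  switch(meth,
    gidc = reconstruct_gidc(A, S, gidc_params(
      learning_rate = config$solver$learning_rate,
      tv_strength = config$solver$tv_strength,
      n_steps = config$solver$n_steps,
      image_shape = ps, seed = gidc_seed)),
    tvls = reconstruct_tv_least_squares(A, S, tau = config$solver$tv_strength,
                                        n_steps = config$solver$n_steps),
    cgls = reconstruct_linear(A, S, "cgls"),
    pinv = reconstruct_linear(A, S, "pinv"))
}

#' Run the full simulation-reconstruction pipeline
#'
#' Chains every stage from one configuration: mask and pattern
#' generation, phantom construction, per-angle scatter simulation and
#' bucket measurement, per-angle reconstruction (scatter) plus
#' transmission-negative projection, modality combination, SART-TV
#' volumes for all three modalities, an FRC resolution estimate from
#' two disjoint-pattern-subset reconstructions, and a JSON run report.
#' All randomness derives from `config$master_seed`, so a rerun with
#' the same config reproduces the report bit-for-bit (timings aside).
#'
#' @param config an `sct_config`, see [default_config()].
#' @param write_outputs write TIFF/CSV/JSON artefacts under
#'   `config$output_root` (default `TRUE`); the report is returned
#'   either way.
#' @return the run report, invisibly a list with per-stage seeds,
#'   metrics and timings.
#' @export
run_pipeline <- function(config = default_config(), write_outputs = TRUE) {
  validate_config(config)
  t_all <- proc.time()[3]
  report <- list(config_hash = config_hash(config),
                 profile = config$profile %||% "custom",
                 seeds = list(), metrics = list(), timings = list())
  out <- config$output_root
  if (write_outputs) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed

  stage <- "mask"
  res <- try({
    seed_mask <- derive_seed(ms, "mask")
    mask <- generate_mask(config$mask$height_px, config$mask$width_px,
                          config$mask$pitch_um, config$mask$duty, seed_mask)
    seed_pat <- derive_seed(ms, "patterns")
    A <- extract_patterns(mask, config$patterns$n_patterns,
                          config$patterns$pattern_shape,
                          strategy = config$patterns$strategy, seed = seed_pat)
    report$seeds$mask <- seed_mask
    report$seeds$patterns <- seed_pat
    if (write_outputs) write_patterns(A, file.path(out, "patterns.tif"))

    stage <- "phantom"
    seed_ph <- derive_seed(ms, "phantom")
    ph <- make_bone_phantom(config$phantom$shape, config$phantom$voxel_mm,
                            config$phantom$hole_top_um, config$phantom$hole_bottom_um,
                            config$phantom$mu_bone, config$phantom$rho_bone,
                            texture = config$phantom$texture, seed = seed_ph)
    report$seeds$phantom <- seed_ph
    if (write_outputs) write_phantom(ph, file.path(out, "phantom.tif"))

    stage <- "simulate"
    angles <- config_angles(config)
    t_sim <- proc.time()[3]
    scatter_imgs <- vector("list", length(angles))
    trans_imgs <- vector("list", length(angles))
    buckets <- vector("list", length(angles))
    per_angle_pearson <- numeric(length(angles))
    ps <- as.integer(config$patterns$pattern_shape)
    for (a in seq_along(angles)) {
      geom <- scatter_geometry(config$geometry$photon_energy_keV,
                               config$geometry$detector_angle_deg,
                               config$geometry$detector_distance_mm,
                               rotation_angle_deg = angles[a])
      resp <- scatter_response_map(ph, geom)
      xv <- resp$values
      if (!all(dim(xv) == ps)) {
        sct_stop("invalid_argument",
                 "response map %dx%d does not match pattern shape %dx%d",
                 nrow(xv), ncol(xv), ps[1], ps[2])
      }
      sb <- bucket_signals(A, resp, noise = config$noise$model,
                           scale = config$noise$scale,
                           seed = derive_seed(ms, "buckets", a))
      buckets[[a]] <- sb
      trans_imgs[[a]] <- transmission_projection(ph, angles[a])$values
      stage <- "reconstruct"
      rec <- solve_angle(A, sb, config, derive_seed(ms, "gidc", a))
      scatter_imgs[[a]] <- rec$image
      per_angle_pearson[a] <- cor(as.numeric(rec$image), as.numeric(xv))
      if (write_outputs) {
        write_buckets(sb, file.path(out, sprintf("buckets_%03d.csv", a)))
        write_recon(rec, file.path(out, sprintf("scatter_%03d.tif", a)))
      }
      stage <- "simulate"
    }
    report$timings$simulate_reconstruct_s <- proc.time()[3] - t_sim
    report$metrics$per_angle_pearson <- per_angle_pearson

    stage <- "ct"
    t_ct <- proc.time()[3]
    px_um <- config$phantom$voxel_mm * 1000
    sc_stack <- projection_stack(scatter_imgs, angles %% 360, "scatter", px_um)
    tn_stack <- projection_stack(lapply(trans_imgs, negative_transmission),
                                 angles %% 360, "transmission-negative", px_um)
    cb_stack <- combine_modalities(tn_stack, sc_stack)
    sp <- sart_params(config$ct$n_iterations, config$ct$tv_lambda,
                      config$ct$tv_iter, config$ct$mode, config$ct$relaxation)
    vols <- list(scatter = sart_tv(sc_stack, sp),
                 transmission_negative = sart_tv(tn_stack, sp),
                 combined = sart_tv(cb_stack, sp))
    report$timings$ct_s <- proc.time()[3] - t_ct
    if (write_outputs) {
      for (nm in names(vols)) {
        write_volume(vols[[nm]], file.path(out, sprintf("volume_%s.tif", nm)))
      }
    }

    stage <- "metrics"
    im <- image_metrics(vols$scatter$values, ph$rho_e)
    report$metrics$scatter_volume_pearson <- im$pearson
    report$metrics$scatter_volume_rmse <- im$rmse
    tw <- hole_taper_widths(vols$scatter, ph)
    report$metrics$hole_top_um <- tw$top_um
    report$metrics$hole_bottom_um <- tw$bottom_um

    # FRC from two disjoint pattern subsets at the first angle
    stage <- "frc"
    m <- nrow(A$values)
    half <- m %/% 2
    sub <- function(idx) {
      Ai <- A
      Ai$values <- A$values[idx, , drop = FALSE]
      Ai$offsets <- A$offsets[idx, , drop = FALSE]
      Ai$sampling_rate <- length(idx) / ncol(A$values)
      Si <- buckets[[1]]
      Si$values <- buckets[[1]]$values[idx]
      solve_angle(Ai, Si, config, derive_seed(ms, "frc", length(idx)))$image
    }
    if (min(ps) >= 16 && half >= 8) {
      r1 <- sub(seq_len(half))
      r2 <- sub((half + 1):m)
      fr <- frc_curve(r1, r2, pixel_um = px_um)
      co <- cutoff_frequency(fr)
      report$metrics$frc_cutoff_per_um <- co$frequency_per_um
      report$metrics$frc_resolution_um <- resolution_from_cutoff(co$frequency_per_um)
      report$metrics$frc_no_crossing <- co$no_crossing
      if (write_outputs) write_frc(fr, file.path(out, "frc.csv"))
    }
    report$timings$total_s <- proc.time()[3] - t_all
    report
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    sct_stop("stage_failure", "pipeline failed in stage '%s': %s",
             stage, attr(res, "condition")$message)
  }
  if (write_outputs) {
    rep_out <- res
    rep_out$timings <- NULL   # report file excludes wall-clock noise
    jsonlite::write_json(rep_out, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Write the canonical small test fixtures
#'
#' Generates the package's hand-checkable fixture set under `out_dir`:
#' a 16 x 16 toy mask, an 8^3 phantom, a 12-pattern / 16-pixel toy
#' system with its expected bucket values, and the worked FRC curve
#' used to illustrate cutoff interpolation. A manifest lists every
#' file with an MD5 content hash; regenerating with the same seed
#' reproduces identical hashes.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @return the manifest, invisibly (list of file = hash entries).
#' @export
make_fixtures <- function(out_dir, seed = 0L) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    sct_stop("io_error", "cannot create fixture directory %s", out_dir)
  }
  probe <- file.path(out_dir, ".write_probe")
  if (inherits(try(writeLines("x", probe), silent = TRUE), "try-error")) {
    sct_stop("io_error", "fixture directory %s is not writable", out_dir)
  }
  unlink(probe)

  mask <- generate_mask(16, 16, 100, seed = derive_seed(seed, "fixture_mask"))
  write_mask(mask, file.path(out_dir, "toy_mask.tif"))

  ph <- make_bone_phantom(c(8, 8, 8), 0.5, 2000, 1200, texture = 0,
                          seed = derive_seed(seed, "fixture_phantom"))
  write_phantom(ph, file.path(out_dir, "toy_phantom.tif"))

  A <- extract_patterns(mask, 12, c(4, 4),
                        seed = derive_seed(seed, "fixture_patterns"))
  write_patterns(A, file.path(out_dir, "toy_patterns.tif"))
  x <- matrix(seq(0, 1, length.out = 16), 4, 4)
  S <- bucket_signals(A, x)
  write_buckets(S, file.path(out_dir, "toy_buckets.csv"))
  write.csv(data.frame(pixel_index = 1:16, value = as.numeric(x)),
            file.path(out_dir, "toy_response.csv"), row.names = FALSE)

  write.csv(data.frame(freq_per_um = c(0.001, 0.002, 0.003),
                       frc = c(0.9, 0.8, 0.3), halfbit = rep(0.5, 3)),
            file.path(out_dir, "worked_frc.csv"), row.names = FALSE)

  files <- c("toy_mask.tif", "toy_mask.tif.json", "toy_phantom.tif",
             "toy_phantom.tif.json", "toy_patterns.tif",
             "toy_patterns.tif.json", "toy_buckets.csv",
             "toy_buckets.csv.json", "toy_response.csv", "worked_frc.csv")
  manifest <- lapply(files, function(f) {
    list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
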