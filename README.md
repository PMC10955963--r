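# scatterct

Simulation and reconstruction toolkit for **X-ray scatter computational
ghost imaging (CGI) tomography** — imaging an object's Compton-scatter
response with a single-pixel ("bucket") detector and known structured
illumination, then assembling per-angle scatter images into a 3D volume.

## The problem and the method

Conventional radiography resolves an image on a pixelated detector;
scattered photons are a nuisance that collimators throw away. Ghost
imaging inverts that logic: the *illumination* carries the spatial
information. A large binary mask (transmission-absorption ratio 1:1) is
stepped between exposures so each exposure illuminates the object with
a known random binary pattern. A spatially unresolved detector placed
off-axis (≈90° to the beam) records one scalar per pattern — the bucket
signal. Writing the flattened patterns as the rows of a measurement
matrix `A`, the object's scatter response map `x` satisfies

    A x = S,

where `S` is the vector of bucket readings. At sampling rates below 1
(fewer patterns than pixels; the reference profile uses 3468 patterns
for 128 × 128 = 16384 pixels, rate ≈ 0.211) the system is
underdetermined and is solved with regularisation:

* **Linear solvers** — minimum-norm least squares (`pinv`) and
  conjugate-gradient least squares (`cgls`), the exact baselines.
* **TV least squares** — monotone-FISTA minimisation of
  `|A x − S|² + τ·TV(x)` over pixels.
* **Untrained-network solver** (`gidc`) — the weights φ of a small,
  randomly initialised convolutional encoder–decoder `T_φ` are
  optimised so its output satisfies the measurement physics,

      φ* = argmin_φ |A T_φ(x₀) − S|² + τ·𝔗[T_φ(x₀)],

  with `x₀` the linear reconstruction fed as the network input and 𝔗
  the anisotropic total variation. No training data is involved: the
  network's spectral bias acts as the image prior (defaults: learning
  rate 0.002, τ = 10^−3.9, 1501 steps, 128 × 128).

The forward physics is a single-scatter analytic model: per beam pixel,
`Σ_k ρ_e · T_in · KN(θ) · T_out`, with Beer–Lambert attenuation along
the entry and exit paths and the Klein-Nishina differential cross
section `KN(θ) = ½ r_e² (λ/λ′)² [λ/λ′ + λ′/λ − sin²θ]` at the detector
angle. Per-angle images (scatter, transmission-negative, and their
normalized average) over a fixed 28-angle list are assembled into 3D
volumes with **SART-TV** under parallel-beam geometry, and resolution
is quantified by **Fourier ring correlation** against the half-bit
threshold, converting the cutoff frequency `f_c` to resolution
`1/(2 f_c)` (0.001 µm⁻¹ ↔ 500 µm).

## Worked example

```r
library(scatterct)

# phantom: bone cylinder with a conical hole tapering 2000 -> 1200 um
ph   <- make_bone_phantom(c(32, 32, 32), voxel_mm = 0.25, seed = 1)
geom <- scatter_geometry(photon_energy_keV = 60, detector_angle_deg = 90)
resp <- scatter_response_map(ph, geom)           # 32 x 32 response map

# illumination: windows of a large binary mask, sampling rate 0.211
mask <- generate_mask(128, 128, pitch_um = 250, seed = 2)
A    <- extract_patterns(mask, 216, c(32, 32), seed = 3)
S    <- bucket_signals(A, resp, noise = "poisson", scale = 1e4, seed = 4)

# recover the scatter image with the untrained-network solver
rec <- reconstruct_gidc(A, S, gidc_params(image_shape = c(32, 32),
                                          n_steps = 300, seed = 5))
cor(as.numeric(rec$image), as.numeric(resp$values))
#> [1] 0.9521631
```

The full chain (8 angles → per-angle reconstructions → SART-TV volumes
for scatter / transmission-negative / combined → FRC report) runs from
one config:

```r
rep <- run_pipeline(default_config("desk", master_seed = 1))
rep$metrics$scatter_volume_pearson   # 0.8309 (volume vs true scatter density)
rep$metrics$hole_top_um              # 1995   (measured top hole width, true 2000)
rep$metrics$hole_bottom_um           # 1551   (measured bottom width, true 1200)
rep$metrics$frc_resolution_um        # 1020   (two disjoint half-pattern subsets)
```

The volume correlates strongly with the true scatter density, and the
measured hole widths preserve the taper direction (top wider than
bottom) at the 250 µm voxel scale.

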