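---
title: "Methods: scatter computational ghost imaging and tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scatter computational ghost imaging and tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterct)
```

This vignette documents the models, numerical choices and known
limitations of **scatterct**. It states no empirical result beyond
what the package's test-suite and `scripts/acceptance.R` themselves
compute.

## 1. Measurement model

Computational ghost imaging replaces detector-side resolution with
illumination-side structure. A binary transmission mask — in the
reference geometry 1480 × 1480 pixels over 160 mm, i.e. a pitch of
about 108 µm, with a 1:1 transmission–absorption ratio — is translated
between exposures. `extract_patterns()` emulates this by cutting
windows out of one seeded mask, so patterns are correlated exactly the
way physically shifted windows are. Each flattened window forms one
row of the measurement matrix `A`, and a single-pixel detector
supplies one scalar per pattern:

$$A\,x = S ,$$

where `x` is the object's per-pixel response (scatter, here) and `S`
the bucket-signal vector. The finest feature the illumination encodes
is set by the mask autocorrelation; `autocorrelation_width()` reports
the FWHM of the mean-subtracted, peak-normalised horizontal
autocorrelation with linear interpolation between integer lags. For an
i.i.d. duty-0.5 mask this is delta-like (1–2 px). The estimator is a
deliberate, documented choice; other estimators (diagonal cuts,
algorithm-aware widths) give different numbers, and the package makes
no claim of equivalence to any externally quoted mask-resolution
length.

In-memory flattening is column-major with 1-based offsets — the native
R convention — and every file the package writes records this in its
JSON sidecar, so the layout is unambiguous to external readers.

## 2. Single-scatter forward physics

`scatter_response_map()` implements an analytic single-scatter
surrogate for full Monte-Carlo transport. For each transverse beam
pixel the response is

$$x(i,j) \;=\; \sum_k \rho_e \cdot T_{\mathrm{in}} \cdot
\mathrm{KN}(\theta) \cdot T_{\mathrm{out}},$$

with Beer–Lambert attenuation $T_{\mathrm{in}}$ accumulated along the
beam to each voxel, $T_{\mathrm{out}}$ along the straight exit ray
toward the detector (a midpoint-rule march at half-voxel steps,
nearest-voxel lookup), and the Klein-Nishina differential cross
section

$$\frac{d\sigma}{d\Omega} = \tfrac12 r_e^2
\left(\frac{\lambda}{\lambda'}\right)^2
\left[\frac{\lambda}{\lambda'} + \frac{\lambda'}{\lambda}
- \sin^2\theta\right],
\qquad \lambda' = \lambda + \lambda_C (1 - \cos\theta).$$

Choices and their reasons:

* **Monoenergetic beam, default 60 keV.** A polychromatic 80 kVp
  spectrum would require a spectrum model that is out of scope; the
  Klein-Nishina weight is evaluated at a single effective wavelength.
  60 keV is a reasonable effective energy for an 80 kVp tungsten tube,
  and it is a package default, not an externally fixed value.
* **Detector at 90°, 50 mm** by default, matching the experimental
  arrangement the method targets; the cross section at 90° is small,
  which is exactly the regime in which scatter imaging must work.
* **Neglected:** multiple scatter, coherent (Rayleigh) scattering,
  detector solid-angle variation across the object, fluorescence and
  detector energy response. These are the standard gaps between a
  single-scatter analytic model and Monte-Carlo transport; they bias
  absolute intensities but preserve the image-formation structure the
  reconstruction depends on.
* **Rotation** uses nearest-voxel resampling by default so projections
  are exactly reproducible and 0° ≡ 360°; trilinear resampling is
  available.

The phantom generator `make_bone_phantom()` builds the study object: a
cortical-shell cylinder (shell at full attenuation/density, trabecular
interior at 60 % with a 5 % seeded texture) drilled by a conical
through-hole tapering linearly between the requested end diameters,
2000 µm to 1200 µm by default, offset a third of the way to the rim.
Background voxels are empty. The defaults — 0.25 mm voxels, µ(bone) =
0.1 mm⁻¹ — describe a desk-scale bone specimen at diagnostic energies.
Poisson noise is parameterised by the expected photon count at the
brightest bucket (`scale`, default 10⁴), a single interpretable SNR
knob.

## 3. Inversion

All solvers share the differential-measurement preprocessing standard
in ghost imaging: the per-pixel means of `A` and the mean of `S` are
removed. Because the centred residual is orthogonal to the all-ones
vector, appending one scaled mean-row makes the centred problem
*exactly* equivalent to the raw least-squares problem while removing
the dominant common-mode singular value, so the linear solvers lose
nothing. For the regularised solvers the mean equation is appended at
unit weight instead — it then counts as one ordinary measurement and
cannot swamp the optimisation.

**Normalised solving units.** The regularised objective is the literal
sum of squared residuals plus the TV penalty,

$$\min \; \lVert A f - S\rVert^2 + \tau\,\mathrm{TV}(f),$$

evaluated with the bucket fluctuations scaled to unit maximum and the
image expressed in units of the linear reconstruction's maximum (the
operator is rescaled to keep the equation consistent). In these units
the data term at realistic noise levels and the TV term at τ = 10^−3.9
— the shipped default — are of the same order, which is what makes a
single dimensionless τ transferable across problem sizes and photon
budgets. The reference implementation's internal scaling is not
documented anywhere we could verify, so this normalisation is the
package's own, chosen by this dimensional argument and recorded here.

**TV solver.** Monotone FISTA (accepted iterates never increase the
objective) with a spectral step size from 30 power iterations and an
anisotropic-TV proximal step solved by 30 projected dual iterations.
Warm-started at the CGLS reconstruction, so the unregularised limit
reproduces the linear solution immediately.

**Untrained-network solver.** The network is a three-scale
convolutional encoder–decoder: 3×3 convolutions with 16 channels at
full, half and quarter resolution, leaky-ReLU activations, 2×2
mean-pool downsampling, sparse *bilinear* upsampling, one skip
connection at the half-resolution scale, and a zero-initialised 1×1
output projection. Design rationale:

* The output is synthesised entirely by the decoder — no passthrough
  of the input image — because the prior lives in the network's
  spectral bias: low-frequency structure is fitted first, so noise in
  the data is reproduced last. A residual path from the input would
  hand the noisy linear reconstruction straight to the output and
  disable the prior.
* Bilinear (not nearest-neighbour) upsampling biases the decoder
  toward smooth outputs; with nearest-neighbour upsampling the same
  optimisation visibly passes more pixel noise.
* The network input is the CGLS reconstruction scaled to unit maximum;
  it conditions the synthesis but does not set the output units.
* Optimisation is Adam at the default learning rate 0.002 with a
  50-step linear warm-up (Adam's first steps are unit-sized per
  parameter regardless of gradient magnitude) and cosine decay to 10 %
  (stabilises the late phase so the best iterate is a settled one).
  The returned image is the best-loss iterate, because untrained-prior
  optimisations degrade late; the loss history and best step index are
  recorded in the result.
* Gradients are computed analytically (im2col convolutions over BLAS);
  runs are bit-reproducible for a fixed seed, and the power-of-two
  image-shape restriction mirrors the decoder's fixed 4× scale
  pyramid.

`resize_to_pow2()` provides exact area-overlap resampling (total
intensity preserved to machine precision) for data acquired on
non-power-of-two grids, e.g. 184 × 163 → 128 × 128.

## 4. Tomography

`forward_project()` computes, per z-slice, *exact* line integrals of
the bilinear interpolant of the slice (per-cell Simpson quadrature,
which is exact for the piecewise-quadratic integrand), assembled as a
cached sparse matrix per angle. The backprojector is therefore exactly
the transpose, and the adjoint identity holds to machine precision —
which is what makes SART updates consistent. The projector's angle
convention is aligned with the phantom-rotation convention and tested
against it.

`sart_tv()` runs SART sweeps (angle-by-angle relaxed updates,
relaxation 0.3 by default — a common choice; the value is not
externally prescribed) interleaved with TV relaxation in the
ASD-POCS style: after each sweep, `tv_iter` normalised
gradient-descent steps on the smoothed anisotropic 3D TV
(ε = 10⁻⁸) whose total length is `tv_lambda` times the norm of that
sweep's SART update, followed by projection onto non-negativity. The
`tv_lambda`/`tv_iter` scaling is this package's own, defined so that
`tv_lambda` is a dimensionless fraction of the data-driven update; CT
toolboxes each scale these knobs differently and no numeric
equivalence with any external tool's values (e.g. settings quoted as
1000/1000 elsewhere) is claimed. Scatter projection stacks are fed to
the same parallel-beam reconstructor as attenuation-like projections;
this ignores the physical difference between scatter line integrals
and transmission line integrals, a simplification the combined
modality inherits.

The fixed 28-angle list (`paper_angle_list()`) interleaves coarse
bisection angles with fine asymmetric fill-ins; angle order affects
SART only weakly (tested < 1 % on noiseless data).
`combine_modalities()` maps each image's robust 1st–99th percentile
range to [0, 1] before averaging, so one modality's scale cannot
dominate; stacks are assumed pre-aligned.

## 5. Resolution metrics

`frc_curve()` correlates two independent reconstructions ring by ring
in Fourier space, using the real part of the cross-spectrum, 1-px
rings with the DC term excluded and frequencies at ring outer edges so
the last ring sits exactly at Nyquist. The threshold is the standard
half-bit information criterion
$(0.2071 + 1.9102/\sqrt{n})/(1.2071 + 0.9102/\sqrt{n})$. The cutoff is
the first FRC/half-bit crossing with linear interpolation, and
resolution is `1/(2 f_c)` — the convention under which a cutoff of
0.001 µm⁻¹ corresponds to 500 µm. The package computes 2D FRC on
tomogram slices; 3D Fourier shell correlation is out of scope. The
pipeline's FRC protocol reconstructs one angle twice from two disjoint
halves of the pattern set, which makes the two inputs' noise
independent by construction.

## 6. Pipeline, profiles and problem sizes

`run_pipeline()` chains mask → patterns → phantom → per-angle scatter
simulation and bucket measurement → per-angle reconstruction →
modality combination → SART-TV volumes → FRC report, with every
stochastic stage seeded deterministically from one master seed
(`derive_seed()`), so a rerun is bit-identical apart from timings.

Two presets are shipped. `"paper"` carries the reference acquisition
profile (1480² mask, 128² patterns, 3468 samplings, 28 angles, 1501
network steps, 500 SART iterations). `"desk"` is the profile the
test-suite and the acceptance script use: a 32³ phantom at 0.25 mm
voxels, 32 × 32 patterns at the same 0.211 sampling rate, 8 angles,
600 network steps and 40 SART iterations. The desk sizes were chosen
once as the smallest geometry in which every effect the package
models — undersampling, Poisson noise, self-attenuation, the tapered
hole, multi-angle assembly — is still clearly expressed; the package's
acceptance properties (volume correlation, taper direction, solver
ordering) are evaluated there. The response map of a 32³ phantom has 32 × 32
transverse pixels, so the desk profile uses 32 × 32 patterns, keeping
the simulation and reconstruction grids identical. The desk network
step count (600) sits where the untrained-network solver's best
iterate balances the two properties the pipeline is judged on: at a
few hundred steps the decoder has not yet resolved the narrow bottom
hole (the dip is at the blur limit even on noiseless data), while
beyond roughly a thousand steps late noise-fitting erodes the volume
correlation. The 1200 µm bottom hole spans under five 250 µm voxels,
so its measured width carries an uncertainty of a few hundred µm; the
taper *direction* is the robust observable.

## 7. What the synthetic data does and does not show

The generator emulates: a translated physical binary mask, Poisson
counting noise, single-scatter contrast with self-attenuation, a
two-material bone-like object with a measurable internal defect, and
the multi-angle acquisition geometry. It does **not** emulate:
polychromatic beam hardening, multiple scatter and detector
cross-talk, mask manufacturing defects and partial transmission,
detector energy response, geometric misalignment between modalities,
or electronic/ground-loop noise. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms under the
stated physics — not that an experimental system achieves any
particular image quality. Quantities an experiment would measure
(absolute resolution in µm, absolute scatter rates) depend on exactly
the effects listed above and are reported here only as properties of
the synthetic study conditions.

## 8. Degenerate inputs and numerical edges

* Constant masks have no autocorrelation peak → `degenerate_input`.
* All-zero measurement matrices → `degenerate_system`.
* Constant images cannot be contrast-inverted (`negative_transmission`)
  and have no defined Pearson correlation (`image_metrics`) → errors.
* Zero-power FRC rings get `frc = 0` and a flag rather than NaN.
* A non-finite network loss aborts with the last finite step reported.
* Poisson buckets with an all-zero noiseless signal are returned as
  zeros (the draw would be degenerate).
* `sart_tv` checks finiteness each sweep and clamps negatives at each
  iteration's end.

## 9. Known limitations

* The untrained-network solver's quality depends on its architecture;
  the shipped encoder–decoder is small by design (CPU-friendly,
  reproducible) and is a package choice, not a reproduction of any
  external network.
* The single-scatter model underestimates background in thick objects.
* The hole-width metric (`hole_taper_widths`) measures a half-depth
  width along one profile; at 250 µm voxels its discretisation error
  is of order one voxel, so it is used for the taper *direction* and
  coarse size, not sub-voxel metrology.
* Parallel-beam geometry only; cone-beam is out of scope.
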