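# fibralign

Quantification of fibrillar collagen matrix microstructure and 3D cell
motility from reflection-confocal images and cell-tracking tables.

Cells migrating through a 3D collagen matrix respond to the matrix's
microarchitecture — the size of the pores between fibers and the degree to
which fibers are locally aligned — at least as strongly as to its bulk
stiffness or protein density. `fibralign` is for labs that image collagen
gels by reflection confocal microscopy and track embedded cells by
timelapse: it turns a raw reflection image into a binary fiber mask, scores
the matrix with two bulk microstructure statistics, summarises cell
trajectories and protrusion events, and correlates matrix and motility
metrics across experimental conditions.

## What it computes

**Fiber segmentation.** The interference background of a reflection image
is estimated as a function of radial distance from the image center
(angular medians in 1 px bins, linearly interpolated) and removed by
flat-field normalization, `I_N = I_R · ⟨I_B⟩ / I_B`. Fibers are then
enhanced with an oriented filter bank: for each of 15 orientations θ a
5 × 5 mask holds a 1-px digital line through the center; the difference
between the line-masked Gaussian (sd 0.7) convolution and the line-masked
average convolution responds to linear structure along θ, and the enhanced
image `I_FEF` is the pixel-wise maximum over θ. Otsu thresholding gives the
binary fiber mask `I_BW`.

**Pore-size spectrum (granulometry).** The conjugate (pore) image is
opened with digital disks of increasing radius r; the retained area I(r)
counts pores wider than r, so P(r) = I(r) − I(r+1) is the area at radius r
and f(r) = P(r)/ΣP is the pore-size distribution, from which the mean pore
diameter follows in μm.

**Alignment index.** The angular distribution of Fourier power,
F_I(θ), is obtained by Radon-style line integrals of the centered DFT
magnitude. With C_xy the n × 2 matrix of points
(F_I(θ_i) cos θ_i, F_I(θ_i) sin θ_i), the eigenvalues λ₁ ≥ λ₂ of
C_xyᵀC_xy give the alignment index **α = 1 − λ₂/λ₁**: 0 for an isotropic
matrix, 1 for perfectly aligned fibers.

**Cell motility.** From trajectory tables: mean speed (step length per
sampling interval) and net invasion distance (maximum displacement from the
origin). From protrusion event tables: protrusion rate per 90 min, the
fraction of protrusions in eight 45° sectors about the initial anterior
axis, and the polarization index **(C₁ − C₂)/(C₁ + C₂)** contrasting
anteroposterior (sectors 1, 5) with lateral (sectors 3, 7) counts.

**Condition-level statistics.** Min-max normalization of condition means
and pairwise OLS regressions reporting slope, r² and the slope p-value.

A synthetic-data generator (fiber networks with tunable orientation
concentration, width, length and density; radial interference backgrounds
with speckle; persistent random walks; protrusion streams with tunable
axial bias) provides ground-truthed inputs for every stage, so the whole
pipeline is testable without microscope data.

## Worked example

```r
library(fibralign)

# a synthetic aligned fiber field with interference background
params <- fiber_field_params(image_size_px = 320, n_fibers = 220,
                             mean_length_px = 140, width_px = 3,
                             orientation_kappa = 8,
                             orientation_center_rad = pi/3,
                             fiber_intensity = 0.6, seed = 42)
bg <- background_params(center_intensity = 0.5, falloff_scale_px = 220,
                        floor_intensity = 0.05, speckle_sd = 0.05, seed = 42)
sim <- generate_fiber_image(params, bg)

report <- analyze_microstructure(sim$image, pixel_size_um = 0.2,
                                 max_radius_px = 20)
print(report)
#> <microstructure_report>
#>   alignment alpha: 0.6832
#>   mean pore diameter: 0.794 um (1.98 px radius)

# a persistent random walk and a polarized protrusion stream, 2 min sampling
tr <- generate_trajectory(walk_params(n_steps = 495, dt_min = 2,
                                      speed_um_per_min = 0.6,
                                      persistence = 0.7, seed = 42), "cell1")
pr <- generate_protrusion_stream(protrusion_stream_params(
  duration_min = 720, rate_per_90min = 4, axial_bias = 0.8, seed = 42),
  "cell1")
print(motility_summary(tr, pr))
#> <motility_summary 'cell1'>
#>   speed: 0.6 um/min, net invasion: 154 um
#>   protrusions/90min: 4.88, C1 = 31, C2 = 2, polarization = 0.879
```

The strongly concentrated orientation distribution (kappa = 8) yields a
high alignment index; the recovered speed equals the generator's ground
truth exactly because steps are noise-free; and a protrusion stream with
80% axial bias produces a polarization index near 0.9.

`run_pipeline()` chains the stages over file inputs and writes CSV/JSON
results plus a manifest that allows a bit-identical rerun
(`rerun_from_manifest()`). A thin command-line front end with subcommands
`simulate`, `enhance`, `pores`, `alignment`, `motility`, `correlate` and
`run` is installed under `exec/fibralign`.

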