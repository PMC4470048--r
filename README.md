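# cardioflow4d

Quantification of intracardiac blood flow from whole-heart 4D flow
cardiovascular MR (time-resolved, three-directional phase-contrast
velocity data), for researchers comparing acquisition variants — e.g.
respiratory-gated versus non-gated scans, or different coils — on
quantitative rather than visual grounds.

The package implements the full chain from stored velocities to
agreement statistics:

* **Preprocessing** — temporal phase unwrapping at the VENC
  (`v → v ± 2·VENC` wherever the jump to the temporal predecessor
  exceeds the VENC) and eddy-current background correction by
  subtracting a least-squares first-order spatial fit
  `c0 + c1x + c2y + c3z` of the time-averaged velocity in stationary
  tissue.
* **Particle tracing** — pathlines `dx/dt = v(x, t)` by fourth-order
  Runge–Kutta with a constant 5 ms step and linear space–time
  interpolation. One particle per end-diastolic LV voxel, each carrying
  the voxel volume; particles traced backward to end-systole ending
  basal of the mitral plane are **PT inflow**, particles traced forward
  ending basal of the aortic plane are **PT outflow**. With normal
  valves, inflow ≈ outflow.
* **Kinetic energy** — `KE(t) = Σ ½ m |v|²` over the segmented blood
  pool, `m = ρ · voxel volume`, ρ = 1060 kg/m³, reported in mJ with
  cycle mean and peak.
* **Vortex-ring volumetry** — finite-time Lyapunov exponent fields
  `FTLE = ln λ_max(FᵀF) / (2|T|)` from the flow map, whose ridges mark
  Lagrangian coherent structures; the ring is delineated in short-axis
  slices 4 mm apart and the volume is the summed slice volume.
* **Stroke volume** — through-plane flux `Φ(t) = Σ v·n · pixel area`
  over a vessel ROI, integrated over the cycle, on acquired 2D series
  and on planes resampled from the 4D data.
* **Agreement layer** — paired two-tailed Wilcoxon signed-rank (exact
  for n ≤ 25, ties handled), Pearson r/r², linear regression, and
  Bland–Altman bias ± SD with bias ± 1.96·SD limits of agreement.

No clinical datasets ship with the package. Instead, analytic phantom
generators (plug-flow tube, contracting ellipsoidal ventricle, Hill
spherical vortex, plus VENC-wrap/noise/background corruption) provide
ground truth known in closed form or by construction, and the test
suite validates every stage against them. See the methods vignette
(`vignettes/cardioflow4d-methods.Rmd`) for the models, assumptions and
design decisions.

## Worked example

Generate an 80 ml ventricle phantom at clinical settings (3 mm voxels,
40 phases, VENC 100 cm/s) and run the intracardiac measures:

```r
library(cardioflow4d)

ph <- make_contracting_ellipsoid(target_sv = 80, v_ed = 140)
ph$field
#> <velocity_field> 40 frames, grid 43 x 38 x 71 (x,y,z), spacing 3 x 3 x 3 mm
#>   timeframe 25 ms (cycle 1000 ms), VENC 100 cm/s, voxel 27 mm^3

pt_volumes(ph$field, ph$seg, ph$planes$mitral, ph$planes$aortic)
#> <pt_result> 5192 particles, seeded 140.2 ml
#>   inflow  80.0 ml (residual 60.2, left grid 0.0)
#>   outflow 80.0 ml (residual 60.2, left grid 0.0)

kinetic_energy_curve(ph$field, ph$seg)
#> <ke_curve> 40 frames: mean 0.948 mJ, peak 5.24 mJ (rho = 1060 kg/m^3)
```

The particle-trace inflow and outflow each recover the constructed
80 ml stroke volume (5192 seeded particles × 27 mm³ = 140.2 ml
end-diastolic volume; the residual 60.2 ml is the end-systolic blood
that never crosses a valve plane). The KE curve peaks during ejection
at 5.2 mJ — the magnitude expected for a healthy LV.

Stroke volume by flux on the tube phantom, from the 4D data:

```r
tube <- make_plug_tube()          # true SV = 91.2 ml in closed form
flux_2d(resample_plane_from_4d(tube$field, tube$roi), tube$roi)
#> <flux_series> 40 frames, SV 90.87 ml, peak flux 358.0 ml/s
```

i.e. within 0.4% of the analytic truth; the independently sampled 2D
path lands within 0.05% of the 4D path.

A two-condition study (clean vs noise-corrupted phantom), end to end:

```r
res <- run_pipeline(list(
  seed = 1, metrics = list("pt", "ke"),
  conditions = list(
    list(label = "clean", subject = "s1",
         phantom = list(kind = "contracting_ellipsoid")),
    list(label = "noisy", subject = "s1",
         phantom = list(kind = "contracting_ellipsoid"),
         corrupt = list(noise_sigma = 5, seed = 2)))))
res$metrics
```

A thin command-line launcher with the same capabilities
(`phantom`, `preprocess`, `intracardiac`, `vortex`, `sv`, `compare`,
`run`) is installed at `inst/cli/cardioflow4d`.

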