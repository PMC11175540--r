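# simbar

Similarity-driven motion-resolved reconstruction for free-running radial
cardiac MRI, in R.

Free-running whole-heart MRI acquires 3D radial k-space continuously —
no ECG triggering, no breath-holds — and sorts out cardiac and
respiratory motion afterwards. The similarity-driven approach clusters
the acquisition's superior–inferior (SI) self-gating projections by
similarity (PCA + k-means, with the cluster count `k` chosen to minimize
the mean point-to-centroid distance in the most populated cluster) and
reconstructs whole clusters of motion-consistent data. `simbar`
implements the full chain:

* **SIMBA** — density-compensated gridded reconstruction of the most
  populated cluster;
* **XD** — compressed sensing over the cluster dimension: the four most
  populated clusters `x^(i)` are reconstructed jointly, with a cyclic
  total-variation penalty linking them,

  ```
  argmin_x  Σᵢ ‖F⁽ⁱ⁾ C x⁽ⁱ⁾ − y⁽ⁱ⁾‖₂² + λ Σᵢ ‖x⁽ⁱ⁾ − x⁽ⁱ⁻¹⁾‖₁ ,   x⁽⁰⁾ = x⁽ᴷ⁾
  ```

* **XD-MC** — the same objective with non-rigid inter-cluster motion
  compensation, `‖T_{u⁽ⁱ⁾} x⁽ⁱ⁾ − x⁽ⁱ⁻¹⁾‖₁`, where the deformation
  `u⁽ⁱ⁾` registers cluster *i* onto cluster *i−1* and is estimated once
  from the gridded images. Clusters are ordered by population, so
  neighbors can sit in very different physiological states (systole next
  to diastole); the warp restores the sparsity the plain difference
  lacks.

Solved by ADMM with conjugate-gradient inner iterations (defaults:
λ = 0.3, K = 4, 40 ADMM × 3 CG). The package also provides the
supporting machinery — a golden-angle spiral-phyllotaxis trajectory
generator with interleaved SI readouts, Kaiser–Bessel gridding NUFFT
operators with exact adjoints, demons-type multiresolution registration,
a beating/breathing multi-coil numerical phantom for fully synthetic
end-to-end studies, image-quality metrics (blood–myocardium contrast
ratio, sigmoid-fit interface sharpness), an HDF5 raw-data container,
NIfTI output, and a YAML-driven pipeline (`run_pipeline()`, plus a thin
CLI at `inst/cli/simbar`).

## Worked example

Simulate a beating, breathing phantom acquisition, cluster it, and run
the motion-compensated reconstruction:

```r
library(simbar)

spec  <- phantom_spec(grid_size = 64, ndim = 2, cardiac_amplitude = 0.18,
                      resp_amplitude = 4, noise_sigma = 0.01,
                      motion_mode = "discrete", cardiac_levels = 2,
                      resp_levels = 3, resp_shape = "relaxed",
                      systole_width = 0.55)
traj  <- generate_trajectory(37, 4, 128, ndim = 2, include_si = TRUE, tr = 0.06)
coils <- make_coil_maps(64, ndim = 2, n_coils = 8, seed = 3)
kdata <- simulate_acquisition(spec, traj, coils, seed = 5)

assign <- cluster_with_selection(build_si_matrix(kdata), k_range = c(2, 6),
                                 seed = 9, readouts_per_interleave = 4)
assign
#> cluster_assignment: k = 6 (search scores: 2:3.24e+03, 3:3.24e+03, 4:1.74e+03, 5:1.74e+03, 6:1.74e+03)
#>   populations (desc): 60, 24, 20, 20, 16, 8

subsets <- assign_readouts(assign, traj, n_select = 4)
sens    <- estimate_sensitivities(coil_images_from_kdata(kdata, c(64, 64)))
simba   <- lapply(subsets, function(i) gridded_recon(kdata, i, sens, c(64, 64)))

ops <- lapply(subsets, function(i)
  nufft_operator(matrix(traj$coords[i, , ], length(i) * 128, 2), c(64, 64)))
ys  <- lapply(subsets, function(i)
  vapply(1:8, function(c) as.vector(kdata$samples[i, , c]), complex(length(i) * 128)))

fields <- estimate_cluster_deformations(simba)
xdmc   <- solve_xd(ys, ops, sens, fields = fields, cfg = recon_config())
xdmc
#> volume_series: K = 4 volumes on 64x64 grid; final objective 310.2 (data 276.5, L1 112.1)
```

The cluster search rejects under-segmentation (the score drops from
~3240 at k = 2–3 to ~1740 once the repeating motion states are isolated,
then plateaus; plateaus resolve to the largest k). The four selected
clusters hold 60/24/20/20 readouts — undersampled at roughly R ≈ 2–7 for
a 64² matrix — and the solver log reports the balanced data and L1 terms
at the solution. `select_output(xdmc, assign)` returns the volume in the
most populated cluster's motion state; on this phantom its NRMSE against
the rendered ground-truth state is ~0.075, versus ~0.13 for the gridded
SIMBA image and ~0.14 for the uncompensated XD reconstruction — motion
compensation is what lets the cluster dimension share data.

`run_pipeline(config, out_dir)` drives the same flow from a YAML config
and writes the HDF5 container, NIfTI volumes and fields, metrics CSV and
JSON logs.

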