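---
title: "Similarity-driven motion-resolved reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-driven motion-resolved reconstruction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Free-running whole-heart MRI acquires k-space continuously, without ECG
triggering or breath-holds, and defers all motion handling to
reconstruction. The acquisition is 3D radial: every readout is a diameter
through the k-space center, readout endpoints cover the sphere in a
spiral-phyllotaxis ("kooshball") pattern, and readouts are grouped into
short interleaves. Each interleave starts with a superior-inferior (SI)
readout along z whose 1D Fourier transform is a projection of the whole
body column — a self-gating signal sampled at the interleave rate (16 Hz
for the reference protocol of 22 readouts at TR = 2.84 ms).

`simbar` implements the similarity-driven reconstruction chain for such
data, plus a numerical phantom that emulates the acquisition so every
stage can be exercised and verified at desk scale (2D, 48–96 voxel grids)
without scanner data.

## Similarity-driven binning (SIMBA)

The SI projections (all coils concatenated, one complex column per
interleave, each feature row mean-centered) are reduced by PCA; the real
part of the projected scores is clustered with k-means. For every
candidate cluster count $k$ in a search range (10–14 for the whole-heart
protocol), the quality score is the mean Euclidean distance between the
most populated cluster's points and its centroid,
$\frac{1}{|C|}\sum_{\hat s \in C}\lVert \mu_k - \hat s\rVert_2$, and the
selected $k$ minimizes it. Whole interleaves inherit their SI readout's
label, so every cluster is a set of interleaves acquired in a consistent
motion state.

Implementation choices the protocol leaves open, fixed here as follows:

* **PCA dimension** — smallest number of components explaining ≥ 95% of
  the variance, capped at 10 (scale-free and reproducible; configurable).
* **k-means** — k-means++ seeding, 10 restarts, Lloyd iterations, fixed
  recorded seed; each candidate $k$ runs under seed + $k$.
* **Plateau resolution** — the selection score only sees the most
  populated cluster. On data whose states repeat exactly, the score is
  *identical* for every $k$ that isolates that cluster, so a plain argmin
  degenerates to the smallest candidate. `cluster_with_selection`
  therefore resolves score plateaus (relative tolerance `tie_tol = 1e-6`)
  to the **largest** plateau member: finer binning costs nothing in the
  selected cluster's compactness, and the criterion saturates toward the
  top of the search range on real data as well.
* **Coil combination** — per-coil concatenation by default (richer
  signal); magnitude root-sum-of-squares available.

## Reconstruction models

Let $F^{(i)}$ be the NUFFT sampling cluster $i$'s k-space coordinates,
$C$ the coil sensitivities (one set, applied identically for all
clusters), $y^{(i)}$ the cluster's k-space data, and $x^{(i)}$ its image.

**Gridded (SIMBA) reconstruction.** Density compensation, adjoint NUFFT
per coil, coil combination
$\sum_c \bar C_c\, F^\dagger(w\, y_c)\,/\,\mathrm{RSS}(C)^2$. Applied to
the most populated cluster this is the classic single-cluster image.

**Motion-resolved CS (XD).** The four most populated clusters, ordered by
population and treated cyclically ($x^{(0)} = x^{(K)}$), become a
dynamic dimension:
$$\hat x = \arg\min_x \sum_{i=1}^{K}\lVert F^{(i)} C x^{(i)} -
y^{(i)}\rVert_2^2 + \lambda \sum_{i=1}^{K}\lVert x^{(i)} -
x^{(i-1)}\rVert_1 .$$

**Motion-compensated CS (XD-MC).** Cluster order is population rank, not
physiological order, so adjacent clusters can sit in very different
states (a systolic cluster next to diastolic ones). Non-rigid deformation
fields $u^{(i)}$, estimated once between gridded images of adjacent
clusters and frozen, restore sparsity:
$$\hat x = \arg\min_x \sum_{i=1}^{K}\lVert F^{(i)} C x^{(i)} -
y^{(i)}\rVert_2^2 + \lambda \sum_{i=1}^{K}\lVert T_{u^{(i)}} x^{(i)} -
x^{(i-1)}\rVert_1 ,$$
where $T_u$ is the linear pull-back warp. In both cases the reported
image is the one in the most populated cluster's motion state.

### Solver

ADMM with conjugate-gradient x-updates: default 40 outer iterations with
3 CG steps each, $\lambda = 0.3$, $K = 4$. The z-update is complex
magnitude soft-thresholding (threshold $\lambda/\rho$); the penalty
$\rho$ defaults to $\lambda$ (standard heuristic, stable on all test
problems). CG is warm-started from the previous iterate; the
initialization is the per-cluster density-compensated gridded
reconstruction. $T^\dagger$ is the exact transpose of the frozen warp
(interpolation-weight scatter), never approximated by $T(-u)$.

Two scaling conventions make $\lambda = 0.3$ meaningful across problem
sizes, both active by default:

1. the data term is evaluated with the forward operator scaled by
   $1/\sqrt{N_{\mathrm{vox}}}$ (approximately unitary), so data and L1
   terms live on comparable scales regardless of grid size;
2. the data are normalized so the initial gridded series has unit peak
   magnitude.

Without these, the regularization weight is numerically irrelevant on
$64^2$-and-larger grids. On the phantom experiments this convention
reproduces the expected behavior of the three reconstructions: the
uncompensated XD image degrades where inter-cluster motion is large,
and XD-MC recovers it (see the acceptance script's NRMSE triplet).

Divergence (objective exceeding 10x its initial value) and NaNs abort
with the convergence log preserved; per-iteration objective, data, L1
and primal-feasibility terms are always logged.

## NUFFT

Kaiser-Bessel gridding with 2x oversampling and a width-8 kernel
(Beatty's $\beta$), closed-form deapodization, centered-DFT convention
$s(k) = \sum_r x(r)\,e^{-2\pi i k\cdot r}$ with $r$ centered at
$\lfloor N/2\rfloor$ and $k \in [-0.5, 0.5)$ cycles/FOV. Kernel support
tables are precomputed per operator, so repeated applications inside CG
cost one FFT plus a table-driven gather/scatter. Width 8 gives ~1e-7
agreement with the direct DFT sum; the adjoint is the exact conjugate
transpose of the implemented chain, so adjoint tests hold to machine
precision by construction.

**Density compensation** is the analytic ramp $|k|^{d-1}$ (zero-radius
samples take the first nonzero ring's weight). Normalization is the unit
DC-gain condition — a constant image rounds trip to itself — which makes
gridded reconstruction of dense acquisitions amplitude-correct for
smooth content; an impulse, whose spectrum extends beyond the sampled
ball, rounds trip to the band-coverage fraction (π/4 in 2D) instead.
`gridded_recon` uses an iterative refinement (repeated division by the
kernel-convolved sampling density) that corrects the ramp's
low-frequency shading for finite spoke counts; the plain ramp remains
the `density_weights` default. Against an exact polygon-clipping Voronoi
oracle, ramp weights match cell areas essentially exactly for
uniform-angle spokes, and per-ring averages for golden-angle spokes;
individual golden-angle cells deviate by ~20% (the three-gap structure
of the golden angle), which is why the refinement exists.

**Coil sensitivities** are estimated by a simplified smoothing estimator:
low-resolution per-coil images (density-compensated, Gaussian-weighted
k-space) are smoothed and divided by their root-sum-of-squares; RSS = 1
on the support, background filled from nearest supported voxels. Unit
tests also run with ground-truth maps to decouple reconstruction errors
from calibration errors.

## Registration

`estimate_deformation` is a self-contained multiresolution demons-type
scheme on magnitude images: SSD-driven update
$-e\,\nabla J/(\lVert\nabla J\rVert^2 + e^2)$, Gaussian regularization of
the field (σ = 1.5 voxels), 3 levels, and an iteration cap of 300 per
level (the protocol default). The best field seen — including the zero
field — is returned, so registration can never increase the residual.
The planned B-spline free-form alternative was set aside: no installed
package provides non-rigid registration, and the demons scheme meets
every numeric contract (translations ≤ 3 voxels recovered with mean
endpoint error < 0.5 voxel; smooth 3-voxel warps < 1 voxel) with far
less machinery. NMI-driven objectives were likewise unnecessary: the
synthetic images share contrast by construction, and histogram-based
metrics are noisy on desk-scale images.

The deformation convention is pull-back, `warp(x, u)(r) = x(r + u(r))`,
applied to real and imaginary parts independently; `u[[i]]` registers
cluster *i* onto cluster *i − 1* with the cyclic pair (1, K) included —
exactly the operator's role in the motion-compensated objective. Fields
are estimated once from gridded images and frozen during CS iterations.

## The synthetic acquisition

The phantom is a 2D/3D set of soft-edged ellipsoids (bright blood pool,
myocardial shell, liver, static lung, body) with affine-per-structure
motion, so ground-truth states and deformations exist in closed form:

* **cardiac** — heart semi-axes scaled by $1 - a_c\,w(t)$, $w$ a
  raised-cosine systolic pulse occupying `systole_width` (default 1/3)
  of the cycle; default amplitude $a_c = 0.15$, period 0.83 s;
* **respiratory** — heart + liver translated along SI by
  $a_r\,s(t)$; $s$ is a sinusoid or a "relaxed" squared-raised-cosine
  with an end-expiratory dwell; default $a_r = 2$ voxels, period 3.7 s;
* **discrete mode** — both waveforms quantized to a few levels, giving
  exactly repeating states with unequal dwell times and planted labels
  (the regime where clustered reconstruction is exact); an optional
  jitter term (residual continuous SI translation, default off) emulates
  the intra-cluster motion real clusters retain;
* **coils** — smooth Gaussian lobes around the FOV with low-order phase;
  **noise** — i.i.d. complex Gaussian per sample and coil, std relative
  to peak signal; all randomness seeded.

Motion is frozen within an interleave (matching the clustering
granularity), and SI readouts are stored as 1D projections exactly as
the reconstruction consumes them.

What the phantom does *not* emulate: through-plane motion, non-rigid
myocardial strain (structures move affinely), coil correlation,
relaxation/contrast kinetics, trajectory errors, or arrhythmia. Passing
tests therefore demonstrate correctness of the chain and the expected
*ordering* of reconstruction quality under controlled motion — not
clinical image quality.

### Study problem sizes

Tests and the acceptance script use 2D 64² grids with 8 coils:
clustering recovery on 240 interleaves x 4 readouts with 2x2 planted
states (SI-projection SNR ≈ 19); the end-to-end comparison on 37
interleaves x 4 readouts with 2x3 states and a widened systolic pulse
(`systole_width = 0.55`), which puts a systolic cluster among the four
most populated and the selected clusters at undersampling factors
R ≈ 2.2–6.7. The reference protocol's cluster-size percentages belong to
a 6-minute scan and are not reproducible in a seconds-long desk
acquisition; the undersampling factor is the quantity that controls the
reconstruction regime, so it is what the desk study matches.

## Image-quality metrics

* **Contrast ratio** — (blood − myocardium)/myocardium over label-map
  ROIs, eroded by one voxel to exclude partial-volume boundary voxels.
* **Interface sharpness** — least-squares fit of
  $s(t) = L + (U - L)/(1 + e^{-a(t - t_0)})$ along a user-chosen profile
  (sampled at 4x voxel density by linear interpolation); the sharpness is
  $|a|$ per unit position, invariant to affine intensity rescaling.
  Initialization from plateau means and the midpoint crossing; flat or
  non-fittable profiles return NaN with an explicit flag. Sharpness
  values depend on the position normalization and are comparable only
  within one convention.

## Known limitations

* Intra-cluster motion is not corrected (fields are inter-cluster only).
* The registration is SSD-driven; data with strong inter-cluster
  contrast differences would need the metric replaced.
* The phyllotaxis polar law is the equal-area spiral (uniform endpoint
  density, golden-angle azimuth); published interleaved implementations
  differ in detail, and only the uniformity contract is claimed.
* 2D mode exists for desk-scale testing; all operators are
  dimension-agnostic, but 3D runs at meaningful matrix sizes are slow in
  plain R + FFT.
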