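test_that("static phantom renders identically at all times", {
  sp <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 0)
  a <- render_phantom(sp, 0)
  b <- render_phantom(sp, 1.7)
  expect_identical(a$image, b$image)
  expect_setequal(setdiff(unique(as.vector(a$labels)), ""),
                  c("background", "lung", "liver", "myocardium", "blood"))
})

test_that("respiratory translation matches an FFT-shift oracle", {
  # isolate the moving structures so the whole image shifts rigidly
  ell <- list(
    list(center = c(32, 30), semiaxes = c(12, 10), value = 1.2 + 0i,
         label = "liver"),
    list(center = c(32, 30), semiaxes = c(6, 5), value = 2.4 + 0i,
         label = "blood"))
  sp <- phantom_spec(64, 2, ellipsoids = ell, cardiac_amplitude = 0,
                     resp_amplitude = 2, resp_shape = "sin")
  t_shift <- sp$resp_period / 4  # sin peak: translation exactly +2 voxels
  v0 <- render_phantom(sp, 0)$image
  v1 <- render_phantom(sp, t_shift)$image
  # shift v0 by +2 voxels along the SI axis with an FFT phase ramp
  kz <- simbar:::centered_axis(64) / 64
  ramp <- exp(-2i * pi * kz * 2)
  shifted <- simbar:::cdft_adj(simbar:::cdft(v0) *
                                 matrix(ramp, 64, 64, byrow = TRUE)) / 64^2
  expect_lt(nrmse(shifted, v1), 0.02)
})

test_that("systolic contraction scales the blood-pool volume as (1-a)^ndim", {
  amp <- 0.2
  sp <- phantom_spec(48, 3, cardiac_amplitude = amp, resp_amplitude = 0)
  # peak systole: w = 1 at one sixth of the cardiac period
  t_sys <- sp$cardiac_period / 6
  expect_equal(simbar:::cardiac_weight(t_sys, sp$cardiac_period), 1)
  v_dia <- sum(render_phantom(sp, 0)$labels == "blood")
  v_sys <- sum(render_phantom(sp, t_sys)$labels == "blood")
  expect_equal(v_sys / v_dia, (1 - amp)^3, tolerance = 0.02)
})

test_that("phantoms that leave the grid are rejected at construction", {
  ell <- list(list(center = c(60, 32), semiaxes = c(8, 8),
                   value = 1 + 0i, label = "liver"))
  expect_error(phantom_spec(64, 2, ellipsoids = ell, resp_amplitude = 10),
               "leaves the grid")
  expect_error(phantom_spec(64, 2, cardiac_period = 5, resp_period = 4),
               "physiology")
})

test_that("coil maps are smooth, deterministic and cover the support", {
  c1 <- make_coil_maps(64, 2, 8, seed = 4)
  c2 <- make_coil_maps(64, 2, 8, seed = 4)
  expect_identical(c1$maps, c2$maps)
  r <- simbar:::rss(c1$maps)
  expect_true(all(r > 0))
  expect_equal(make_coil_maps(32, 2, 1)$maps,
               array(1 + 0i, dim = c(32, 32, 1)))
})

test_that("k-space of a single-voxel impulse obeys the Fourier model", {
  ell <- list(list(center = c(20, 25), semiaxes = c(0.5, 0.5),
                   value = 1 + 0i, label = "blood"))
  sp <- phantom_spec(48, 2, ellipsoids = ell, cardiac_amplitude = 0,
                     resp_amplitude = 0, noise_sigma = 0)
  img <- render_phantom(sp, 0)$image
  expect_equal(sum(abs(img) > 1e-9), 1)
  traj <- generate_trajectory(6, 2, 32, ndim = 2, include_si = TRUE,
                              tr = 0.01)
  coils <- make_coil_maps(48, 2, 4, seed = 2)
  kd <- simulate_acquisition(sp, traj, coils, seed = 1)
  vox <- which(abs(img) > 1e-9, arr.ind = TRUE)[1, ]
  r0 <- vox - 1 - floor(48 / 2)
  for (c in c(1, 4)) {
    cmag <- abs(coils$maps[vox[1], vox[2], c] * img[vox[1], vox[2]])
    expect_equal(abs(kd$samples[, , c]), array(cmag, dim(kd$samples)[1:2]),
                 tolerance = 1e-6)
    # phase linear in k.r: compare against the model directly
    co <- matrix(kd$traj$coords[2, , ], ncol = 2)
    model <- coils$maps[vox[1], vox[2], c] * img[vox[1], vox[2]] *
      exp(-2i * pi * as.vector(co %*% r0))
    expect_equal(kd$samples[2, , c], model, tolerance = 1e-6)
  }
})

test_that("SI projections are static for a static phantom and oscillate at
           the respiratory frequency for a breathing one", {
  sp0 <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 0,
                      noise_sigma = 0)
  traj <- generate_trajectory(32, 4, 64, ndim = 2, include_si = TRUE,
                              tr = 0.03)
  coils <- make_coil_maps(48, 2, 2, seed = 2)
  kd0 <- simulate_acquisition(sp0, traj, coils, seed = 1)
  p <- kd0$si_projections[, , 1]
  expect_lt(max(abs(p - p[, 1])), 1e-10)

  sp1 <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 3,
                      noise_sigma = 0, resp_period = 1.6, resp_shape = "sin")
  kd1 <- simulate_acquisition(sp1, traj, coils, seed = 1)
  sig <- colSums(abs(kd1$si_projections[, , 1]) *
                   seq_len(64))  # center of mass over z
  sig <- sig - mean(sig)
  n_si <- length(sig)
  dt <- 4 * 0.03  # one SI per interleave
  spec <- Mod(fft(sig))[2:floor(n_si / 2)]
  f <- (seq_along(spec)) / (n_si * dt)
  expect_lt(abs(f[which.max(spec)] - 1 / sp1$resp_period),
            1.01 / (n_si * dt))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  sp <- phantom_spec(48, 2, noise_sigma = 0.01)
  traj <- generate_trajectory(6, 4, 64, ndim = 2, include_si = TRUE,
                              tr = 0.02)
  coils <- make_coil_maps(48, 2, 3, seed = 2)
  k1 <- simulate_acquisition(sp, traj, coils, seed = 9)
  k2 <- simulate_acquisition(sp, traj, coils, seed = 9)
  expect_identical(k1$samples, k2$samples)
  k3 <- simulate_acquisition(sp, traj, coils, seed = 10)
  expect_false(identical(k1$samples, k3$samples))
})
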