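test_that("forward NUFFT matches the direct DFT sum", {
  set.seed(21)
  for (dims in list(c(8, 8), c(8, 8, 8), c(16, 16, 16), c(9, 7))) {
    x <- array(rand_cplx(prod(dims)), dim = dims)
    co <- matrix(runif(30 * length(dims), -0.5, 0.4999), 30)
    op <- nufft_operator(co, dims)
    s <- nufft_forward(op, x)
    s0 <- direct_ndft(x, co)
    expect_lt(max(abs(s - s0)) / max(abs(s0)), 1e-6)
  }
})

test_that("a centered unit impulse transforms to unit samples", {
  co <- matrix(runif(80, -0.5, 0.4999), 40, 2)
  op <- nufft_operator(co, c(12, 12))
  e <- array(0i, c(12, 12))
  e[7, 7] <- 1  # 0-based (6,6) = floor(12/2)
  expect_lt(max(abs(nufft_forward(op, e) - 1)), 1e-6)
  # DC atom maps back to a constant image
  opdc <- nufft_operator(matrix(0, 1, 2), c(12, 12))
  img <- nufft_adjoint(opdc, 1 + 0i)
  expect_lt(max(abs(img - img[1, 1])) / abs(img[1, 1]), 1e-6)
})

test_that("forward is linear and the adjoint is exact", {
  set.seed(22)
  dims <- c(8, 8, 8)
  x <- array(rand_cplx(prod(dims)), dim = dims)
  co <- matrix(runif(150, -0.5, 0.4999), 50, 3)
  op <- nufft_operator(co, dims)
  expect_equal(nufft_forward(op, 2 * x), 2 * nufft_forward(op, x),
               tolerance = 1e-12)
  y <- rand_cplx(50)
  expect_lt(rel_ip_mismatch(nufft_forward(op, x), y, x,
                            nufft_adjoint(op, y)), 1e-6)
  expect_equal(nufft_adjoint(op, rep(0i, 50)),
               array(0i, dims))
  expect_error(nufft_operator(matrix(0.6, 1, 2), c(8, 8)), "0.5")
  expect_error(nufft_forward(op, array(0i, c(4, 4, 4))), "grid")
  expect_error(nufft_adjoint(op, rep(0i, 3)), "length")
})

test_that("density weights follow the |k|^(ndim-1) ramp", {
  co2 <- rbind(c(0.1, 0), c(0.2, 0))
  w2 <- density_weights(co2, 2)
  expect_equal(w2[2] / w2[1], 2)
  co3 <- rbind(c(0.1, 0, 0), c(0.2, 0, 0))
  w3 <- density_weights(co3, 3)
  expect_equal(w3[2] / w3[1], 4)
  # DC sample takes the first nonzero radius' weight
  w0 <- density_weights(rbind(c(0, 0), c(0.25, 0)), 2)
  expect_equal(w0[1], w0[2])
  expect_error(density_weights(matrix(numeric(0), 0, 2)), "empty")
})

test_that("analytic radial weights agree with Voronoi cell areas", {
  # uniform-angle spokes: every interior cell is the annular sector the
  # ramp models, so the agreement must be essentially exact
  th <- (0:127) * pi / 128
  radii <- ((0:15) - 7.5) / 16
  co_u <- do.call(rbind, lapply(1:128, function(i)
    outer(radii, c(cos(th[i]), sin(th[i])))))
  a_u <- voronoi_areas(co_u)
  r_u <- sqrt(rowSums(co_u^2))
  keep <- is.finite(a_u) & r_u < max(r_u) - 1e-9
  w_u <- density_weights(co_u, 2)
  ratio <- (w_u[keep] / median(w_u[keep])) /
    (a_u[keep] / median(a_u[keep]))
  expect_lt(median(abs(ratio - 1)), 0.1)
  expect_lt(max(abs(ratio - 1)), 1e-9)

  # golden-angle spokes: the three-gap azimuthal structure moves single
  # cells by ~20% around the ramp, but per-ring mean areas (what density
  # compensation weights model) still follow the ramp law
  traj <- generate_trajectory(128, 1, 16, ndim = 2)
  co <- simbar:::flatten_coords(traj, seq_len(128))
  w <- density_weights(co, 2)
  areas <- voronoi_areas(co)
  r <- round(sqrt(rowSums(co^2)), 9)
  keep <- is.finite(areas) & r < max(r) - 1e-9
  aw <- tapply(areas[keep], r[keep], mean)
  ww <- tapply(w[keep], r[keep], mean)
  ring_ratio <- (ww / median(ww)) / (aw / median(aw))
  expect_lt(median(abs(ring_ratio - 1)), 0.1)
})

test_that("normalized weights give amplitude-correct gridding of smooth
           content", {
  traj <- generate_trajectory(120, 1, 32, ndim = 2)
  co <- simbar:::flatten_coords(traj, seq_len(120))
  op <- nufft_operator(co, c(16, 16))
  w <- density_weights(co, 2, op)
  # unit DC gain: a constant image rounds trip to itself in the interior
  ones <- array(1 + 0i, c(16, 16))
  z <- nufft_adjoint(op, w * nufft_forward(op, ones))
  expect_equal(mean(Re(z[5:12, 5:12])), 1, tolerance = 1e-6)
  # the analytic (operator-free) normalization agrees within the ramp
  # model's accuracy
  w0 <- density_weights(co, 2)
  expect_equal(sum(w0), pi * max(sqrt(rowSums(co^2)))^2, tolerance = 1e-12)
  expect_equal(median(w / w0), 1, tolerance = 0.2)
})

test_that("sensitivity estimation recovers smooth maps up to phase", {
  sp <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 0,
                     noise_sigma = 0)
  img <- render_phantom(sp, 0)$image
  coils <- make_coil_maps(48, 2, 8, seed = 6)
  cimgs <- array(0i, c(48, 48, 8))
  for (c in 1:8) cimgs[, , c] <- coils$maps[, , c] * img
  est <- estimate_sensitivities(cimgs, smooth_sigma = 1)
  supp <- est$support
  # RSS of the returned maps is 1 on support
  expect_equal(max(abs(simbar:::rss(est$maps)[supp] - 1)), 0,
               tolerance = 1e-6)
  # maps match ground truth up to the common RSS normalization
  truth_n <- coils$maps / array(simbar:::rss(coils$maps), c(48, 48, 8))
  err <- vapply(1:8, function(c) {
    e <- est$maps[, , c][supp] - truth_n[, , c][supp]
    sqrt(mean(abs(e)^2)) / sqrt(mean(abs(truth_n[, , c][supp])^2))
  }, numeric(1))
  expect_lt(max(err), 0.1)
  # degenerate single uniform coil
  one <- estimate_sensitivities(array(img, c(48, 48, 1)))
  expect_equal(max(abs(abs(one$maps[, , 1][one$support]) - 1)), 0,
               tolerance = 1e-6)
  expect_error(estimate_sensitivities(array(0i, c(8, 8, 2))), "all-zero")
})

test_that("dense noiseless gridded reconstruction recovers the phantom", {
  sp <- phantom_spec(48, 2, cardiac_amplitude = 0, resp_amplitude = 0,
                     noise_sigma = 0)
  traj <- generate_trajectory(160, 1, 96, ndim = 2)  # ~2x Nyquist spokes
  coils <- make_coil_maps(48, 2, 4, seed = 6)
  kd <- simulate_acquisition(sp, traj, coils, seed = 1)
  truth <- render_phantom(sp, 0)$image
  rec <- gridded_recon(kd, seq_len(160), coils, c(48, 48))
  expect_lt(nrmse(rec, truth), 0.05)
  # linearity: all-zero k-space gives the zero image
  kd0 <- kd
  kd0$samples[] <- 0i
  expect_equal(gridded_recon(kd0, seq_len(160), coils, c(48, 48)),
               array(0i, c(48, 48)), tolerance = 1e-12)
  expect_error(gridded_recon(kd, integer(0), coils, c(48, 48)), "empty")
})

test_that("gridded quality degrades gracefully with less data", {
  acq <- planted_acquisition(120)
  a <- cluster_with_selection(build_si_matrix(acq$kdata), k_range = c(2, 4),
                              seed = 9, readouts_per_interleave = 4)
  subs <- assign_readouts(a, acq$traj, 4)
  sens <- coil_sens(acq$coils$maps /
                      array(simbar:::rss(acq$coils$maps), c(64, 64, 8)))
  big <- subs[[1]]
  rec_big <- gridded_recon(acq$kdata, big, sens, c(64, 64))
  set.seed(2)
  small <- sample(big, max(3, length(big) %/% 10))
  rec_small <- gridded_recon(acq$kdata, small, sens, c(64, 64))
  cid <- attr(subs, "cluster_ids")[1]
  mem <- which(a$labels == cid)
  truth <- render_phantom_state(acq$spec,
                                median(acq$kdata$truth$w[mem]),
                                median(acq$kdata$truth$shift[mem]))$image
  e_big <- nrmse(rec_big, truth)
  e_small <- nrmse(rec_small, truth)
  expect_true(is.finite(e_big) && is.finite(e_small))
  expect_lt(e_big, e_small)
})
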