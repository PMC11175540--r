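# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: direct DFT sums, explicit sparse
# operator matrices, polygon-clipped Voronoi areas, and a long-run
# primal-dual reference solver.

# Direct non-uniform DFT: s(k) = sum_r x(r) exp(-2i pi k.r), centered.
direct_ndft <- function(x, coords) {
  d <- dim(x)
  ax <- lapply(d, function(n) seq_len(n) - 1 - floor(n / 2))
  pts <- as.matrix(expand.grid(ax))
  xv <- as.vector(x)
  apply(coords, 1, function(k) sum(xv * exp(-2i * pi * as.vector(pts %*% k))))
}

# Dense matrix of the warp operator on a small grid, built corner by corner
# (independent bilinear bookkeeping).
warp_matrix <- function(u) {
  dm <- u$grid
  d <- length(dm)
  n <- prod(dm)
  A <- matrix(0, n, n)
  comp <- lapply(seq_len(d), function(a) {
    idx <- slice.index(u$displacement, d + 1)
    array(u$displacement[idx == a], dim = dm)
  })
  vox <- as.matrix(expand.grid(lapply(dm, function(m) 0:(m - 1))))
  for (v in seq_len(n)) {
    p <- vox[v, ] + vapply(comp, function(cc) cc[v], numeric(1))
    p <- pmin(pmax(p, 0), dm - 1)
    lo <- pmin(pmax(floor(p), 0), dm - 2)
    fr <- p - lo
    for (m in 0:(2^d - 1)) {
      w <- 1
      off <- 1
      mult <- 1
      for (a in seq_len(d)) {
        hi <- bitwAnd(bitwShiftR(m, a - 1), 1)
        w <- w * if (hi) fr[a] else 1 - fr[a]
        off <- off + (lo[a] + hi) * mult
        mult <- mult * dm[a]
      }
      A[v, off] <- A[v, off] + w
    }
  }
  A
}

# Exact 2D Voronoi cell areas by half-plane clipping of a bounding box,
# processing neighbors in ascending distance with security-radius
# termination: once half the neighbor distance exceeds the cell's
# circumradius, no further point can clip the cell, so the result is exact.
voronoi_areas <- function(pts, box = 0.55) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    poly <- matrix(c(-box, -box, box, -box, box, box, -box, box),
                   ncol = 2, byrow = TRUE)
    nb <- order(D[i, ])[-1]
    for (j in nb) {
      if (nrow(poly) < 3) break
      rmax <- sqrt(max(rowSums(sweep(poly, 2, pts[i, ])^2)))
      if (D[i, j] / 2 > rmax) break
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]
      keep <- (poly %*% nrm) <= sum(mid * nrm) + 1e-15
      # Sutherland-Hodgman clip against the half-plane
      out <- NULL
      np <- nrow(poly)
      for (e in seq_len(np)) {
        a <- poly[e, ]
        b <- poly[if (e == np) 1 else e + 1, ]
        ain <- keep[e]
        bin <- keep[if (e == np) 1 else e + 1]
        if (ain) out <- rbind(out, a)
        if (xor(ain, bin)) {
          t <- (sum(mid * nrm) - sum(a * nrm)) / sum((b - a) * nrm)
          out <- rbind(out, a + t * (b - a))
        }
      }
      poly <- if (is.null(out)) matrix(numeric(0), 0, 2) else out
    }
    if (nrow(poly) >= 3) {
      xx <- poly[, 1]; yy <- poly[, 2]
      areas[i] <- abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
    } else areas[i] <- NA_real_
  }
  areas
}

# Long-run Chambolle-Pock primal-dual reference for
#   min_x sum_i ||A_i x_i - y_i||^2 + lam ||D x||_1
# with A_i = masked unitary centered DFT and D the cyclic difference.
# Fully independent of the package ADMM path.
reference_pd_solve <- function(ys, masks, lam, n_iter = 10000) {
  K <- length(ys)
  len <- length(masks[[1]])
  cdft_u <- function(x) simbar:::cdft(array(x, len)) / sqrt(len)
  cdft_u_adj <- function(x) simbar:::cdft_adj(array(x, len)) / sqrt(len)
  Dm <- function(xl) lapply(seq_len(K), function(i)
    xl[[i]] - xl[[if (i == 1) K else i - 1]])
  Dt <- function(dl) lapply(seq_len(K), function(j)
    dl[[j]] - dl[[if (j == K) 1 else j + 1]])
  prox_G <- function(vl, t) lapply(seq_len(K), function(i) {
    vhat <- as.vector(cdft_u(vl[[i]]))
    yfull <- rep(0i, len)
    yfull[masks[[i]]] <- ys[[i]]
    xhat <- (2 * t * yfull + vhat) / (2 * t * as.numeric(masks[[i]]) + 1)
    as.vector(cdft_u_adj(xhat))
  })
  x <- lapply(seq_len(K), function(i) rep(0i, len))
  p <- x
  xb <- x
  t <- 0.25
  s <- 1 / (t * 4)  # ||D||^2 <= 4
  for (it in seq_len(n_iter)) {
    dp <- Dm(xb)
    p <- lapply(seq_len(K), function(i) {
      q <- p[[i]] + s * dp[[i]]
      q * pmin(1, lam / pmax(abs(q), 1e-300))
    })
    xold <- x
    tp <- Dt(p)
    x <- prox_G(lapply(seq_len(K), function(i) x[[i]] - t * tp[[i]]), t)
    xb <- lapply(seq_len(K), function(i) 2 * x[[i]] - xold[[i]])
  }
  x
}

toy_objective <- function(xl, ys, masks, lam) {
  K <- length(ys)
  len <- length(masks[[1]])
  dterm <- sum(vapply(seq_len(K), function(i) {
    s <- (simbar:::cdft(array(xl[[i]], len)) / sqrt(len))[masks[[i]]]
    sum(abs(s - ys[[i]])^2)
  }, numeric(1)))
  l1 <- sum(vapply(seq_len(K), function(i)
    sum(abs(xl[[i]] - xl[[if (i == 1) K else i - 1]])), numeric(1)))
  dterm + lam * l1
}

# Shared small planted acquisition (discrete 2x2 states), cached per session.
.fixture_env <- new.env(parent = emptyenv())
planted_acquisition <- function(n_interleaves = 120, noise_sigma = 0.004,
                                seed = 5) {
  key <- sprintf("acq_%d_%g_%d", n_interleaves, noise_sigma, seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- phantom_spec(64, 2, cardiac_amplitude = 0.15, resp_amplitude = 4,
                         noise_sigma = noise_sigma, motion_mode = "discrete",
                         cardiac_levels = 2, resp_levels = 2,
                         resp_shape = "relaxed", jitter_amplitude = 0.3)
    traj <- generate_trajectory(n_interleaves, 4, 128, ndim = 2,
                                include_si = TRUE, tr = 0.012)
    coils <- make_coil_maps(64, 2, 8, seed = 3)
    kdata <- simulate_acquisition(spec, traj, coils, seed = seed)
    .fixture_env[[key]] <- list(spec = spec, traj = traj, coils = coils,
                                kdata = kdata)
  }
  .fixture_env[[key]]
}

rand_cplx <- function(n, sd = 1) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

rel_ip_mismatch <- function(Ax, y, x, Aty) {
  abs(sum(Conj(Ax) * y) - sum(Conj(x) * Aty)) /
    (sqrt(sum(abs(Ax)^2)) * sqrt(sum(abs(y)^2)))
}
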