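# Numerical phantom of a beating, breathing torso section and the forward
# simulation of a free-running multi-coil radial acquisition.
#
# Motion model (affine per structure, so ground-truth deformations are known
# in closed form):
#  - heart (blood pool + myocardium): semi-axes scaled by
#    1 - cardiac_amplitude * w(t), where w is a raised-cosine systolic pulse
#    occupying one third of the cardiac period;
#  - heart + liver: translated along the SI axis (last axis) by
#    resp_amplitude * s(t), with s a sinusoid by default or a "relaxed"
#    waveform that dwells near end-expiration;
#  - lung and body are static, so the lung-liver interface moves with
#    respiration.
# A "discrete" motion mode quantizes both waveforms to a small number of
# levels, producing a set of exactly repeating motion states with unequal
# dwell times (the regime in which clustered reconstruction is exact); the
# planted state labels are kept as ground truth.

#' Specify a beating, breathing numerical phantom
#'
#' @param grid_size voxels per axis (scalar; isotropic grid).
#' @param ndim 2 or 3.
#' @param ellipsoids optional list of structures; each a list with fields
#'   \code{center} (voxels, t = 0), \code{semiaxes} (voxels), \code{value}
#'   (complex intensity) and \code{label} (one of blood, myocardium, liver,
#'   lung, background). Default: a body ellipse, a static lung, a breathing
#'   liver and a beating two-layer heart with bright (contrast-enhanced)
#'   blood pool.
#' @param cardiac_period,resp_period seconds; cardiac must be shorter
#'   (physiology).
#' @param cardiac_amplitude fractional systolic contraction of the heart
#'   semi-axes, in \code{[0, 1)}.
#' @param resp_amplitude SI translation of heart + liver, in voxels.
#' @param noise_sigma complex-Gaussian noise std, relative to the peak
#'   k-space signal magnitude.
#' @param motion_mode \code{"smooth"} (continuous waveforms) or
#'   \code{"discrete"} (quantized waveforms; exactly repeating states).
#' @param cardiac_levels,resp_levels number of quantization levels per
#'   waveform in discrete mode.
#' @param jitter_amplitude residual continuous SI translation (voxels)
#'   added on top of the (possibly quantized) respiratory shift; emulates
#'   the intra-state motion real clusters retain. Default 0.
#' @param jitter_period period of the jitter in seconds (default
#'   \code{resp_period / 3.61}, incommensurate with both main periods).
#' @param systole_width fraction of the cardiac cycle occupied by the
#'   raised-cosine systolic pulse (default 1/3; larger values lengthen the
#'   systolic dwell, e.g. to emulate higher heart rates where systole fills
#'   more of the cycle).
#' @param resp_shape \code{"sin"} (the plain sinusoid) or \code{"relaxed"}
#'   (squared raised cosine; longer end-expiratory dwell).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_size = 64, ndim = 2, ellipsoids = NULL,
                         cardiac_period = 0.83, resp_period = 3.7,
                         cardiac_amplitude = 0.15, resp_amplitude = 2,
                         noise_sigma = 0.01,
                         motion_mode = c("smooth", "discrete"),
                         cardiac_levels = 2, resp_levels = 2,
                         resp_shape = c("sin", "relaxed"),
                         jitter_amplitude = 0, jitter_period = NULL,
                         systole_width = 1 / 3) {
  motion_mode <- match.arg(motion_mode)
  resp_shape <- match.arg(resp_shape)
  if (!ndim %in% c(2, 3)) stop_arg("ndim must be 2 or 3")
  if (cardiac_period <= 0 || resp_period <= 0) stop_arg("periods must be > 0")
  if (cardiac_period >= resp_period)
    stop_arg("cardiac_period must be below resp_period (physiology)")
  if (cardiac_amplitude < 0 || cardiac_amplitude >= 1)
    stop_arg("cardiac_amplitude must be in [0, 1)")
  if (resp_amplitude < 0) stop_arg("resp_amplitude must be >= 0")
  if (jitter_amplitude < 0) stop_arg("jitter_amplitude must be >= 0")
  if (systole_width <= 0 || systole_width > 1)
    stop_arg("systole_width must be in (0, 1]")
  jitter_period <- jitter_period %||% (resp_period / 3.61)
  if (is.null(ellipsoids)) ellipsoids <- default_anatomy(grid_size, ndim)
  spec <- structure(list(
    grid_size = as.integer(grid_size), ndim = as.integer(ndim),
    ellipsoids = ellipsoids,
    cardiac_period = cardiac_period, resp_period = resp_period,
    cardiac_amplitude = cardiac_amplitude, resp_amplitude = resp_amplitude,
    noise_sigma = noise_sigma, motion_mode = motion_mode,
    cardiac_levels = as.integer(cardiac_levels),
    resp_levels = as.integer(resp_levels),
    resp_shape = resp_shape,
    jitter_amplitude = jitter_amplitude,
    jitter_period = jitter_period,
    systole_width = systole_width), class = "phantom_spec")
  validate_phantom_extent(spec)
  spec
}

# Structures sized relative to the grid; SI axis is the last axis.
default_anatomy <- function(n, ndim) {
  ctr <- function(...) c(...)[seq_len(ndim)] * n
  ax <- function(...) c(...)[seq_len(ndim)] * n
  list(
    list(center = ctr(0.5, 0.5, 0.5), semiaxes = ax(0.45, 0.43, 0.43),
         value = 0.5 + 0i, label = "background"),
    list(center = ctr(0.68, 0.68, 0.68), semiaxes = ax(0.22, 0.20, 0.20),
         value = 0.15 + 0i, label = "lung"),
    list(center = ctr(0.62, 0.33, 0.33), semiaxes = ax(0.25, 0.14, 0.14),
         value = 1.2 + 0i, label = "liver"),
    list(center = ctr(0.36, 0.58, 0.55), semiaxes = ax(0.17, 0.16, 0.16),
         value = 1 + 0i, label = "myocardium"),
    list(center = ctr(0.36, 0.58, 0.55), semiaxes = ax(0.11, 0.10, 0.10),
         value = 2.4 + 0i, label = "blood")
  )
}

validate_phantom_extent <- function(spec) {
  n <- spec$grid_size
  for (e in spec$ellipsoids) {
    shift <- if (e$label %in% c("blood", "myocardium", "liver"))
      spec$resp_amplitude + spec$jitter_amplitude else 0
    lo <- e$center - e$semiaxes - shift
    hi <- e$center + e$semiaxes + shift
    if (any(lo < 0) || any(hi > n - 1))
      stop_arg("structure '%s' leaves the grid at extreme phases", e$label)
  }
  invisible(spec)
}

# Raised-cosine systolic pulse at the start of the cycle; width is the
# fraction of the cycle the pulse occupies (default one third).
cardiac_weight <- function(t, period, width = 1 / 3) {
  ph <- (t / period) %% 1
  ifelse(ph < width, 0.5 * (1 - cos(2 * pi * ph / width)), 0)
}

resp_wave <- function(t, period, shape) {
  ph <- (t / period) %% 1
  switch(shape,
    sin = sin(2 * pi * ph),
    relaxed = (0.5 - 0.5 * cos(2 * pi * ph))^2)
}

quantize_levels <- function(v, levels, lo, hi) {
  if (levels <= 1) return(rep(lo, length(v)))
  q <- round((v - lo) / (hi - lo) * (levels - 1))
  lo + q / (levels - 1) * (hi - lo)
}

# Motion parameters (cardiac weight, SI shift, state label) at time t.
motion_state <- function(spec, t) {
  w <- cardiac_weight(t, spec$cardiac_period, spec$systole_width %||% (1 / 3))
  s <- resp_wave(t, spec$resp_period, spec$resp_shape)
  slo <- if (spec$resp_shape == "sin") -1 else 0
  if (spec$motion_mode == "discrete") {
    w <- quantize_levels(w, spec$cardiac_levels, 0, 1)
    s <- quantize_levels(s, spec$resp_levels, slo, 1)
    wi <- round(w * (spec$cardiac_levels - 1))
    si <- round((s - slo) / (1 - slo) * (spec$resp_levels - 1))
    lab <- wi * spec$resp_levels + si + 1
  } else {
    lab <- rep(NA_integer_, length(t))
  }
  shift <- spec$resp_amplitude * s
  if (spec$jitter_amplitude > 0)
    shift <- shift + spec$jitter_amplitude * sin(2 * pi * t / spec$jitter_period)
  list(w = w, shift = shift, label = as.integer(lab))
}

#' Render the phantom at a time point
#'
#' Ellipsoids are rasterized with anti-aliased (linear ramp) edges about one
#' voxel wide, painted in list order.
#'
#' @param spec a \code{phantom_spec}.
#' @param t time in seconds (scalar, >= 0).
#' @return list with \code{image} (complex array) and \code{labels}
#'   (character array; "" where empty).
#' @export
render_phantom <- function(spec, t = 0) {
  stopifnot(inherits(spec, "phantom_spec"), t >= 0)
  st <- motion_state(spec, t)
  render_phantom_state(spec, st$w, st$shift)
}

#' Render the phantom at an explicit motion state
#'
#' Like \code{\link{render_phantom}} but parameterized directly by the
#' systolic weight and SI shift instead of time; useful for rendering the
#' ground-truth volume of a reconstructed cluster's motion state.
#'
#' @param spec a \code{phantom_spec}.
#' @param w systolic weight in \code{[0, 1]}.
#' @param shift SI translation of heart and liver, voxels.
#' @return list with \code{image} and \code{labels} as in
#'   \code{\link{render_phantom}}.
#' @export
render_phantom_state <- function(spec, w, shift) {
  n <- spec$grid_size
  d <- spec$ndim
  dims <- rep(n, d)
  ax <- lapply(seq_len(d), function(a) seq_len(n) - 1)
  img <- array(0i, dim = dims)
  lab <- array("", dim = dims)
  # voxel coordinate arrays
  coords <- vector("list", d)
  for (a in seq_len(d)) {
    rep_each <- prod(dims[seq_len(a - 1)])
    rep_times <- prod(dims[seq_len(d)[-seq_len(a)]])
    coords[[a]] <- array(rep(rep(ax[[a]], each = rep_each), times = rep_times),
                         dim = dims)
  }
  for (e in spec$ellipsoids) {
    cen <- e$center
    sem <- e$semiaxes
    if (e$label %in% c("blood", "myocardium")) {
      sem <- sem * (1 - spec$cardiac_amplitude * w)
      cen[d] <- cen[d] + shift
    } else if (e$label == "liver") {
      cen[d] <- cen[d] + shift
    }
    rho2 <- 0
    for (a in seq_len(d)) rho2 <- rho2 + ((coords[[a]] - cen[a]) / sem[a])^2
    rho <- sqrt(rho2)
    edge <- 1 / min(sem)  # ~one voxel in normalized radius units
    cov <- pmin(pmax((1 - rho) / edge + 0.5, 0), 1)
    img <- img * (1 - cov) + e$value * cov
    lab[cov >= 0.5] <- e$label
  }
  list(image = img, labels = lab)
}

#' Generate smooth synthetic coil sensitivity maps
#'
#' Gaussian receive lobes placed around the field of view with low-order
#' polynomial phase; deterministic given the seed. A single coil yields a
#' uniform all-ones map.
#'
#' @param grid_size voxels per axis (scalar).
#' @param ndim 2 or 3.
#' @param n_coils number of coils (>= 1).
#' @param seed RNG seed.
#' @return a \code{coil_sens} object.
#' @export
make_coil_maps <- function(grid_size, ndim = 2, n_coils = 8, seed = 1) {
  if (n_coils < 1) stop_arg("n_coils must be >= 1")
  n <- grid_size
  dims <- rep(n, ndim)
  if (n_coils == 1)
    return(coil_sens(array(1 + 0i, dim = c(dims, 1))))
  with_seed(seed, function() {
    ax <- centered_axis(n) / n
    coords <- vector("list", ndim)
    for (a in seq_len(ndim)) {
      rep_each <- prod(dims[seq_len(a - 1)])
      rep_times <- prod(dims[seq_len(ndim)[-seq_len(a)]])
      coords[[a]] <- array(rep(rep(ax, each = rep_each), times = rep_times),
                           dim = dims)
    }
    maps <- array(0i, dim = c(dims, n_coils))
    idx <- slice.index(maps, ndim + 1)
    for (c in seq_len(n_coils)) {
      th <- 2 * pi * (c - 1) / n_coils + runif(1, -0.2, 0.2)
      cen <- 0.55 * c(cos(th), sin(th), runif(1, -0.3, 0.3))[seq_len(ndim)]
      sig <- runif(1, 0.45, 0.65)
      r2 <- 0
      for (a in seq_len(ndim)) r2 <- r2 + (coords[[a]] - cen[a])^2
      mag <- exp(-r2 / (2 * sig^2))
      ph <- 0
      for (a in seq_len(ndim)) ph <- ph + runif(1, -2, 2) * coords[[a]]
      maps[idx == c] <- mag * exp(1i * (ph + runif(1, -pi, pi)))
    }
    coil_sens(maps)
  })
}

#' Simulate a free-running multi-coil acquisition
#'
#' For every readout, the phantom is rendered at the readout's interleave
#' timestamp (motion is frozen within an interleave, matching the
#' interleave-level clustering granularity), multiplied by each coil map,
#' and sampled with the NUFFT at the readout's k-space coordinates. SI
#' readouts are additionally stored as 1D projections (inverse Fourier
#' transform of the SI readout along the SI axis). Complex Gaussian noise
#' with std \code{noise_sigma * max |signal|} is added; the RNG is fully
#' determined by \code{seed}.
#'
#' @param spec a \code{phantom_spec}.
#' @param traj a \code{radial_trajectory} with matching dimensionality.
#' @param coils a \code{coil_sens} on the phantom grid.
#' @param seed RNG seed for the noise.
#' @return object of class \code{kspace_data}: complex \code{samples}
#'   \code{[n_readouts, samples_per_readout, n_coils]}, the trajectory,
#'   \code{si_projections} \code{[n_z, n_si, n_coils]}, and a \code{truth}
#'   list (per-interleave timestamps, motion states, planted labels).
#' @export
simulate_acquisition <- function(spec, traj, coils, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(traj, "radial_trajectory"),
            inherits(coils, "coil_sens"))
  if (spec$ndim != traj$ndim)
    stop_arg("phantom is %dD but trajectory is %dD", spec$ndim, traj$ndim)
  dims <- rep(spec$grid_size, spec$ndim)
  if (!identical(as.integer(coils$grid), as.integer(dims)))
    stop_arg("coil maps do not match the phantom grid")
  n_int <- traj$n_interleaves
  rpi <- traj$readouts_per_interleave
  S <- traj$samples_per_readout
  nc <- coils$n_coils
  # One timestamp per interleave: its first readout.
  t_int <- traj$timestamp[(seq_len(n_int) - 1) * rpi + 1]
  st <- motion_state(spec, t_int)
  samples <- array(0i, dim = c(n_int * rpi, S, nc))
  # Cache rendered volumes by motion state (exact reuse in discrete mode).
  cache <- new.env(parent = emptyenv())
  cmaps <- lapply(seq_len(nc), function(c) coil_map(coils, c))
  for (m in seq_len(n_int)) {
    key <- sprintf("%.12g_%.12g", st$w[m], st$shift[m])
    if (is.null(cache[[key]])) {
      vol <- render_phantom_state(spec, st$w[m], st$shift[m])$image
      cache[[key]] <- lapply(cmaps, function(cm) cm * vol)
    }
    cimgs <- cache[[key]]
    ro_idx <- (m - 1) * rpi + seq_len(rpi)
    op <- nufft_operator(flatten_coords(traj, ro_idx), dims)
    for (c in seq_len(nc)) {
      samples[ro_idx, , c] <- matrix(nufft_forward(op, cimgs[[c]]), rpi, S)
    }
  }
  peak <- max(abs(samples))
  if (spec$noise_sigma > 0) {
    with_seed(seed, function() {
      nn <- length(samples)
      noise <- complex(real = rnorm(nn), imaginary = rnorm(nn)) *
        (spec$noise_sigma * peak)
      samples <<- samples + array(noise, dim = dim(samples))
    })
  }
  si_idx <- which(traj$is_si)
  si_proj <- NULL
  if (length(si_idx)) {
    # Inverse FT of each SI readout along the SI axis: radii are
    # (s - S/2 + 0.5)/S, so use an explicit centered transform.
    radii <- (seq_len(S) - 1 - (S - 1) / 2) / S
    z <- centered_axis(S)
    Fh <- exp(2i * pi * outer(z, radii))  # [n_z, S]
    si_proj <- array(0i, dim = c(S, length(si_idx), nc))
    for (c in seq_len(nc)) {
      m <- matrix(samples[si_idx, , c], length(si_idx), S)
      si_proj[, , c] <- Fh %*% t(m)
    }
  }
  structure(list(
    samples = samples, traj = traj, si_projections = si_proj,
    n_coils = nc, grid = dims,
    truth = list(t_interleave = t_int, w = st$w, shift = st$shift,
                 label = st$label, coils = coils,
                 noise_sigma = spec$noise_sigma, seed = seed)),
    class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "kspace_data: %d readouts x %d samples x %d coils (%s grid)%s\n",
    d[1], d[2], d[3], paste(x$grid, collapse = "x"),
    if (!is.null(x$si_projections))
      sprintf(", %d SI projections", dim(x$si_projections)[2]) else ""))
  invisible(x)
}
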