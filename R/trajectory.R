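# Free-running radial trajectory generation.
#
# 3D mode produces a golden-angle spiral-phyllotaxis "kooshball": readout
# diameter endpoints spiral over the hemisphere with golden-angle azimuthal
# increments, interleaves are decimated subsets additionally rotated by the
# golden angle about z. 2D mode produces golden-angle spokes for desk-scale
# testing. Every interleave optionally starts with a superior-inferior (SI)
# self-gating readout along +z (3D) or the last axis (2D).

GOLDEN_ANGLE <- pi * (3 - sqrt(5))  # ~111.246 degrees

#' Generate a free-running radial trajectory
#'
#' Readouts are straight lines (full diameters) through the k-space center;
#' sample positions along each readout are equispaced and symmetric about 0,
#' in normalized units (cycles/FOV, each axis within \code{[-0.5, 0.5)}).
#' In 3D the imaging readout endpoints follow a spiral-phyllotaxis pattern:
#' golden-angle azimuth and (by default) an equal-area polar law, so that
#' endpoint directions cover the sphere uniformly; interleave \code{m} takes
#' every \code{n_interleaves}-th spiral point starting at \code{m} and is
#' rotated by \code{m} golden angles about z. In 2D consecutive imaging
#' spokes are rotated by the golden angle.
#'
#' @param n_interleaves number of interleaves (groups of readouts acquired
#'   consecutively; the clustering granularity).
#' @param readouts_per_interleave readouts per interleave, including the SI
#'   readout when \code{include_si = TRUE}.
#' @param samples_per_readout even number of samples per readout.
#' @param ndim 2 or 3.
#' @param include_si prepend an SI self-gating readout (direction +z) to each
#'   interleave.
#' @param tr repetition time in seconds; one readout per TR.
#' @param polar_law polar-angle law of the 3D spiral: \code{"equal_area"}
#'   (cos(theta) uniform over the hemisphere; uniform endpoint density) or
#'   \code{"sqrt"} (theta proportional to sqrt(n/N), the classical spiral
#'   phyllotaxis which mildly densifies the pole).
#' @return an object of class \code{radial_trajectory} with per-readout
#'   coordinates \code{[n_readouts, samples_per_readout, ndim]}, interleave
#'   structure, SI flags and timestamps.
#' @export
generate_trajectory <- function(n_interleaves, readouts_per_interleave,
                                samples_per_readout, ndim = 3,
                                include_si = FALSE, tr = 0.00284,
                                polar_law = c("equal_area", "sqrt")) {
  polar_law <- match.arg(polar_law)
  if (!ndim %in% c(2, 3)) stop_arg("ndim must be 2 or 3, got %s", ndim)
  if (n_interleaves < 1 || readouts_per_interleave < 1 ||
      samples_per_readout < 1)
    stop_arg("all counts must be >= 1")
  if (samples_per_readout %% 2 != 0)
    stop_arg("samples_per_readout must be even, got %d", samples_per_readout)
  if (tr <= 0) stop_arg("tr must be positive")
  if (include_si && readouts_per_interleave < 2)
    stop_arg("include_si requires at least 2 readouts per interleave")

  n_int <- as.integer(n_interleaves)
  rpi <- as.integer(readouts_per_interleave)
  S <- as.integer(samples_per_readout)
  n_ro <- n_int * rpi
  rpi_img <- rpi - as.integer(include_si)
  n_img <- n_int * rpi_img

  # Unit endpoint direction per imaging readout.
  if (ndim == 3) {
    N <- n_img
    # Spiral point index for imaging readout j (0-based within interleave
    # imaging readouts) of interleave m: p = m + j * n_int.
    m <- rep(0:(n_int - 1), each = rpi_img)
    j <- rep(seq_len(rpi_img) - 1, times = n_int)
    p <- m + j * n_int
    phi <- (p + m) * GOLDEN_ANGLE  # spiral azimuth + per-interleave rotation
    u <- (p + 0.5) / N
    cth <- switch(polar_law,
      equal_area = 1 - u,
      sqrt = cos(pi / 2 * sqrt(u)))
    sth <- sqrt(pmax(0, 1 - cth^2))
    dirs <- cbind(sth * cos(phi), sth * sin(phi), cth)
  } else {
    az <- (seq_len(n_img) - 1) * GOLDEN_ANGLE
    dirs <- cbind(cos(az), sin(az))
  }

  # Interleave SI readouts (first readout of each interleave, +z / last axis).
  is_si <- logical(n_ro)
  all_dirs <- matrix(0, n_ro, ndim)
  img_ptr <- 1L
  for (mi in seq_len(n_int)) {
    base <- (mi - 1) * rpi
    offs <- seq_len(rpi)
    if (include_si) {
      is_si[base + 1] <- TRUE
      all_dirs[base + 1, ] <- c(rep(0, ndim - 1), 1)
      offs <- offs[-1]
    }
    k <- length(offs)
    all_dirs[base + offs, ] <- dirs[img_ptr:(img_ptr + k - 1), , drop = FALSE]
    img_ptr <- img_ptr + k
  }

  # Equispaced radii symmetric about zero, |k| < 0.5.
  radii <- (seq_len(S) - 1 - (S - 1) / 2) / S
  coords <- array(0, dim = c(n_ro, S, ndim))
  for (a in seq_len(ndim)) {
    coords[, , a] <- outer(all_dirs[, a], radii)
  }

  structure(list(
    coords = coords,
    directions = all_dirs,
    interleave_id = rep(seq_len(n_int), each = rpi),
    readout_in_interleave = rep(seq_len(rpi), times = n_int),
    is_si = is_si,
    timestamp = (seq_len(n_ro) - 1) * tr,
    n_interleaves = n_int,
    readouts_per_interleave = rpi,
    samples_per_readout = S,
    ndim = as.integer(ndim),
    tr = tr,
    include_si = include_si
  ), class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf(
    "radial_trajectory: %dD, %d interleaves x %d readouts (%d samples each)%s\n",
    x$ndim, x$n_interleaves, x$readouts_per_interleave, x$samples_per_readout,
    if (x$include_si) ", SI self-gating enabled" else ""))
  invisible(x)
}

#' SI self-gating schedule
#'
#' One entry per interleave: the timestamp and interleave id of its SI
#' readout. The mean rate is \code{1 / (readouts_per_interleave * tr)}
#' (16 Hz for the reference whole-heart protocol: 22 readouts at
#' TR = 2.84 ms).
#'
#' @param traj a \code{radial_trajectory} with SI readouts.
#' @return data.frame with columns \code{timestamp}, \code{interleave_id};
#'   attribute \code{rate_hz} carries the mean SI rate.
#' @export
si_schedule <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (!any(traj$is_si))
    stop_arg("trajectory has no SI readouts")
  idx <- which(traj$is_si)
  out <- data.frame(timestamp = traj$timestamp[idx],
                    interleave_id = traj$interleave_id[idx])
  attr(out, "rate_hz") <- 1 / (traj$readouts_per_interleave * traj$tr)
  out
}

# Coordinates of a subset of readouts, flattened to a sample matrix [n, ndim].
flatten_coords <- function(traj, readout_idx) {
  cc <- traj$coords[readout_idx, , , drop = FALSE]
  d <- dim(cc)
  matrix(cc, d[1] * d[2], d[3])
}
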