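# Image-quality metrics: blood-myocardium contrast ratio and sigmoid-fit
# interface sharpness along a user-chosen profile line.

#' Blood-to-myocardium contrast ratio
#'
#' \code{(blood - myocardium) / myocardium} of mean ROI signal intensities.
#'
#' @param blood_mean,myo_mean mean magnitude intensities; \code{myo_mean}
#'   must be positive.
#' @return the contrast ratio.
#' @export
contrast_ratio <- function(blood_mean, myo_mean) {
  if (myo_mean <= 0) stop_arg("myo_mean must be positive")
  (blood_mean - myo_mean) / myo_mean
}

#' Mean magnitude intensity over labelled ROIs
#'
#' ROIs are eroded by \code{erode} voxels before averaging, excluding
#' partial-volume voxels at tissue boundaries (the usual practice when
#' placing ROIs inside a tissue).
#'
#' @param volume complex or numeric image.
#' @param labels character array of the same shape (e.g. the phantom label
#'   map).
#' @param which labels to report (default: all present).
#' @param erode voxels of binary erosion applied to each ROI (default 1);
#'   skipped when erosion would empty the ROI.
#' @return named numeric vector of ROI means.
#' @export
roi_means <- function(volume, labels, which = NULL, erode = 1) {
  stopifnot(identical(dim(volume), dim(labels)))
  lv <- setdiff(unique(as.vector(labels)), "")
  if (!is.null(which)) lv <- intersect(lv, which)
  vapply(lv, function(l) {
    m <- array(labels == l, dim(labels))
    if (erode > 0) {
      me <- m
      for (i in seq_len(erode)) me <- erode_mask(me)
      if (any(me)) m <- me
    }
    mean(abs(volume)[m])
  }, numeric(1))
}

# One step of binary erosion with the 3^d box element (replicate edges).
erode_mask <- function(m) {
  d <- dim(m)
  out <- as.double(m)
  for (a in seq_along(d)) {
    out <- .conv_axis(out, as.integer(d), a - 1L, rep(1 / 3, 3))
  }
  array(out > 1 - 1e-9, dim = d)
}

#' Sample an intensity profile across a tissue interface
#'
#' Magnitudes are sampled by linear interpolation along the segment from
#' \code{p0} to \code{p1} (0-based voxel coordinates), at 4x voxel density
#' by default.
#'
#' @param volume image array.
#' @param p0,p1 segment endpoints, 0-based voxel coordinates.
#' @param oversample samples per voxel of segment length (default 4).
#' @return object of class \code{profile_line}: \code{positions} (voxels
#'   along the segment, strictly increasing) and \code{intensities}.
#' @export
extract_profile <- function(volume, p0, p1, oversample = 4) {
  d <- length(dim(volume))
  stopifnot(length(p0) == d, length(p1) == d)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(8, ceiling(len * oversample) + 1)
  tt <- seq(0, 1, length.out = n)
  pos <- outer(tt, p1 - p0) + matrix(p0, n, d, byrow = TRUE)
  structure(list(positions = tt * len,
                 intensities = abs(interp_linear(abs(volume), pos)),
                 endpoints = list(p0 = p0, p1 = p1)),
            class = "profile_line")
}

#' Interface sharpness: slope of a fitted sigmoid
#'
#' Least-squares fit of \code{s(t) = L + (U - L) / (1 + exp(-a (t - t0)))}
#' to the profile, initialized from the plateau means and the midpoint
#' crossing. The returned sharpness is \code{|a|} per unit position. The
#' slope is invariant to affine intensity rescaling of the profile.
#' Degenerate (flat) or non-fittable profiles return \code{NaN} with
#' \code{ok = FALSE}, never silently.
#'
#' @param p a \code{profile_line}, or a list with \code{positions} and
#'   \code{intensities} (>= 8 samples, strictly increasing positions).
#' @return list with \code{slope} (\code{|a|}), \code{ok} flag, and the
#'   fitted parameters \code{L}, \code{U}, \code{t0}, \code{a}.
#' @export
interface_sharpness <- function(p) {
  t <- as.numeric(p$positions)
  y <- as.numeric(p$intensities)
  if (length(t) < 8) stop_arg("profile needs at least 8 samples")
  if (any(diff(t) <= 0)) stop_arg("positions must be strictly increasing")
  q <- max(3L, floor(length(y) / 4))
  L0 <- mean(y[seq_len(q)])
  U0 <- mean(y[seq(length(y) - q + 1, length(y))])
  if (abs(U0 - L0) < 1e-8 * max(abs(y), 1e-12)) {
    return(list(slope = NaN, ok = FALSE, L = L0, U = U0,
                t0 = NA_real_, a = NA_real_,
                reason = "flat profile (no interface)"))
  }
  mid <- (L0 + U0) / 2
  cross <- which(diff(sign(y - mid)) != 0)
  t00 <- if (length(cross)) t[cross[1]] else t[ceiling(length(t) / 2)]
  a0 <- sign(U0 - L0) * 4 * max(abs(diff(y)) / diff(t)) / abs(U0 - L0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ L + (U - L) / (1 + exp(-a * (t - t0))),
      start = list(L = L0, U = U0, a = a0, t0 = t00),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(slope = NaN, ok = FALSE, L = L0, U = U0, t0 = NA_real_,
                a = NA_real_, reason = "fit did not converge"))
  }
  cf <- stats::coef(fit)
  list(slope = abs(unname(cf["a"])), ok = TRUE, L = unname(cf["L"]),
       U = unname(cf["U"]), t0 = unname(cf["t0"]), a = unname(cf["a"]))
}

#' Per-case image-quality report
#'
#' Computes the blood-myocardium contrast ratio from the label map and the
#' sigmoid sharpness along supplied profiles, as a tidy table.
#'
#' @param volume reconstructed image.
#' @param labels phantom label map (same grid).
#' @param profiles named list of \code{profile_line}s (or endpoint pairs
#'   \code{list(p0=, p1=)}).
#' @param case,method identifiers recorded in the table.
#' @return data.frame with columns case, method, metric, value.
#' @export
quality_report <- function(volume, labels = NULL, profiles = list(),
                           case = "case", method = "method") {
  rows <- list()
  if (!is.null(labels)) {
    mu <- roi_means(volume, labels, c("blood", "myocardium"))
    if (all(c("blood", "myocardium") %in% names(mu))) {
      rows[[length(rows) + 1]] <- data.frame(
        case = case, method = method, metric = "contrast_ratio",
        value = contrast_ratio(mu[["blood"]], mu[["myocardium"]]))
    }
  }
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    if (!inherits(pr, "profile_line"))
      pr <- extract_profile(volume, pr$p0, pr$p1)
    sh <- interface_sharpness(pr)
    rows[[length(rows) + 1]] <- data.frame(
      case = case, method = method,
      metric = paste0("sharpness_", nm), value = sh$slope)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
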