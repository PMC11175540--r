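# Shared numeric helpers. Conventions fixed across the package:
#  - k-space coordinates in cycles/FOV, each axis in [-0.5, 0.5);
#  - image indices 0-based, centered at floor(N/2) per axis;
#  - complex arrays are base-R complex arrays with a dim attribute.

#' @useDynLib simbar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft kmeans dnorm median sd rnorm runif setNames coef
#' @importFrom utils tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root-mean-square error of magnitudes, normalized by the reference
#'
#' Complex reconstructions carry an arbitrary global phase, so volumes are
#' compared through their magnitudes.
#'
#' @param x,ref arrays of identical dimension (complex or numeric).
#' @return scalar \code{||abs(x) - abs(ref)|| / ||abs(ref)||}.
#' @export
nrmse <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  sqrt(sum((abs(x) - abs(ref))^2)) / sqrt(sum(abs(ref)^2))
}

# Evaluate f() under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  f()
}

# Circularly roll an array by `by` (recycled per axis).
roll_array <- function(a, by) {
  d <- dim(a) %||% length(a)
  by <- rep_len(by, length(d))
  idx <- lapply(seq_along(d), function(i) {
    n <- d[i]
    ((seq_len(n) - 1 - by[i]) %% n) + 1
  })
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  dim(out) <- dim(a)
  out
}

# fftshift: move index 0 to the grid center floor(n/2); ifftshift inverts it.
fftshift <- function(a) roll_array(a, floor((dim(a) %||% length(a)) / 2))
ifftshift <- function(a) roll_array(a, -floor((dim(a) %||% length(a)) / 2))

# Centered DFT pair: cdft(x)[k] = sum_r x[r] exp(-2i pi k r / n) with both
# r and k centered at floor(n/2). cdft_adj is its exact conjugate transpose.
cdft <- function(x) fftshift(fft(ifftshift(x)))
cdft_adj <- function(y) fftshift(fft(ifftshift(y), inverse = TRUE))

# 0-based centered index coordinates of a grid axis.
centered_axis <- function(n) seq_len(n) - 1 - floor(n / 2)

# Linear (bi/trilinear) interpolation of an array at arbitrary fractional
# 0-based positions (matrix n x d), clamped to the grid.
interp_linear <- function(arr, pos) {
  d <- length(dim(arr))
  stopifnot(ncol(pos) == d)
  dm <- dim(arr)
  pos <- pmin(pmax(pos, 0), matrix(dm - 1, nrow(pos), d, byrow = TRUE))
  lo <- pmin(floor(pos), matrix(dm - 2, nrow(pos), d, byrow = TRUE))
  lo <- pmax(lo, 0)
  fr <- pos - lo
  out <- if (is.complex(arr)) complex(nrow(pos)) else numeric(nrow(pos))
  for (m in 0:(2^d - 1)) {
    w <- rep(1, nrow(pos))
    off <- rep(1, nrow(pos))  # 1-based flat index
    mult <- 1
    for (a in seq_len(d)) {
      hi <- bitwAnd(bitwShiftR(m, a - 1), 1)
      w <- w * if (hi) fr[, a] else 1 - fr[, a]
      off <- off + (lo[, a] + hi) * mult
      mult <- mult * dm[a]
    }
    out <- out + w * arr[off]
  }
  out
}

# Separable Gaussian smoothing with replicate-edge handling.
gauss_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr) %||% length(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- as.double(arr)
  for (a in seq_along(d)) {
    out <- .conv_axis(out, as.integer(d), a - 1L, k)
  }
  array(out, dim = dim(arr))
}

gauss_smooth_cplx <- function(arr, sigma) {
  array(complex(real = gauss_smooth(Re(arr), sigma),
                imaginary = gauss_smooth(Im(arr), sigma)), dim = dim(arr))
}

# Central-difference gradient along each axis (replicate edges).
# Returns a list of arrays.
array_gradient <- function(arr) {
  d <- dim(arr)
  nd <- length(d)
  lapply(seq_len(nd), function(a) {
    idx_p <- lapply(seq_len(nd), function(i) seq_len(d[i]))
    idx_m <- idx_p
    idx_p[[a]] <- pmin(idx_p[[a]] + 1, d[a])
    idx_m[[a]] <- pmax(idx_m[[a]] - 1, 1)
    g <- (do.call(`[`, c(list(arr), idx_p)) -
            do.call(`[`, c(list(arr), idx_m))) / 2
    dim(g) <- d
    g
  })
}

# Block-average downsampling by a factor of 2 along every axis.
downsample2 <- function(arr) {
  d <- dim(arr)
  nd <- length(d)
  dn <- pmax(floor(d / 2), 1)
  out <- array(if (is.complex(arr)) 0i else 0, dim = dn)
  cnt <- 0
  offs <- expand.grid(rep(list(0:1), nd))
  for (r in seq_len(nrow(offs))) {
    idx <- lapply(seq_len(nd), function(a) {
      pmin(2 * (seq_len(dn[a]) - 1) + 1 + offs[r, a], d[a])
    })
    out <- out + do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  out / nrow(offs)
}

# Flat 1-based index of the centered voxel.
center_index <- function(dm) {
  ctr <- floor(dm / 2)  # 0-based
  sum(ctr * cumprod(c(1, dm[-length(dm)]))) + 1
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
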