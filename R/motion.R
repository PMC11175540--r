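# Non-rigid deformation estimation between adjacent-cluster images and the
# warping operator T_u with its exact adjoint.
#
# Registration is a self-contained multiresolution demons-type scheme:
# an SSD-driven force on magnitude images, Gaussian regularization of the
# displacement field, and best-so-far tracking (which guarantees that
# registration never increases the residual). The deformation is expressed
# in the pull-back convention warp(x, u)(r) = x(r + u(r)), i.e. u maps the
# moving image onto the reference, exactly the role of the inter-cluster
# operator in the motion-compensated reconstruction.

#' Construct a deformation field
#'
#' @param displacement array \code{[dims..., ndim]} of per-voxel
#'   displacements in voxel units (pull-back convention).
#' @param pair_id optional integer pair \code{(i, i-1)} naming the cluster
#'   pair the field registers.
#' @return object of class \code{deformation_field}.
#' @export
deformation_field <- function(displacement, pair_id = NULL) {
  d <- dim(displacement)
  nd <- d[length(d)]
  stopifnot(nd == length(d) - 1)
  if (any(!is.finite(displacement))) stop_arg("non-finite displacement")
  structure(list(displacement = displacement, grid = d[-length(d)],
                 ndim = nd, pair_id = pair_id,
                 converged = NA, residual = NA_real_),
            class = "deformation_field")
}

#' Identity (all-zero) deformation field
#' @param grid integer vector of grid sizes.
#' @return a \code{deformation_field} with zero displacement.
#' @export
identity_field <- function(grid) {
  deformation_field(array(0, dim = c(grid, length(grid))))
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("deformation_field: %s grid, max |u| = %.3f voxels%s\n",
              paste(x$grid, collapse = "x"), max(abs(x$displacement)),
              if (!is.null(x$pair_id))
                sprintf(" (pair %d -> %d)", x$pair_id[1], x$pair_id[2])
              else ""))
  invisible(x)
}

field_components <- function(u) {
  d <- dim(u$displacement)
  idx <- slice.index(u$displacement, length(d))
  lapply(seq_len(u$ndim), function(a)
    array(u$displacement[idx == a], dim = d[-length(d)]))
}

#' Warp an image with a deformation field (linear operator T_u)
#'
#' Linear-interpolation pull-back \code{out(r) = x(r + u(r))}, applied to
#' real and imaginary parts independently; out-of-grid lookups clamp to the
#' nearest edge. For a fixed field this is a linear operator in the image;
#' its exact transpose is \code{\link{warp_adjoint}}. A zero field returns
#' the input unchanged.
#'
#' @param x complex or numeric image array.
#' @param u a \code{deformation_field} on the same grid.
#' @return warped image (same storage mode as the input).
#' @export
warp <- function(x, u) {
  stopifnot(inherits(u, "deformation_field"))
  if (!identical(as.integer(dim(x)), as.integer(u$grid)))
    stop_arg("image grid does not match deformation field")
  if (all(u$displacement == 0)) return(x)
  cx <- is.complex(x)
  out <- .warp_pull(as.complex(x), field_components(u),
                    as.integer(u$grid))
  out <- array(out, dim = dim(x))
  if (cx) out else Re(out)
}

#' Adjoint of the warping operator
#'
#' Exact matrix transpose of \code{\link{warp}} for the same field:
#' interpolation weights are scattered instead of gathered.
#'
#' @param y image array (same grid as the field).
#' @param u a \code{deformation_field}.
#' @return adjoint-warped image.
#' @export
warp_adjoint <- function(y, u) {
  stopifnot(inherits(u, "deformation_field"))
  if (!identical(as.integer(dim(y)), as.integer(u$grid)))
    stop_arg("image grid does not match deformation field")
  if (all(u$displacement == 0)) return(y)
  cx <- is.complex(y)
  out <- .warp_push(as.complex(y), field_components(u),
                    as.integer(u$grid))
  out <- array(out, dim = dim(y))
  if (cx) out else Re(out)
}

# Upsample a displacement-component list to a finer grid (factor ~2),
# scaling displacements by the axis size ratio.
upsample_field <- function(comps, fine_dims) {
  coarse_dims <- dim(comps[[1]])
  d <- length(coarse_dims)
  # target voxel v maps to coarse position v * (nc-1)/(nf-1)
  ax <- lapply(seq_len(d), function(a) {
    if (fine_dims[a] == 1) 0 else
      (seq_len(fine_dims[a]) - 1) * (coarse_dims[a] - 1) / (fine_dims[a] - 1)
  })
  pos <- as.matrix(expand.grid(ax))
  lapply(seq_len(d), function(a) {
    sc <- fine_dims[a] / coarse_dims[a]
    array(interp_linear(comps[[a]], pos) * sc, dim = fine_dims)
  })
}

#' Estimate a non-rigid deformation between two volumes
#'
#' Multiresolution demons-style registration on magnitude images: at each
#' level the moving image is warped by the current field, an SSD-driven
#' update is computed from the local gradient, and the field is smoothed
#' with a Gaussian. The best field seen (lowest residual, including the
#' zero field) is returned, so registration never increases the residual.
#' Deterministic given its inputs.
#'
#' @param moving,reference complex or numeric volumes on the same grid
#'   (complex inputs are reduced to magnitude).
#' @param max_iters iteration cap per resolution level (default 300).
#' @param levels number of resolution levels (default 3).
#' @param smooth_sigma Gaussian regularization of the field, voxels
#'   (default 1.5).
#' @param step update step scale (default 1).
#' @param tol relative residual improvement below which iteration stops
#'   (default 1e-6).
#' @return a \code{deformation_field} \code{u} with
#'   \code{warp(moving, u) ~ reference}; fields \code{converged} and
#'   \code{residual} report the final state (non-convergence returns the
#'   best field seen, never an error).
#' @export
estimate_deformation <- function(moving, reference, max_iters = 300,
                                 levels = 3, smooth_sigma = 1.5,
                                 step = 1, tol = 1e-6) {
  if (!identical(dim(moving), dim(reference)))
    stop_arg("moving and reference grids differ")
  dims <- dim(moving)
  d <- length(dims)
  sc <- max(abs(reference), abs(moving))
  if (sc == 0) sc <- 1
  mov <- abs(moving) / sc
  ref <- abs(reference) / sc
  pyr <- list(list(mov = mov, ref = ref, dims = dims))
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[l]]
    if (min(prev$dims) <= 8) break
    pyr[[l + 1]] <- list(mov = downsample2(prev$mov),
                         ref = downsample2(prev$ref),
                         dims = dim(downsample2(prev$ref)))
  }
  pyr <- rev(pyr)  # coarse to fine
  u <- NULL
  converged <- FALSE
  best_res <- NA_real_
  for (lev in seq_along(pyr)) {
    p <- pyr[[lev]]
    u <- if (is.null(u)) {
      lapply(seq_len(d), function(a) array(0, dim = p$dims))
    } else {
      upsample_field(u, p$dims)
    }
    resid <- function(uc) {
      wm <- Re(.warp_pull(as.complex(p$mov), uc, as.integer(p$dims)))
      sum((wm - as.vector(p$ref))^2)
    }
    zero <- lapply(seq_len(d), function(a) array(0, dim = p$dims))
    best_u <- u
    best_res <- resid(u)
    r0 <- resid(zero)
    if (r0 < best_res) { best_u <- zero; best_res <- r0 }
    cur <- best_res
    stall <- 0
    for (it in seq_len(max_iters)) {
      wm <- array(Re(.warp_pull(as.complex(p$mov), u, as.integer(p$dims))),
                  dim = p$dims)
      e <- wm - p$ref
      g <- array_gradient(wm)
      den <- Reduce(`+`, lapply(g, function(x) x^2)) + e^2 + 1e-9
      for (a in seq_len(d)) {
        u[[a]] <- gauss_smooth(u[[a]] - step * e * g[[a]] / den,
                               smooth_sigma)
      }
      r <- resid(u)
      if (r < best_res) { best_u <- u; best_res <- r }
      if (cur - r < tol * max(cur, 1e-12)) stall <- stall + 1 else stall <- 0
      cur <- r
      if (stall >= 10) { converged <- TRUE; break }
    }
    u <- best_u
  }
  disp <- array(0, dim = c(dims, d))
  idx <- slice.index(disp, d + 1)
  for (a in seq_len(d)) disp[idx == a] <- u[[a]]
  out <- deformation_field(disp)
  out$converged <- converged
  out$residual <- sqrt(best_res)
  out
}

#' Estimate inter-cluster deformation fields for a volume series
#'
#' For clusters ordered by population (the cyclic adjacency of the
#' motion-resolved reconstruction), estimates \code{u_i} registering
#' cluster i onto cluster i-1, with the cyclic pair \code{x_0 = x_K}.
#'
#' @param volumes list of K gridded cluster volumes (population-rank
#'   order).
#' @param ... passed to \code{\link{estimate_deformation}}.
#' @return list of K \code{deformation_field}s; element i registers
#'   volume i onto volume i-1 (element 1 onto volume K).
#' @export
estimate_cluster_deformations <- function(volumes, ...) {
  K <- length(volumes)
  lapply(seq_len(K), function(i) {
    ref_i <- if (i == 1) K else i - 1
    u <- estimate_deformation(volumes[[i]], volumes[[ref_i]], ...)
    u$pair_id <- c(i, ref_i)
    u
  })
}
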