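# Similarity-driven binning (SIMBA): the SI-projection matrix is
# PCA-reduced, the real part of the projected scores is k-means-clustered
# for each candidate cluster count, and the count minimizing the mean
# point-to-centroid distance within the most populated cluster is selected.
# Whole interleaves inherit their SI readout's cluster label.

#' Build the SI feature matrix from acquired self-gating projections
#'
#' SI projections are concatenated across coils into a single complex matrix
#' (one column per SI readout, ordered by acquisition time); each feature row
#' is mean-centered.
#'
#' @param kdata a \code{kspace_data} containing SI projections.
#' @param coil_combine \code{"concat"} (stack all coils; default) or
#'   \code{"rss"} (magnitude root-sum-of-squares across coils).
#' @return object of class \code{si_matrix}: complex matrix \code{data}
#'   \code{[n_features, n_si]} plus bookkeeping.
#' @export
build_si_matrix <- function(kdata, coil_combine = c("concat", "rss")) {
  coil_combine <- match.arg(coil_combine)
  if (is.null(kdata$si_projections) || dim(kdata$si_projections)[2] == 0)
    stop_arg("k-space data has no SI projections")
  p <- kdata$si_projections  # [n_z, n_si, n_coils]
  d <- dim(p)
  X <- if (coil_combine == "concat") {
    matrix(aperm(p, c(1, 3, 2)), d[1] * d[3], d[2])
  } else {
    m <- sqrt(apply(abs(p)^2, c(1, 2), sum))
    matrix(as.complex(m), d[1], d[2])
  }
  if (anyNA(X)) stop_arg("NaN in SI projections")
  X <- X - rowMeans(X)
  structure(list(data = X, n_si = d[2], n_z = d[1], n_coils = d[3],
                 coil_combine = coil_combine), class = "si_matrix")
}

#' @export
print.si_matrix <- function(x, ...) {
  cat(sprintf("si_matrix: %d features x %d SI readouts (%s coils)\n",
              nrow(x$data), x$n_si, x$coil_combine))
  invisible(x)
}

# PCA scores of a centered complex matrix: complex SVD, retain the fewest
# components explaining >= var_explained (capped), return the REAL part of
# the projections (the part that is clustered).
pca_scores <- function(X, n_components = NULL, var_explained = 0.95,
                       max_components = 10) {
  sv <- svd(X)
  ev <- sv$d^2
  if (is.null(n_components)) {
    if (sum(ev) <= 0) {
      n_components <- 1L
    } else {
      cum <- cumsum(ev) / sum(ev)
      n_components <- min(which(cum >= var_explained)[1], max_components,
                          length(ev))
    }
  }
  n_components <- max(1L, min(n_components, length(sv$d)))
  U <- sv$u[, seq_len(n_components), drop = FALSE]
  scores <- t(Re(Conj(t(U)) %*% X))  # [n_si, n_components]
  list(scores = scores, n_components = n_components, sdev = sv$d)
}

# k-means++ seeding followed by standard Lloyd iterations (stats::kmeans),
# best of n_restarts by total within-cluster sum of squares.
kmeans_pp <- function(X, k, n_restarts = 10) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- matrix(0, k, ncol(X))
    ci <- sample.int(n, 1)
    centers[1, ] <- X[ci, ]
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    if (k > 1) for (j in 2:k) {
      pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      ci <- sample.int(n, 1, prob = pr)
      centers[j, ] <- X[ci, ]
      d2j <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(
      kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

# Deterministic k-means for one k: fixed derived seed.
run_kmeans <- function(scores, k, seed) {
  with_seed(seed + k, function() kmeans_pp(scores, k))
}

# The selection score: mean Euclidean distance between the most populated
# cluster's points and its centroid.
selection_score <- function(km, scores) {
  big <- which.max(km$size)
  pts <- scores[km$cluster == big, , drop = FALSE]
  ctr <- km$centers[big, ]
  mean(sqrt(rowSums((pts - matrix(ctr, nrow(pts), ncol(pts),
                                  byrow = TRUE))^2)))
}

#' Cluster SI projections with automatic cluster-count selection
#'
#' PCA is computed on the (centered, complex) SI matrix; the real part of
#' the projected scores is clustered with k-means (k-means++ seeding, 10
#' restarts) for every candidate k; the selected k minimizes the mean
#' distance between the most populated cluster's points and its centroid.
#' The default search range 10..14 matches the whole-heart protocol
#' (thousands of interleaves); desk-scale simulations use a smaller range.
#'
#' @param sim an \code{si_matrix} (or a plain numeric score matrix
#'   \code{[n_obs, n_feat]}, already reduced, for testing).
#' @param k_range integer vector \code{c(k_min, k_max)}; requires
#'   \code{k_min >= 2} and more observations than \code{k_max}.
#' @param n_components number of principal components; default: fewest
#'   explaining >= 95\% variance, capped at 10.
#' @param seed RNG seed; k-means for candidate k runs under
#'   \code{seed + k}.
#' @param readouts_per_interleave readouts represented by each SI column
#'   (populations are reported in readouts).
#' @param tie_tol relative tolerance within which candidate scores count as
#'   a plateau; the largest k on the minimal plateau is selected. On data
#'   with well-separated repeating states the score is identical for every
#'   k that isolates the most populated state, and richer binning costs
#'   nothing in the selected cluster's compactness, so plateaus resolve
#'   upward (the criterion saturates toward the top of the search range on
#'   real data too).
#' @return object of class \code{cluster_assignment}: per-interleave
#'   \code{labels}, \code{k_selected}, per-cluster \code{populations}
#'   (readouts), \code{rank_order} (cluster ids by descending population),
#'   \code{centroids}, the candidate \code{scores_by_k}, \code{seed}, and a
#'   \code{degenerate} flag.
#' @export
cluster_with_selection <- function(sim, k_range = c(10, 14),
                                   n_components = NULL, seed = 1,
                                   readouts_per_interleave = 1,
                                   tie_tol = 1e-6) {
  if (inherits(sim, "si_matrix")) {
    pca <- pca_scores(sim$data, n_components)
    scores <- pca$scores
  } else {
    scores <- as.matrix(sim)
    pca <- list(n_components = ncol(scores))
  }
  n <- nrow(scores)
  k_min <- as.integer(k_range[1])
  k_max <- as.integer(k_range[length(k_range)])
  if (k_min < 2) stop_arg("k_min must be >= 2")
  if (n <= k_max)
    stop_arg("need more SI readouts (%d) than k_max (%d)", n, k_max)
  degenerate <- all(apply(scores, 2, function(v) diff(range(v)) == 0))
  if (degenerate) {
    warning("degenerate (all-identical) SI data; returning k_min")
    ks <- k_min
  } else {
    ks <- k_min:k_max
  }
  fits <- lapply(ks, function(k) run_kmeans(scores, k, seed))
  sc <- vapply(seq_along(ks), function(i)
    if (degenerate) 0 else selection_score(fits[[i]], scores), numeric(1))
  pick <- max(which(sc <= min(sc) * (1 + tie_tol)))
  km <- fits[[pick]]
  pops <- as.integer(km$size * readouts_per_interleave)
  rank_order <- order(pops, seq_along(pops), decreasing = c(TRUE, FALSE),
                      method = "radix")
  structure(list(
    labels = km$cluster, k_selected = ks[pick], populations = pops,
    rank_order = rank_order, centroids = km$centers,
    scores_by_k = stats::setNames(sc, ks), pca_components = pca$n_components,
    seed = seed, degenerate = degenerate), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: k = %d (search scores: %s)\n  populations (desc): %s\n",
    x$k_selected,
    paste(sprintf("%d:%.3g", as.integer(names(x$scores_by_k)),
                  x$scores_by_k), collapse = ", "),
    paste(x$populations[x$rank_order], collapse = ", ")))
  invisible(x)
}

#' Map cluster labels back to imaging readouts
#'
#' Every imaging (non-SI) readout of an interleave inherits the interleave's
#' cluster label; the \code{n_select} most populated clusters are returned
#' in population-rank order. This order is the cyclic adjacency used by the
#' motion-resolved reconstruction (cluster K is adjacent to cluster 1).
#'
#' @param assign a \code{cluster_assignment} with one label per interleave.
#' @param traj the matching \code{radial_trajectory}.
#' @param n_select number of clusters to keep (default 4, the
#'   motion-resolved reconstruction's cluster count).
#' @return list of integer vectors of readout indices, one per selected
#'   cluster, in population-rank order; attribute \code{cluster_ids} gives
#'   the original cluster ids.
#' @export
assign_readouts <- function(assign, traj, n_select = 4) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(traj, "radial_trajectory"))
  if (n_select > assign$k_selected)
    stop_arg("n_select (%d) exceeds the number of clusters (%d)",
             n_select, assign$k_selected)
  if (length(assign$labels) != traj$n_interleaves)
    stop_arg("labels (%d) do not match interleaves (%d)",
             length(assign$labels), traj$n_interleaves)
  keep <- assign$rank_order[seq_len(n_select)]
  imaging <- !traj$is_si
  out <- lapply(keep, function(cid) {
    which(imaging & assign$labels[traj$interleave_id] == cid)
  })
  attr(out, "cluster_ids") <- keep
  out
}
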