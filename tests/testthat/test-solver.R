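test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(soft_threshold(2 + 0i, 0.5), 1.5 + 0i)
  expect_equal(soft_threshold(3i, 1), 2i)
  expect_equal(soft_threshold(0.3 - 0.4i, 0.5), 0 + 0i)  # |v| = 0.5 <= tau
  expect_equal(soft_threshold(c(1, -2, 0), 0), c(1, -2, 0))
  v <- rand_cplx(100)
  s <- soft_threshold(v, 0.3)
  nz <- abs(v) > 0.3
  expect_equal(Arg(s[nz]), Arg(v[nz]), tolerance = 1e-12)
  expect_equal(abs(s), pmax(abs(v) - 0.3, 0), tolerance = 1e-12)
  expect_error(soft_threshold(v, -1), "tau")
})

test_that("cyclic cluster differences: constants vanish, identity fields
           reduce to the plain difference", {
  K <- 4
  xs <- lapply(seq_len(K), function(i) array(1.7 - 0.3i, c(8, 8)))
  d <- cluster_difference(xs)
  expect_true(all(vapply(d, function(v) max(abs(v)), numeric(1)) == 0))
  xs2 <- lapply(seq_len(K), function(i) array(rand_cplx(64), c(8, 8)))
  idf <- lapply(seq_len(K), function(i) identity_field(c(8, 8)))
  expect_identical(cluster_difference(xs2, idf), cluster_difference(xs2))
  expect_error(cluster_difference(xs2, idf[1:2]), "fields")
})

test_that("the composite difference operator passes an explicit-matrix
           adjoint test", {
  set.seed(41)
  K <- 3
  dims <- c(8, 8)
  n <- prod(dims)
  fields <- lapply(seq_len(K), function(i)
    deformation_field(array(rnorm(n * 2, sd = 1), c(dims, 2))))
  # dense matrix of D on the stacked space via the warp-matrix oracle
  W <- lapply(fields, warp_matrix)
  Dm <- matrix(0, K * n, K * n)
  for (i in seq_len(K)) {
    prev <- if (i == 1) K else i - 1
    ri <- (i - 1) * n + seq_len(n)
    Dm[ri, (i - 1) * n + seq_len(n)] <- W[[i]]
    Dm[ri, (prev - 1) * n + seq_len(n)] <-
      Dm[ri, (prev - 1) * n + seq_len(n)] - diag(n)
  }
  xs <- lapply(seq_len(K), function(i) array(rand_cplx(n), dims))
  ds <- lapply(seq_len(K), function(i) array(rand_cplx(n), dims))
  fwd <- cluster_difference(xs, fields)
  expect_equal(unlist(lapply(fwd, as.vector)),
               as.vector(Dm %*% unlist(lapply(xs, as.vector))),
               tolerance = 1e-12)
  adj <- cluster_difference_adjoint(ds, fields)
  expect_equal(unlist(lapply(adj, as.vector)),
               as.vector(t(Dm) %*% unlist(lapply(ds, as.vector))),
               tolerance = 1e-12)
  num <- abs(sum(Conj(unlist(fwd)) * unlist(ds)) -
               sum(Conj(unlist(xs)) * unlist(adj)))
  expect_lt(num / (sqrt(sum(abs(unlist(fwd))^2)) *
                     sqrt(sum(abs(unlist(ds))^2))), 1e-10)
})

make_toy_problem <- function(seed = 7, len = 16, K = 3, lam = 0.05) {
  set.seed(seed)
  xs_true <- lapply(seq_len(K), function(i)
    complex(real = cumsum(rnorm(len, sd = 0.3))))
  masks <- lapply(seq_len(K), function(i) {
    m <- rep(FALSE, len)
    m[sample(len, 9)] <- TRUE
    m[floor(len / 2) + 1] <- TRUE
    array(m, len)
  })
  ops <- lapply(masks, fft_mask_op)
  ys <- lapply(seq_len(K), function(i) {
    ns <- ops[[i]]$n_samples
    simbar:::op_forward(ops[[i]], array(xs_true[[i]], len)) +
      0.01 * rand_cplx(ns)
  })
  list(ys = ys, masks = masks, ops = ops, lam = lam, len = len, K = K)
}

test_that("ADMM with protocol iteration counts matches a 10k-iteration
           primal-dual reference within 0.1% objective", {
  tp <- make_toy_problem()
  cfg <- recon_config(lam = tp$lam, K = tp$K, admm_iters = 40, cg_iters = 3,
                      normalize = FALSE)
  xs <- solve_xd(tp$ys, tp$ops, sens = NULL, fields = NULL, cfg = cfg)
  obj_admm <- utils::tail(xs$log$objective, 1)
  ref <- reference_pd_solve(tp$ys, tp$masks, tp$lam)
  obj_ref <- toy_objective(ref, tp$ys, tp$masks, tp$lam)
  expect_lt(abs(obj_admm - obj_ref) / obj_ref, 1e-3)
  # the logged objective is the true objective of the returned volumes
  expect_equal(toy_objective(lapply(xs$volumes, as.vector), tp$ys, tp$masks,
                             tp$lam), obj_admm, tolerance = 1e-8)
})

test_that("with lambda = 0 the solver matches the conjugate-gradient
           least-squares solution", {
  tp <- make_toy_problem(seed = 9)
  cfg <- recon_config(lam = 0, K = tp$K, admm_iters = 4, cg_iters = 30,
                      normalize = FALSE)
  xs <- solve_xd(tp$ys, tp$ops, sens = NULL, fields = NULL, cfg = cfg)
  # independent LS solution per cluster in closed form (masked unitary DFT)
  for (i in seq_len(tp$K)) {
    yfull <- rep(0i, tp$len)
    yfull[tp$masks[[i]]] <- tp$ys[[i]]
    xhat <- yfull  # A^+ y: unsampled modes stay zero
    x_ls <- as.vector(simbar:::cdft_adj(array(xhat, tp$len)) / sqrt(tp$len))
    expect_lt(max(abs(as.vector(xs$volumes[[i]]) - x_ls)) /
                max(abs(x_ls)), 1e-3)
  }
})

test_that("identity deformation fields reproduce the field-free solution", {
  set.seed(11)
  dims <- c(12, 12)
  K <- 3
  masks <- lapply(seq_len(K), function(i)
    array(runif(prod(dims)) < 0.5, dims))
  ops <- lapply(masks, fft_mask_op)
  xs_true <- lapply(seq_len(K), function(i)
    array(rand_cplx(prod(dims)), dims))
  ys <- lapply(seq_len(K), function(i)
    simbar:::op_forward(ops[[i]], xs_true[[i]]))
  cfg <- recon_config(lam = 0.05, K = K, admm_iters = 15, cg_iters = 3,
                      normalize = FALSE)
  xs0 <- solve_xd(ys, ops, sens = NULL, fields = NULL, cfg = cfg)
  idf <- lapply(seq_len(K), function(i) identity_field(dims))
  xs1 <- solve_xd(ys, ops, sens = NULL, fields = idf, cfg = cfg)
  for (i in seq_len(K)) {
    expect_lt(max(abs(xs1$volumes[[i]] - xs0$volumes[[i]])) /
                max(abs(xs0$volumes[[i]])), 1e-10)
  }
})

test_that("increasing lambda never increases the L1/data ratio trade-off", {
  tp <- make_toy_problem(seed = 13)
  ratios <- vapply(c(0.03, 0.3, 3), function(l) {
    cfg <- recon_config(lam = l, K = tp$K, admm_iters = 30, cg_iters = 3,
                        normalize = FALSE)
    xs <- solve_xd(tp$ys, tp$ops, sens = NULL, fields = NULL, cfg = cfg)
    lg <- utils::tail(xs$log, 1)
    lg$l1 / max(lg$data, 1e-12)
  }, numeric(1))
  expect_true(all(diff(ratios) <= 1e-9))
})

test_that("primal feasibility improves over the ADMM run", {
  tp <- make_toy_problem(seed = 15)
  cfg <- recon_config(lam = tp$lam, K = tp$K, admm_iters = 30, cg_iters = 3,
                      normalize = FALSE)
  xs <- solve_xd(tp$ys, tp$ops, sens = NULL, fields = NULL, cfg = cfg)
  gaps <- xs$log$primal_gap
  expect_lt(utils::tail(gaps, 1), gaps[1])
})

test_that("configuration defaults follow the whole-heart protocol", {
  cfg <- recon_config()
  expect_equal(cfg$lam, 0.3)
  expect_equal(cfg$K, 4)
  expect_equal(cfg$admm_iters, 40)
  expect_equal(cfg$cg_iters, 3)
  expect_equal(cfg$rho, cfg$lam)
  expect_true(cfg$normalize)
  expect_error(recon_config(lam = -1), "lam")
  expect_error(recon_config(K = 1), "K")
  expect_error(recon_config(admm_iters = 0), "iteration")
})

test_that("the selected output is the most populated cluster's volume", {
  tp <- make_toy_problem(seed = 17)
  cfg <- recon_config(lam = tp$lam, K = tp$K, admm_iters = 5, cg_iters = 3,
                      normalize = FALSE)
  xs <- solve_xd(tp$ys, tp$ops, sens = NULL, fields = NULL, cfg = cfg)
  a <- structure(list(rank_order = c(3L, 1L, 2L)),
                 class = "cluster_assignment")
  out <- select_output(xs, a)
  expect_equal(as.vector(out), as.vector(xs$volumes[[1]]))
  expect_equal(attr(out, "cluster_id"), 3L)
  expect_equal(as.vector(select_output(xs)), as.vector(xs$volumes[[1]]))
})
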