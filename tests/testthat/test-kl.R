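test_that("pivoted Cholesky terminates exactly on planted low-rank input", {
  set.seed(41)
  v <- rnorm(30)
  cfun <- function(p) v * v[p]
  pc <- pivoted_cholesky(v^2, cfun, tol = 1e-10)
  expect_identical(pc$rank, 1L)
  expect_lt(max(abs(tcrossprod(pc$L) - outer(v, v))), 1e-10)
  # identity covariance admits no compression
  n <- 17L
  pc2 <- pivoted_cholesky(rep(1, n), function(p) {
    e <- numeric(n); e[p] <- 1; e
  }, tol = 1e-4)
  expect_identical(pc2$rank, n)
})

test_that("the factor matches a dense eigendecomposition at the tolerance", {
  geom <- default_torso()
  kl <- build_kl(geom, tol = 1e-4, n_sigma = 25L,
                 times = geom$times[c(1, 26)])   # 100 dof
  np <- 2L * 25L
  pos <- kl$mean
  tidx <- rep(kl$times, each = 25L)
  dmat <- as.matrix(stats::dist(pos))
  ktime <- outer(tidx, tidx, temporal_kernel, period = geom$period)
  cfull <- rbind(cbind(matern_kernel(dmat, 2.5) * ktime, matrix(0, np, np)),
                 cbind(matrix(0, np, np), matern_kernel(dmat, Inf) * ktime))
  resid <- cfull - tcrossprod(kl$modes)
  # trace residual of the factorisation: within tolerance, and the
  # internal bookkeeping agrees with the dense recomputation
  expect_lt(sum(diag(resid)), 1e-4 * sum(diag(cfull)))
  expect_lt(abs(sum(diag(resid)) - kl$trace_residual), 1e-10 * kl$trace)
  # trace-norm agreement with the eigendecomposition oracle
  ev <- eigen(resid, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(sum(abs(ev)), 2e-4 * sum(diag(cfull)))
  # residual sequence of the greedy factorisation is non-increasing
  pc <- pivoted_cholesky(diag(cfull), function(p) cfull[, p], tol = 1e-6)
  expect_true(all(diff(pc$residuals) <= 1e-12 * pc$trace))
})

test_that("sampling is affine in xi with the reference as its mean", {
  snap <- default_snapshot()
  kl <- snap$kl
  k <- kl$rank
  ref <- sample_deformation(kl, rep(0, k), 1L)
  expect_equal(eval_curve(ref, collocation_grid(kl$n_sigma))$point,
               kl$mean, tolerance = 1e-10)
  set.seed(51)
  xi <- runif(k, -1, 1)
  p0 <- eval_curve(sample_deformation(kl, 0 * xi, 1L, check = "none"),
                   collocation_grid(kl$n_sigma))$point
  p1 <- eval_curve(sample_deformation(kl, xi, 1L, check = "none"),
                   collocation_grid(kl$n_sigma))$point
  ph <- eval_curve(sample_deformation(kl, xi / 2, 1L, check = "none"),
                   collocation_grid(kl$n_sigma))$point
  expect_equal(ph - p0, (p1 - p0) / 2, tolerance = 1e-10)
  expect_error(sample_deformation(kl, rep(2, k), 1L), "\\[-1, 1\\]")
  expect_error(sample_deformation(kl, xi, 99L), "time index")
})

test_that("sampled displacement variance matches the closed form", {
  snap <- default_snapshot()
  kl <- snap$kl
  qmc <- halton_rule(kl$rank, 1e4)
  disp <- kl$modes %*% t(qmc$nodes)       # dof x N displacements
  emp <- rowMeans(disp^2)                 # mean is zero by symmetry
  ana <- rowSums(kl$modes^2) / 3
  keep <- ana > 1e-3 * max(ana)
  expect_lt(max(abs(emp[keep] / ana[keep] - 1)), 0.05)
  # shape_std reports the same field, per component
  ss <- shape_std(kl)
  np <- kl$n_sigma
  expect_equal(ss[, 1], sqrt(ana[seq_len(np)]), tolerance = 1e-12)
  expect_equal(ss[, 2], sqrt(ana[np + seq_len(np)]), tolerance = 1e-12)
})

test_that("shape standard deviation follows the uniform-variance rule", {
  kl <- default_snapshot()$kl
  z <- kl; z$modes <- kl$modes * 0
  expect_true(all(shape_std(z) == 0))
  one <- kl; one$modes <- matrix(0.9, nrow(kl$modes), 1)
  expect_equal(shape_std(one)[1, 1], 0.9 / sqrt(3), tolerance = 1e-12)
  perm <- kl; perm$modes <- kl$modes[, sample(ncol(kl$modes))]
  expect_equal(shape_std(perm), shape_std(kl), tolerance = 1e-12)
})

test_that("inadmissible deformations are refused with a located error", {
  kl <- default_snapshot()$kl
  big <- kl
  big$modes <- kl$modes * 60   # tens of mm: guaranteed to leave the chest
  xi <- rep(1, big$rank)
  expect_error(sample_deformation(big, xi, 1L), "instant 1")
})

test_that("a KL directory round-trips through CSV + manifest", {
  geom <- default_torso()
  kl <- build_kl(geom, tol = 1e-2, n_sigma = 12L, times = geom$times[1:2])
  dir <- withr::local_tempdir()
  write_kl(kl, dir)
  back <- read_kl(dir, geometry = geom)
  expect_equal(back$modes, kl$modes, tolerance = 1e-15)
  expect_equal(back$mean, kl$mean, tolerance = 1e-15)
  expect_identical(back$rank, kl$rank)
  expect_equal(back$model$rho, kl$model$rho)
})
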