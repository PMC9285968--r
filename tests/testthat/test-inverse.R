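# a transparent diagonal stand-in for the transfer operators
diag_ops <- function(n = 8L, a = rep(1, n)) {
  structure(list(A = diag(a, n), B = diag(1, n),
                 s_sigma = rep(1, n), s_gamma = rep(1, n),
                 n_sigma = n, n_gamma = n),
            class = "transfer_operators")
}

test_that("regularisation matrices take their prescribed forms", {
  bl <- annulus_blocks(1, 2, 64L)
  ops <- build_transfer(bl)
  # zero order: the mass matrix itself
  m0 <- regularisation_matrix(regularisation_spec("tik0"),
                              build_transfer(annulus_blocks(1, 2, 10L)))
  expect_equal(m0, diag(2 * pi / 10, 10), tolerance = 1e-12)
  # first order and H1/2 are symmetric by construction
  m1 <- regularisation_matrix(regularisation_spec("tik1"), ops)
  mh <- regularisation_matrix(regularisation_spec("h12"), ops)
  expect_identical(mh, t(mh))
  expect_equal(m1, t(m1), tolerance = 1e-14)
  # lagged-diffusivity weights at u0 = 0: 1 / (2 sqrt(beta))
  dops <- diag_ops(6L)
  mtv <- regularisation_matrix(regularisation_spec("tv"), dops,
                               u0 = rep(0, 6))
  expect_equal(diag(mtv), rep(1 / (2 * sqrt(1e-5)), 6), tolerance = 1e-9)
  expect_equal(mtv[1, 1], 158.1139, tolerance = 1e-4)
  expect_error(regularisation_matrix(regularisation_spec("tv"), dops),
               "u0")
})

test_that("the normal equations reduce to the scalar shrinkage formula", {
  ops <- diag_ops(8L)
  yd <- rnorm(8)
  for (lam in c(0.1, 1, 10)) {
    u <- inverse_solve(ops, yd, regularisation_spec("tik0", lam),
                       check = TRUE)
    expect_equal(u, yd / (1 + lam^2), tolerance = 1e-12)
  }
  # enormous lambda shrinks the solution to zero
  u <- inverse_solve(ops, yd, regularisation_spec("tik0", 1e6))
  expect_lt(max(abs(u)), 1e-6 * max(abs(yd)))
})

test_that("noiseless annulus data are reconstructed to 1e-3", {
  bl <- annulus_blocks(1, 2, 128L)
  ops <- build_transfer(bl)
  s <- collocation_grid(128L)
  u_true <- cos(2 * pi * s)
  yd <- as.numeric(ops$A %*% u_true)
  u <- inverse_solve(ops, yd, regularisation_spec("tik0", 1e-6))
  expect_lt(sqrt(mean((u - u_true)^2)) / sqrt(mean(u_true^2)), 1e-3)
})

test_that("quadratic solutions are the unique minimisers of the objective", {
  bl <- annulus_blocks(1, 2, 32L)
  ops <- build_transfer(bl)
  set.seed(5)
  yd <- as.numeric(ops$A %*% cos(2 * pi * collocation_grid(32L))) +
    rnorm(32L, 0, 1e-4)
  for (kind in c("tik0", "tik1", "h12")) {
    spec <- regularisation_spec(kind, 1e-3)
    u <- inverse_solve(ops, yd, spec)
    m <- regularisation_matrix(spec, ops)
    objective <- function(v) {
      r <- as.numeric(ops$A %*% v) - yd
      0.5 * sum(r^2 * ops$s_gamma) + spec$lambda^2 * sum(v * (m %*% v))
    }
    j0 <- objective(u)
    for (i in 1:5) {
      d <- rnorm(32L); d <- d / sqrt(sum(d^2)) * 1e-6 * sqrt(sum(u^2))
      # second difference: the first-order terms cancel, leaving the
      # (positive definite) curvature d' H d, robust to round-off
      expect_gt(objective(u + d) + objective(u - d) - 2 * j0, 0)
      # one-sided increases hold up to the round-off of the objective
      expect_gte(objective(u + d), j0 - 1e-11)
      expect_gte(objective(u - d), j0 - 1e-11)
    }
  }
})

test_that("solutions vary continuously along the lambda grid", {
  bl <- annulus_blocks(1, 2, 32L)
  ops <- build_transfer(bl)
  yd <- as.numeric(ops$A %*% cos(2 * pi * collocation_grid(32L)))
  lambdas <- 10^seq(-6, 0, length.out = 13)
  for (kind in c("tik0", "tik1", "h12")) {
    norms <- vapply(lambdas, function(l)
      sqrt(sum(inverse_solve(ops, yd, regularisation_spec(kind, l))^2)), 1)
    expect_lt(max(norms[-1] / norms[-13], norms[-13] / norms[-1]), 10)
  }
})

test_that("the L-curve picks the maximal-curvature corner", {
  bl <- annulus_blocks(1, 2, 32L)
  ops <- build_transfer(bl)
  set.seed(8)
  yd <- as.numeric(ops$A %*% cos(2 * pi * collocation_grid(32L))) +
    rnorm(32L, 0, 1e-4)
  lambdas <- 10^seq(-8, 0, length.out = 17)
  sel <- l_curve_select(ops, yd, "tik0", lambdas)
  tab <- sel$table
  # monotone trade-off along the curve
  expect_true(all(diff(tab$residual) >= -1e-10 * tab$residual[-1]))
  expect_true(all(diff(tab$penalty) <= 1e-10 * tab$penalty[-1]))
  # brute-force curvature recomputation from the returned table
  x <- log(tab$residual); y <- log(tab$penalty)
  i <- 2:(nrow(tab) - 1)
  dx <- (x[i + 1] - x[i - 1]) / 2; dy <- (y[i + 1] - y[i - 1]) / 2
  ddx <- x[i + 1] - 2 * x[i] + x[i - 1]; ddy <- y[i + 1] - 2 * y[i] + y[i - 1]
  curv <- abs(dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
  expect_equal(sel$lambda, tab$lambda[i[max(which(curv == max(curv)))]])
  # a time series of identical problems returns the single-step choice
  sel3 <- l_curve_select(ops, cbind(yd, yd, yd), "tik0", lambdas)
  expect_identical(sel3$lambda, sel$lambda)
  expect_identical(sel3$per_step, rep(sel$lambda, 3))
  expect_error(l_curve_select(ops, yd, "tik0", 10^seq(-4, 0, length.out = 5)),
               "at least 9")
})

test_that("h12 reconstructs the reference potential with its selected lambda", {
  snap <- default_snapshot()
  geom <- default_torso()
  n <- snap$n_sigma
  cache <- snap$cache
  num <- den <- 0
  lambda <- NULL
  for (j in seq(1, 50, by = 10)) {
    bl <- assemble_blocks(geom$pericardium[[j]], geom$chest, n,
                          chest_cache = cache)
    ops <- build_transfer(bl)
    u_true <- reference_potential(collocation_grid(n), geom$times[j])
    yd <- as.numeric(add_noise(forward_solve(bl, u_true), 1e-8, j)$y)
    if (is.null(lambda)) lambda <- l_curve_select(ops, yd, "h12")$lambda
    u <- inverse_solve(ops, yd, regularisation_spec("h12", lambda))
    num <- num + sum((u - u_true)^2 * ops$s_sigma)
    den <- den + sum(u_true^2 * ops$s_sigma)
  }
  expect_lt(sqrt(num / den), 0.25)
})
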