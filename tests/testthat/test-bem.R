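test_that("single-layer quadrature reproduces the circle closed form", {
  # V (constant density 1) on a circle of radius a equals -a log a
  for (a in c(1, 2)) {
    cc <- chest_blocks_cache(circle_curve(a, "chest"), 128L)
    v1 <- cc$v_gg %*% cc$ev$speed       # rho = 1, speed-weighted density
    expect_lt(max(abs(v1 - (-a * log(a)))), 1e-10)
  }
})

test_that("double-layer row sums satisfy the Gauss jump identity", {
  # single closed curve with outward normal: K 1 = -1/2
  for (crv in list(circle_curve(2, "chest"),
                   fit_fourier_curve(sample_points(function(s)
                     c(3 * cos(2 * pi * s), sin(2 * pi * s)), 64L),
                     threshold = 1e-6))) {
    cc <- chest_blocks_cache(crv, 128L)
    expect_lt(max(abs(cc$k_gg %*% rep(1, 128L) + 0.5)), 1e-8)
  }
  # two-component boundary with exterior normals:
  # (1/2 I + K_dD) 1 = 0 on both components
  bl <- annulus_blocks()
  n <- bl$n_sigma
  kdd <- rbind(cbind(bl$k_ss, bl$k_sg), cbind(bl$k_gs, bl$k_gg))
  expect_lt(max(abs(kdd %*% rep(1, 2 * n) + 0.5)), 1e-6)
})

test_that("mass matrices carry the trapezoidal arc-length weights", {
  m <- mass_matrix(circle_curve(1, "chest"), 10L)
  expect_equal(diag(m), rep(2 * pi / 10, 10), tolerance = 1e-14)
  expect_equal(sum(diag(m)), 2 * pi, tolerance = 1e-14)
  # ellipse: trace matches adaptive arc-length integration
  ell <- closed_curve(c(0, 3), c(0, 0), c(0, 0), c(0, 1), role = "chest")
  len <- stats::integrate(function(t)
    sqrt(9 * sin(t)^2 + cos(t)^2), 0, 2 * pi, rel.tol = 1e-13)$value
  expect_lt(abs(sum(diag(mass_matrix(ell, 256L))) - len), 1e-10)
  expect_error(mass_matrix(ell, 2L), "at least 4")
})

test_that("the annulus boundary value problem matches separation of variables", {
  bl <- annulus_blocks(1, 2, 128L)
  s <- collocation_grid(128L)
  # constants: unit trace, zero flux
  solc <- solve_bvp(bl, rep(1, 128L))
  expect_lt(max(abs(solc$rho0_gamma - 1)), 1e-8)
  expect_lt(max(abs(solc$rho1_sigma)), 1e-8)
  # m = 1: chest amplitude 0.8, Steklov amplitude 0.6
  sol1 <- solve_bvp(bl, cos(2 * pi * s))
  expect_lt(max(abs(sol1$rho0_gamma - annulus_chest_amp(1, 2, 1) *
                      cos(2 * pi * s))), 1e-8)
  expect_lt(max(abs(sol1$rho1_sigma - 0.6 * cos(2 * pi * s))), 1e-8)
  # m = 2: chest amplitude 8/17
  sol2 <- solve_bvp(bl, cos(4 * pi * s))
  expect_lt(max(abs(sol2$rho0_gamma - (8 / 17) * cos(4 * pi * s))), 1e-8)
  # speed-weighted vs plain Neumann density
  expect_equal(sol1$rho1_sigma, sol1$rho1t_sigma / bl$ev_sigma$speed,
               tolerance = 1e-14)
})

test_that("transfer operators preserve constants and match the Schur path", {
  bl <- annulus_blocks(1, 2, 128L)
  ops <- build_transfer(bl)
  one <- rep(1, 128L)
  expect_lt(max(abs(ops$A %*% one - 1)), 1e-8)
  expect_lt(max(abs(ops$B %*% one)), 1e-8)
  # V cross blocks are mutual transposes on matching grids
  expect_lt(max(abs(bl$v_gs - t(bl$v_sg))), 1e-14)
  # Schur-complement path (radius != 1 so V_SS is invertible)
  bl2 <- assemble_blocks(circle_curve(0.5, "pericardium"),
                         circle_curve(2, "chest"), 128L)
  o1 <- build_transfer(bl2)
  o2 <- build_transfer(bl2, method = "schur")
  expect_lt(max(abs(o1$A - o2$A)) / max(abs(o1$A)), 1e-10)
  expect_lt(max(abs(o1$B - o2$B)) / max(abs(o1$B)), 1e-10)
})

test_that("the collocation solution self-converges spectrally", {
  geom <- default_torso()
  peri <- geom$pericardium[[1]]
  uf <- function(s) cos(2 * pi * s) + 0.3 * sin(4 * pi * s)
  tr <- function(n) {
    bl <- assemble_blocks(peri, geom$chest, n, n)
    solve_bvp(bl, uf(collocation_grid(n)))$rho0_gamma
  }
  ref <- tr(512L)
  coarse <- tr(128L)
  expect_lt(max(abs(coarse - ref[seq(1, 512, by = 4)])),
            1e-8 * max(abs(ref)))
})

test_that("degenerate assembly inputs are rejected", {
  expect_error(assemble_blocks(circle_curve(2, "pericardium"),
                               circle_curve(2, "chest"), 64L),
               "collide")
  expect_error(assemble_blocks(circle_curve(1, "chest"),
                               circle_curve(2, "chest"), 64L),
               "pericardium")
  expect_error(kress_weights(63L), "even")
})
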