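test_that("exact low-order shapes are recovered at their true order", {
  # circle of radius 2: order-1 curve, zero residual
  pts <- sample_points(function(s) 2 * c(cos(2 * pi * s), sin(2 * pi * s)),
                       64L)
  crv <- fit_fourier_curve(pts, threshold = 1e-3)
  expect_identical(crv$order, 1L)
  expect_lt(attr(crv, "rel_rmse"), 1e-12)

  # rotated ellipse: still exactly order 1; verify the fit reproduces the
  # points directly (independent check of the least-squares solution)
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- sample_points(function(s)
    rot %*% c(3 * cos(2 * pi * s), sin(2 * pi * s)), 128L)
  crv <- fit_fourier_curve(pts, threshold = 1e-3)
  expect_identical(crv$order, 1L)
  fitted <- eval_curve(crv, collocation_grid(128L))$point
  expect_lt(max(abs(fitted - pts)), 1e-10)
})

test_that("a high harmonic above the threshold forces a high-order fit", {
  # 5th-harmonic radial bump of relative amplitude 5%: spectral energy at
  # harmonics 4 and 6 far exceeds the 1e-3 threshold, so M >= 5
  pts <- sample_points(function(s) {
    r <- 2 * (1 + 0.05 * cos(10 * pi * s))
    r * c(cos(2 * pi * s), sin(2 * pi * s))
  }, 64L)
  crv <- fit_fourier_curve(pts, threshold = 1e-3)
  expect_gte(crv$order, 5L)
})

test_that("degenerate fitting inputs are rejected", {
  pts_bow <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1, -1, 0.5, 2, 0.5,
                      0.5, -1, 0.5, 2), ncol = 2, byrow = TRUE)
  expect_error(fit_fourier_curve(pts_bow), "not simple")
  expect_error(fit_fourier_curve(matrix(rnorm(10), 5, 2)), "at least 8")
  # simple star polygon with rough radii: unreachable threshold reports
  # the achieved error
  set.seed(4)
  r <- 1 + 0.3 * runif(16)
  pts <- cbind(r * cos(2 * pi * (0:15) / 16), r * sin(2 * pi * (0:15) / 16))
  expect_error(fit_fourier_curve(pts, threshold = 1e-16),
               "unreachable.*achieved")
})

test_that("curve evaluation returns the exact differential geometry", {
  crv <- circle_curve(2, "chest")
  ev <- eval_curve(crv, 0)
  expect_equal(ev$point[1, ], c(2, 0), tolerance = 1e-14)
  expect_equal(ev$speed, 4 * pi, tolerance = 1e-12)
  expect_equal(ev$curvature, 1 / 2, tolerance = 1e-12)
  # chest normal is outward
  expect_equal(eval_curve(crv, 0.25)$normal[1, ], c(0, 1), tolerance = 1e-12)
  # pericardium normal is exterior to the torso: towards the cavity
  peri <- circle_curve(1, "pericardium")
  expect_equal(eval_curve(peri, 0)$normal[1, ], c(-1, 0), tolerance = 1e-12)
  # 1-periodicity to round-off
  s <- runif(5)
  expect_equal(eval_curve(crv, s)$point, eval_curve(crv, s + 1)$point,
               tolerance = 1e-12)
})

test_that("orientation is normalised and enforced", {
  pts <- sample_points(function(s) c(cos(2 * pi * s), sin(2 * pi * s)), 32L)
  cw <- pts[c(1, 32:2), ]            # clockwise ordering
  crv <- fit_fourier_curve(cw, threshold = 1e-6)
  pts2 <- eval_curve(crv, collocation_grid(64L))$point
  nxt <- c(2:64, 1)
  shoelace <- sum(pts2[, 1] * pts2[nxt, 2] - pts2[nxt, 1] * pts2[, 2]) / 2
  expect_gt(shoelace, 0)   # counterclockwise
  expect_error(closed_curve(c(0, 1), c(0, 0), c(0, 0), c(0, -1)),
               "counterclockwise")
})

test_that("balanced interpolation is exact at the nodes and round-trips", {
  set.seed(11)
  base <- sample_points(function(s)
    c(cos(2 * pi * s) * (1.5 + 0.2 * cos(6 * pi * s)),
      sin(2 * pi * s) * (1.2 + 0.1 * sin(4 * pi * s))), 32L)
  crv <- interp_closed_curve(base)
  expect_lt(max(abs(eval_curve(crv, collocation_grid(32L))$point - base)),
            1e-10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(crv, path)
  back <- read_curve(path, role = "chest")
  expect_equal(back$ax, crv$ax, tolerance = 1e-15)
  expect_equal(back$by, crv$by, tolerance = 1e-15)
  expect_error(read_curve(withr::local_tempfile(lines = "a,b\n1,2"),
                          role = "chest"),
               "malformed")
})
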