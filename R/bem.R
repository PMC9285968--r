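#' Quadrature weights for the periodic logarithmic kernel
#'
#' Weight matrix `R[i, j]` such that, for a trigonometric polynomial `f`,
#' \deqn{\int_0^{2\pi} \log(4\sin^2((\tau_i - \tau)/2))\, f(\tau)\, d\tau
#'   \approx \sum_j R_{ij} f(\tau_j)} on the uniform grid
#' `tau_j = 2 pi j / n`.  The rule is exact for trigonometric polynomials
#' of degree below `n/2`, which yields spectral accuracy of the single
#' layer operator on analytic curves.
#'
#' @param n Even number of quadrature points.
#' @return An `n x n` matrix.
#' @export
kress_weights <- function(n) {
  if (n %% 2L != 0L) stopf("the log-kernel quadrature requires even n")
  d <- 0:(n - 1)
  m <- seq_len(n %/% 2L - 1L)
  rv <- -(4 * pi / n) * as.numeric(cos(2 * pi * outer(d, m) / n) %*% (1 / m)) -
    (4 * pi / n^2) * cos(pi * d)
  idx <- (outer(0:(n - 1), 0:(n - 1), "-")) %% n
  matrix(rv[idx + 1L], n, n)
}

# per-n cache of the log-kernel weight matrix and of the periodic
# 4 sin^2((tau_i - tau_j)/2) factor, reused across assemblies
.bem_cache <- new.env(parent = emptyenv())

kress_cache <- function(n) {
  key <- as.character(n)
  hit <- .bem_cache[[key]]
  if (!is.null(hit)) return(hit)
  tau <- 2 * pi * collocation_grid(n)
  s4 <- 4 * sin(outer(tau, tau, "-") / 2)^2
  diag(s4) <- 1  # unused on the diagonal; avoids log(0)
  val <- list(rmat = kress_weights(n), s4 = s4)
  .bem_cache[[key]] <- val
  val
}

# differential geometry of the balanced trigonometric interpolant through
# uniformly sampled points, via spectral differentiation (exactly the
# quantities eval_curve() returns for interp_closed_curve(points) at the
# sample nodes, at O(n log n) cost)
ev_from_points <- function(points, role) {
  n <- nrow(points)
  cx <- stats::fft(points[, 1]) / n
  cy <- stats::fft(points[, 2]) / n
  kk <- 0:(n - 1)
  kk <- ifelse(kk <= n %/% 2L, kk, kk - n)
  w1 <- 2i * pi * kk
  if (n %% 2L == 0L) w1[n %/% 2L + 1L] <- 0  # cosine Nyquist: zero at nodes
  w2 <- -(2 * pi * kk)^2
  dx <- Re(stats::fft(cx * w1, inverse = TRUE))
  dy <- Re(stats::fft(cy * w1, inverse = TRUE))
  ddx <- Re(stats::fft(cx * w2, inverse = TRUE))
  ddy <- Re(stats::fft(cy * w2, inverse = TRUE))
  speed <- sqrt(dx^2 + dy^2)
  sgn <- if (role == "chest") 1 else -1
  list(point = points,
       tangent = cbind(dx, dy) / speed,
       normal = cbind(sgn * dy, -sgn * dx) / speed,
       speed = speed,
       curvature = (dx * ddy - dy * ddx) / speed^3)
}

# same-curve single layer matrix acting on the speed-weighted density
# rho_tilde = rho * ||gamma'(s)||, collocated at s_i = i/n; d2 is the
# matrix of squared point distances, kc the kress_cache(n) value
single_layer_self <- function(ev, n, d2, kc) {
  sm <- log(d2 / kc$s4)
  diag(sm) <- 2 * log(ev$speed / (2 * pi))
  -(kc$rmat + (2 * pi / n) * sm) / (8 * pi^2)
}

# double layer matrix acting on plain trace values: trapezoid of the
# kernel (1/2pi) <x - x', n(x')> / ||x - x'||^2 times speed/n, with the
# curvature limit on the (same-curve) diagonal; dx, dy, d2 are the
# row-minus-column coordinate difference and squared distance matrices
double_layer_block <- function(dx, dy, d2, ev_col, n_col, same = FALSE,
                               role_sign = 1) {
  nr <- nrow(dx)
  wx <- ev_col$normal[, 1] * ev_col$speed / (2 * pi * n_col)
  wy <- ev_col$normal[, 2] * ev_col$speed / (2 * pi * n_col)
  kk <- (dx * rep(wx, each = nr) + dy * rep(wy, each = nr)) / d2
  if (same)
    diag(kk) <- -role_sign * ev_col$curvature * ev_col$speed / (4 * pi * n_col)
  kk
}

#' Assemble the collocation blocks of the boundary integral operators
#'
#' Builds the eight dense Nystrom matrices of the single (`V`) and double
#' (`K`) layer operators restricted to the pericardium (Sigma) and chest
#' (Gamma) boundary components, on the uniform collocation grids
#' `s_i = i/n`.  Same-boundary single-layer blocks use the logarithmic
#' kernel splitting quadrature of [kress_weights()]; same-boundary
#' double-layer diagonals use the curvature limit of the kernel;
#' off-boundary blocks are plain trapezoidal rules (spectrally accurate
#' for disjoint analytic curves).  The `V` blocks act on speed-weighted
#' Neumann densities, the `K` blocks on plain Dirichlet traces, matching
#' the block linear system solved by [solve_bvp()].
#'
#' @param curve_sigma Pericardium [closed_curve()].
#' @param curve_gamma Chest [closed_curve()].
#' @param n_sigma,n_gamma Numbers of collocation points (even).
#' @param chest_cache Optional value of [chest_blocks_cache()] to reuse the
#'   fixed chest-chest blocks across assemblies with varying pericardium.
#' @return An object of class `boundary_blocks`.
#' @export
assemble_blocks <- function(curve_sigma, curve_gamma, n_sigma = 128L,
                            n_gamma = n_sigma, chest_cache = NULL) {
  if (curve_sigma$role != "pericardium" || curve_gamma$role != "chest")
    stopf("expected a pericardium curve and a chest curve")
  es <- eval_curve(curve_sigma, collocation_grid(n_sigma))
  if (is.null(chest_cache))
    chest_cache <- chest_blocks_cache(curve_gamma, n_gamma)
  assemble_blocks_ev(es, chest_cache, n_sigma)
}

# assembly from a precomputed Sigma evaluation (hot path of the
# uncertainty-quantification loops)
assemble_blocks_ev <- function(es, chest_cache, n_sigma) {
  eg <- chest_cache$ev
  n_gamma <- chest_cache$n
  # same-boundary Sigma blocks
  dxs <- outer(es$point[, 1], es$point[, 1], "-")
  dys <- outer(es$point[, 2], es$point[, 2], "-")
  d2s <- dxs^2 + dys^2
  diag(d2s) <- 1
  v_ss <- single_layer_self(es, n_sigma, d2s, kress_cache(n_sigma))
  k_ss <- double_layer_block(dxs, dys, d2s, es, n_sigma, same = TRUE,
                             role_sign = -1)
  # cross blocks: plain trapezoid of the smooth kernels
  dxc <- outer(es$point[, 1], eg$point[, 1], "-")
  dyc <- outer(es$point[, 2], eg$point[, 2], "-")
  d2c <- dxc^2 + dyc^2
  if (min(d2c) < 1e-20 * max(d2c))
    stopf("pericardium and chest collocation points collide")
  g_sg <- -log(d2c) / (4 * pi)   # G(x_sigma, x_gamma); log d^2 halves the 2 pi
  v_sg <- g_sg / n_gamma         # acts on speed-weighted Gamma density
  v_gs <- t(g_sg) / n_sigma      # acts on speed-weighted Sigma density
  k_sg <- double_layer_block(dxc, dyc, d2c, eg, n_gamma)
  k_gs <- double_layer_block(-t(dxc), -t(dyc), t(d2c), es, n_sigma)
  structure(list(
    v_ss = v_ss, v_sg = v_sg, v_gs = v_gs, v_gg = chest_cache$v_gg,
    k_ss = k_ss, k_sg = k_sg, k_gs = k_gs, k_gg = chest_cache$k_gg,
    ev_sigma = es, ev_gamma = eg,
    n_sigma = n_sigma, n_gamma = n_gamma),
    class = "boundary_blocks")
}

#' Precompute the fixed chest-chest blocks
#'
#' The chest is fixed over time and not subject to uncertainty, so its
#' same-boundary blocks can be assembled once and reused for every
#' deformed pericardium.
#'
#' @param curve_gamma Chest [closed_curve()].
#' @param n_gamma Number of collocation points (even).
#' @return A list with the chest evaluation and the `V`, `K` chest-chest
#'   blocks.
#' @export
chest_blocks_cache <- function(curve_gamma, n_gamma) {
  eg <- eval_curve(curve_gamma, collocation_grid(n_gamma))
  dx <- outer(eg$point[, 1], eg$point[, 1], "-")
  dy <- outer(eg$point[, 2], eg$point[, 2], "-")
  d2 <- dx^2 + dy^2
  diag(d2) <- 1
  v_gg <- single_layer_self(eg, n_gamma, d2, kress_cache(n_gamma))
  k_gg <- double_layer_block(dx, dy, d2, eg, n_gamma, same = TRUE,
                             role_sign = 1)
  list(ev = eg, n = n_gamma, v_gg = v_gg, k_gg = k_gg)
}

#' Diagonal mass matrix of the trapezoidal inner product
#'
#' Entries \eqn{\|\gamma'(s_i)\|/n}; the trace is the trapezoidal estimate
#' of the curve length.
#'
#' @param curve A [closed_curve()].
#' @param n Number of collocation points (`n >= 4`).
#' @return An `n x n` diagonal matrix.
#' @export
mass_matrix <- function(curve, n) {
  if (n < 4) stopf("n must be at least 4")
  diag(eval_curve(curve, collocation_grid(n))$speed / n, n, n)
}

#' Solve the discrete mixed boundary value problem
#'
#' Solves the 2x2 block linear system of the collocation discretisation
#' for given pericardial Dirichlet values `u`: unknowns are the
#' speed-weighted Neumann density on the pericardium and the chest trace.
#'
#' @param blocks A [assemble_blocks()] result.
#' @param u Pericardial potential values at the Sigma collocation points
#'   (vector of length `n_sigma`, or a matrix with one column per
#'   right-hand side).
#' @return A list with `rho0_gamma` (chest trace), `rho1t_sigma`
#'   (speed-weighted normal derivative) and `rho1_sigma` (normal
#'   derivative values).
#' @export
solve_bvp <- function(blocks, u) {
  u <- as.matrix(u)
  if (nrow(u) != blocks$n_sigma)
    stopf("u must have length n_sigma = %d", blocks$n_sigma)
  ns <- blocks$n_sigma; ng <- blocks$n_gamma
  lhs <- matrix(0, ns + ng, ns + ng)
  lhs[seq_len(ns), seq_len(ns)] <- blocks$v_ss
  lhs[seq_len(ns), ns + seq_len(ng)] <- -blocks$k_sg
  lhs[ns + seq_len(ng), seq_len(ns)] <- -blocks$v_gs
  kg <- blocks$k_gg
  diag(kg) <- diag(kg) + 0.5
  lhs[ns + seq_len(ng), ns + seq_len(ng)] <- kg
  rhs <- rbind(0.5 * u + blocks$k_ss %*% u, -blocks$k_gs %*% u)
  sol <- tryCatch(solve(lhs, rhs),
                  error = function(e) stopf(
                    "block system solve failed (%s); geometry may be degenerate",
                    conditionMessage(e)))
  rho1t <- sol[seq_len(ns), , drop = FALSE]
  list(rho0_gamma = drop(sol[ns + seq_len(ng), , drop = FALSE]),
       rho1t_sigma = drop(rho1t),
       rho1_sigma = drop(rho1t / blocks$ev_sigma$speed))
}

#' Build the discrete transfer operators
#'
#' Constructs the solution operator `A` (pericardial values to chest
#' trace), the Poincare-Steklov (Dirichlet-to-Neumann) operator `B` on the
#' pericardium, and the diagonal mass matrices.  The default path solves
#' the block system column by column; `method = "schur"` forms the Schur
#' complement `S = I/2 + K_GG - V_GS V_SS^{-1} K_SG` explicitly.  Both
#' paths agree to round-off.
#'
#' @param blocks A [assemble_blocks()] result.
#' @param method `"solve"` (default) or `"schur"`.
#' @return An object of class `transfer_operators` with fields `A`, `B`,
#'   `s_sigma`, `s_gamma` (mass matrix diagonals as vectors) and the
#'   collocation sizes.
#' @export
build_transfer <- function(blocks, method = c("solve", "schur")) {
  method <- match.arg(method)
  ns <- blocks$n_sigma; ng <- blocks$n_gamma
  if (method == "solve") {
    sol <- solve_bvp(blocks, diag(1, ns))
    a <- sol$rho0_gamma
    b <- sol$rho1_sigma
  } else {
    # V_SS is singular iff the pericardium has logarithmic capacity one
    # (e.g. the unit circle); the default path has no such restriction
    vss_inv <- tryCatch(
      solve(blocks$v_ss, cbind(blocks$k_sg, diag(0.5, ns) + blocks$k_ss)),
      error = function(e) stopf(
        "Schur path unavailable: V_SS is singular (%s)", conditionMessage(e)))
    vss_inv_ksg <- vss_inv[, seq_len(blocks$n_gamma), drop = FALSE]
    vss_inv_kss <- vss_inv[, blocks$n_gamma + seq_len(ns), drop = FALSE]
    schur <- diag(0.5, ng) + blocks$k_gg - blocks$v_gs %*% vss_inv_ksg
    a <- solve(schur, blocks$v_gs %*% vss_inv_kss - blocks$k_gs)
    b <- (vss_inv_kss + vss_inv_ksg %*% a) / blocks$ev_sigma$speed
  }
  structure(list(A = a, B = b,
                 s_sigma = blocks$ev_sigma$speed / ns,
                 s_gamma = blocks$ev_gamma$speed / ng,
                 n_sigma = ns, n_gamma = ng),
            class = "transfer_operators")
}
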