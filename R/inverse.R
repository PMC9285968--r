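#' Regularisation specification for the inverse problem
#'
#' Four regularisations of the ill-posed reconstruction of the pericardial
#' potential: `tik0` penalises the L2 norm of the Dirichlet data, `tik1`
#' the L2 norm of the Neumann data, `h12` the H^(1/2) trace norm
#' `<Bv, v>` arising from the boundary integral formulation, and `tv` a
#' smoothed, lagged-diffusivity linearisation of the L1 norm of the
#' Neumann data around the zero-order Tikhonov solution.
#'
#' @param kind One of `"tik0"`, `"tik1"`, `"h12"`, `"tv"`.
#' @param lambda Regularisation parameter (> 0); defaults per kind to the
#'   L-curve picks `1e-6`, `1e-3`, `1e-5`, `1e-5`.
#' @param beta Total-variation smoothing constant (> 0), default `1e-5`.
#' @param h12_form `"symmetrised"` (default) uses the exact gradient
#'   `(B' S + S B)/2` of the discrete quadratic form; `"printed"` uses
#'   `S (B' + B)/2`.
#' @return An object of class `regularisation_spec`.
#' @export
regularisation_spec <- function(kind = c("tik0", "tik1", "h12", "tv"),
                                lambda = NULL, beta = 1e-5,
                                h12_form = c("symmetrised", "printed")) {
  kind <- match.arg(kind)
  h12_form <- match.arg(h12_form)
  if (is.null(lambda))
    lambda <- c(tik0 = 1e-6, tik1 = 1e-3, h12 = 1e-5, tv = 1e-5)[[kind]]
  if (lambda <= 0) stopf("lambda must be positive")
  if (beta <= 0) stopf("beta must be positive")
  structure(list(kind = kind, lambda = lambda, beta = beta,
                 h12_form = h12_form),
            class = "regularisation_spec")
}

#' Discrete regularisation matrix
#'
#' Returns the symmetric matrix `M` of the quadratic penalty
#' `v' M v` entering the normal equations of [inverse_solve()]:
#' `tik0 -> S`, `tik1 -> B' S B`, `h12 -> (B' S + S B)/2`,
#' `tv -> B' W S B` with diagonal lagged-diffusivity weights
#' `W_ii = 1 / (2 sqrt((B u0)_i^2 + beta))`.
#'
#' @param spec A [regularisation_spec()].
#' @param ops A [build_transfer()] result.
#' @param u0 Zero-order Tikhonov solution (required iff `kind = "tv"`).
#' @return Symmetric `n_sigma x n_sigma` matrix.
#' @export
regularisation_matrix <- function(spec, ops, u0 = NULL) {
  s <- ops$s_sigma
  m <- switch(spec$kind,
    tik0 = diag(s, ops$n_sigma),
    tik1 = crossprod(ops$B * sqrt(s)),
    h12 = {
      sb <- s * ops$B           # S B (row scaling)
      if (spec$h12_form == "symmetrised") (t(sb) + sb) / 2
      else (s * t(ops$B) + sb) / 2
    },
    tv = {
      if (is.null(u0))
        stopf("total variation requires the zero-order Tikhonov solution u0")
      w <- 1 / (2 * sqrt(as.numeric(ops$B %*% u0)^2 + spec$beta))
      crossprod(ops$B * sqrt(w * s))
    })
  if (any(!is.finite(m))) stopf("non-finite regularisation matrix entries")
  (m + t(m)) / 2
}

#' Solve the regularised inverse problem for one time step
#'
#' Solves the normal equations
#' `(A' S_Gamma A + lambda^2 M) u = A' S_Gamma y_d` by a dense direct
#' solve.  For `tv`, the weights are frozen at the zero-order Tikhonov
#' solution computed with the same `lambda` (a single lagged-diffusivity
#' linearisation, no iteration).
#'
#' @param ops A [build_transfer()] result.
#' @param yd Chest data vector (length `n_gamma`).
#' @param spec A [regularisation_spec()].
#' @param u0 Optional precomputed zero-order Tikhonov solution for `tv`.
#' @param check Verify the optimality residual (default `FALSE`).
#' @return Pericardial potential vector of length `n_sigma`.
#' @export
inverse_solve <- function(ops, yd, spec, u0 = NULL, check = FALSE) {
  if (length(yd) != ops$n_gamma)
    stopf("yd must have length n_gamma = %d", ops$n_gamma)
  if (spec$kind == "tv" && is.null(u0))
    u0 <- inverse_solve(ops, yd, regularisation_spec("tik0", spec$lambda))
  m <- regularisation_matrix(spec, ops, u0)
  asg <- t(ops$A * ops$s_gamma)                  # A' S_Gamma
  nm <- asg %*% ops$A + spec$lambda^2 * m
  rhs <- as.numeric(asg %*% yd)
  u <- tryCatch(as.numeric(solve(nm, rhs)),
                error = function(e) stopf(
                  "normal equations are numerically singular (%s)",
                  conditionMessage(e)))
  if (check) {
    res <- max(abs(nm %*% u - rhs))
    if (res > 1e-10 * max(abs(rhs)))
      stopf("optimality residual %.3e exceeds tolerance", res)
  }
  u
}

# residual and penalty norms of a solution (for the L-curve)
lcurve_point <- function(ops, yd, u, m) {
  r <- as.numeric(ops$A %*% u) - yd
  c(residual = sqrt(sum(r^2 * ops$s_gamma)),
    penalty = sqrt(max(sum(u * as.numeric(m %*% u)), 0)))
}

#' L-curve selection of the regularisation parameter
#'
#' For each time step (column of `yd`), traces the parametric curve
#' `(log residual norm, log penalty norm)` over the `lambda` grid and
#' picks the grid point of maximal finite-difference curvature (interior
#' points only, ties broken towards larger `lambda`).  Across a time
#' series the maximum of the per-step picks is returned, limiting
#' oscillations at the price of possible over-regularisation of single
#' steps.
#'
#' @param ops A [build_transfer()] result.
#' @param yd Chest data: vector or `n_gamma x n_t` matrix.
#' @param kind Regularisation kind, see [regularisation_spec()].
#' @param lambdas Log-spaced grid (>= 9 points), default
#'   `10^seq(-8, 0, length.out = 33)`.
#' @param beta TV smoothing constant.
#' @return List with `lambda` (selected), `per_step` (per-column picks)
#'   and `table` (residual/penalty norms per lambda for the last column).
#' @export
l_curve_select <- function(ops, yd, kind,
                           lambdas = 10^seq(-8, 0, length.out = 33),
                           beta = 1e-5) {
  if (length(lambdas) < 9) stopf("lambda grid must have at least 9 points")
  lambdas <- sort(lambdas)
  yd <- as.matrix(yd)
  picks <- numeric(ncol(yd))
  tab <- NULL
  for (j in seq_len(ncol(yd))) {
    # grid points where the normal equations are numerically singular
    # (lambda far below the noise level) are dropped from the curve
    rp <- vapply(lambdas, function(l) {
      tryCatch({
        spec <- regularisation_spec(kind, l, beta)
        u0 <- if (kind == "tv")
          inverse_solve(ops, yd[, j], regularisation_spec("tik0", l)) else NULL
        u <- inverse_solve(ops, yd[, j], spec, u0 = u0)
        lcurve_point(ops, yd[, j], u,
                     regularisation_matrix(spec, ops, u0))
      }, error = function(e) c(residual = NA_real_, penalty = NA_real_))
    }, numeric(2))
    ok <- !is.na(rp["residual", ])
    if (sum(ok) < 5)
      stopf("L-curve failed: fewer than 5 solvable lambda grid points")
    lam <- lambdas[ok]
    rp <- rp[, ok, drop = FALSE]
    if (any(rp <= 0))
      stopf("degenerate L-curve: zero residual or penalty on the grid")
    x <- log(rp["residual", ]); y <- log(rp["penalty", ])
    n <- length(lam)
    i <- 2:(n - 1)
    dx <- (x[i + 1] - x[i - 1]) / 2; dy <- (y[i + 1] - y[i - 1]) / 2
    ddx <- x[i + 1] - 2 * x[i] + x[i - 1]
    ddy <- y[i + 1] - 2 * y[i] + y[i - 1]
    curv <- abs(dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
    best <- i[max(which(curv == max(curv)))]   # ties towards larger lambda
    picks[j] <- lam[best]
    tab <- data.frame(lambda = lam, residual = rp["residual", ],
                      penalty = rp["penalty", ])
  }
  list(lambda = max(picks), per_step = picks, table = tab)
}
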