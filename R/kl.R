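#' Pivoted Cholesky decomposition of a lazily evaluated covariance
#'
#' Greedy low-rank factorisation `C ~ L L'` of a symmetric positive
#' semi-definite matrix whose columns are evaluated on demand, stopping
#' when the relative trace residual (sum of the remaining Schur-complement
#' diagonal over the initial trace) drops to `tol`.
#'
#' @param diag0 Initial diagonal of the matrix (length `n`).
#' @param col_fun Function `p -> C[, p]` returning one full column.
#' @param tol Relative (default) or absolute trace tolerance.
#' @param max_rank Rank cap, default `n`.
#' @param absolute Interpret `tol` as an absolute trace residual.
#' @return List with `L` (n x K factor), `pivots`, `residuals` (trace
#'   residual after each step), `trace` (initial trace) and `rank`.
#' @export
pivoted_cholesky <- function(diag0, col_fun, tol = 1e-4,
                             max_rank = length(diag0), absolute = FALSE) {
  n <- length(diag0)
  d <- as.numeric(diag0)
  trace0 <- sum(d)
  target <- if (absolute) tol else tol * trace0
  l <- matrix(0, n, 0)
  pivots <- integer(0)
  residuals <- numeric(0)
  while (sum(d) > target && length(pivots) < max_rank) {
    p <- which.max(d)
    if (d[p] < -1e-12 * trace0)
      stopf("covariance is numerically indefinite (pivot %.3e)", d[p])
    if (d[p] <= 0) break
    col <- col_fun(p)
    if (length(pivots)) col <- col - l %*% l[p, ]
    lk <- as.numeric(col) / sqrt(d[p])
    lk[p] <- sqrt(d[p])   # exact by construction
    l <- cbind(l, lk, deparse.level = 0)
    pivots <- c(pivots, p)
    d <- pmax(d - lk^2, 0)
    d[pivots] <- 0
    residuals <- c(residuals, sum(d))
  }
  list(L = l, pivots = pivots, residuals = residuals, trace = trace0,
       rank = length(pivots))
}

#' Karhunen-Loeve expansion of the pericardial deformation field
#'
#' Assembles, lazily and column by column, the covariance of the two
#' displacement components at all space-time collocation points of the
#' reference pericardium and compresses it by [pivoted_cholesky()].  The
#' degrees of freedom are ordered component-major, then time, then
#' s-index.  The mean of the field is the reference position; the columns
#' of the returned factor are the weighted modes
#' \eqn{m_k = \sqrt{\lambda_k}\,\chi_k} of the finite-rank expansion
#' \eqn{\chi(\hat z_i, \xi) = \hat z_i + \sum_k m_k(\hat z_i)\, \xi_k}
#' with \eqn{\xi \in [-1,1]^K}.
#'
#' @param geometry A [space_time_geometry()].
#' @param model A [covariance_model()].
#' @param tol Trace tolerance of the pivoted Cholesky (relative by
#'   default), default `1e-4`.
#' @param n_sigma Collocation points per curve.
#' @param times Subset of instants (ms) to include; default all stored.
#' @param max_rank Optional rank cap.
#' @param tol_absolute Interpret `tol` as an absolute trace residual
#'   (default `FALSE`).
#' @return An object of class `kl_expansion` with fields `mean`
#'   (`(n_t n_sigma) x 2` reference positions), `modes`
#'   (`(2 n_t n_sigma) x K`), `times`, `n_sigma`, `trace`,
#'   `trace_residual`, `chest`, `ref_curves`, `period`, `model`.
#' @export
build_kl <- function(geometry, model = covariance_model(
                       period = geometry$period),
                     tol = 1e-4, n_sigma = 128L, times = NULL,
                     max_rank = NULL, tol_absolute = FALSE) {
  if (tol <= 0 || (!tol_absolute && tol >= 1))
    stopf("tol must be positive (and below 1 when relative)")
  if (is.null(times)) times <- geometry$times
  curves <- lapply(times, function(t) pericardium_at_time(geometry, t))
  s <- collocation_grid(n_sigma)
  pos <- do.call(rbind, lapply(curves, function(crv)
    eval_curve(crv, s)$point))                  # (n_t n_sigma) x 2
  nt <- length(times)
  np <- nt * n_sigma
  tidx <- rep(seq_len(nt), each = n_sigma)
  ktime <- outer(times, times, temporal_kernel, period = model$period)
  col_fun <- function(p) {
    comp <- if (p > np) 2L else 1L
    i <- if (comp == 2L) p - np else p
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    kc <- matern_kernel(d, model$nu[comp], model$rho, model$sigma2) *
      ktime[tidx, tidx[i]]
    if (comp == 1L) c(kc, numeric(np)) else c(numeric(np), kc)
  }
  pc <- pivoted_cholesky(rep(model$sigma2, 2L * np), col_fun, tol = tol,
                         max_rank = if (is.null(max_rank)) 2L * np
                                    else max_rank,
                         absolute = tol_absolute)
  structure(list(mean = pos, modes = pc$L, pivots = pc$pivots,
                 trace = pc$trace,
                 trace_residual = if (length(pc$residuals))
                   pc$residuals[pc$rank] else pc$trace,
                 rank = pc$rank,
                 times = times, n_sigma = n_sigma,
                 chest = geometry$chest,
                 ref_curves = curves, period = geometry$period,
                 model = model, tol = tol),
            class = "kl_expansion")
}

#' @export
print.kl_expansion <- function(x, ...) {
  cat(sprintf(
    "kl_expansion: K=%d modes, %d instants x %d points, trace residual %.2e\n",
    x$rank, length(x$times), x$n_sigma, x$trace_residual / x$trace))
  invisible(x)
}

# dof indices of one time instant, per component
kl_time_slice <- function(kl, t_index) {
  np <- length(kl$times) * kl$n_sigma
  base <- (t_index - 1L) * kl$n_sigma + seq_len(kl$n_sigma)
  list(x = base, y = np + base)
}

# deformed collocation points at one instant (affine in xi)
kl_deformed_points <- function(kl, xi, t_index) {
  idx <- kl_time_slice(kl, t_index)
  base <- (t_index - 1L) * kl$n_sigma + seq_len(kl$n_sigma)
  cbind(kl$mean[base, 1] + as.numeric(kl$modes[idx$x, , drop = FALSE] %*% xi),
        kl$mean[base, 2] + as.numeric(kl$modes[idx$y, , drop = FALSE] %*% xi))
}

# chest polygon cache for the admissibility test
kl_chest_poly <- function(kl) {
  poly <- attr(kl, "chest_poly")
  if (is.null(poly)) poly <- eval_curve(kl$chest, collocation_grid(256L))$point
  poly
}

#' Sample a deformed pericardium curve
#'
#' Evaluates the finite-rank expansion at one time instant for a parameter
#' point `xi` in `[-1, 1]^K` and returns the balanced trigonometric
#' interpolant of the deformed collocation points.  Admissibility checks
#' (a surrogate for the uniformity condition of the deformation field):
#' minimal parameterisation speed above `1e-3` times the mean speed, no
#' self-intersection, strictly inside the chest.  `check = "fast"` skips
#' the quadratic-cost self-intersection test, `"none"` skips all checks.
#'
#' @param kl A [build_kl()] expansion.
#' @param xi Parameter vector, every coordinate in `[-1, 1]`.
#' @param t_index Time-instant index (1-based into `kl$times`).
#' @param check `"full"` (default), `"fast"` or `"none"`.
#' @return A [closed_curve()] with role `"pericardium"`.
#' @export
sample_deformation <- function(kl, xi, t_index = 1L,
                               check = c("full", "fast", "none")) {
  check <- match.arg(check)
  if (length(xi) != kl$rank)
    stopf("xi must have length K = %d", kl$rank)
  if (any(abs(xi) > 1 + 1e-12))
    stopf("xi must lie in [-1, 1]^K")
  if (t_index < 1L || t_index > length(kl$times))
    stopf("invalid time index %d", t_index)
  pts <- kl_deformed_points(kl, xi, t_index)
  ev <- ev_from_points(pts, "pericardium")
  if (check != "none") {
    if (min(ev$speed) <= 1e-3 * mean(ev$speed))
      stopf("inadmissible deformation at instant %d: degenerate speed",
            t_index)
    poly <- kl_chest_poly(kl)
    if (!all(pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2])))
      stopf("inadmissible deformation at instant %d: outside the chest",
            t_index)
    if (check == "full" && !is_simple_polygon(pts))
      stopf("inadmissible deformation at instant %d: self-intersection",
            t_index)
  }
  interp_closed_curve(pts, role = "pericardium", validate = FALSE)
}

#' Pointwise standard deviation of the deformation field
#'
#' With independent `xi_k ~ U(-1, 1)` (variance 1/3) the per-coordinate
#' standard deviation of the expansion is
#' `sqrt(sum_k m_k^2 / 3)`; the conventional 95% shape band is
#' `mean +/- 1.96` times this field.
#'
#' @param kl A [build_kl()] expansion.
#' @return Matrix `(n_t n_sigma) x 2` of standard deviations (mm).
#' @export
shape_std <- function(kl) {
  v <- rowSums(kl$modes^2) / 3
  np <- length(kl$times) * kl$n_sigma
  cbind(sqrt(v[seq_len(np)]), sqrt(v[np + seq_len(np)]))
}

#' Write / read a Karhunen-Loeve expansion directory
#'
#' CSV matrices for the mean positions and the weighted modes (rows in
#' the documented dof order: component-major, then time, then s-index)
#' plus a JSON manifest with sizes, times, period and model parameters.
#'
#' @param kl A [build_kl()] expansion.
#' @param dir Output directory.
#' @return `write_kl` returns `dir` invisibly; `read_kl` returns a
#'   `kl_expansion` (without the geometry back-references unless the
#'   geometry directory is given).
#' @param geometry Optional [space_time_geometry()] to re-attach curves.
#' @export
write_kl <- function(kl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) apply(m, 2, formatC, digits = 17, format = "g")
  utils::write.table(fmt(kl$mean), file.path(dir, "mean.csv"), sep = ",",
                     row.names = FALSE, col.names = c("x", "y"),
                     quote = FALSE)
  utils::write.table(fmt(kl$modes), file.path(dir, "modes.csv"), sep = ",",
                     row.names = FALSE,
                     col.names = paste0("m", seq_len(kl$rank)),
                     quote = FALSE)
  jsonlite::write_json(
    list(rank = kl$rank, n_sigma = kl$n_sigma, times = kl$times,
         period = kl$period, trace = kl$trace,
         trace_residual = kl$trace_residual, tol = kl$tol,
         model = unclass(kl$model), pivots = kl$pivots),
    file.path(dir, "kl.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_kl
#' @export
read_kl <- function(dir, geometry = NULL) {
  man <- jsonlite::read_json(file.path(dir, "kl.json"),
                             simplifyVector = TRUE)
  mean_pos <- as.matrix(utils::read.csv(file.path(dir, "mean.csv")))
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  dimnames(mean_pos) <- NULL; dimnames(modes) <- NULL
  chest <- if (!is.null(geometry)) geometry$chest else NULL
  curves <- if (!is.null(geometry))
    lapply(man$times, function(t) pericardium_at_time(geometry, t)) else NULL
  structure(list(mean = mean_pos, modes = modes, pivots = man$pivots,
                 trace = man$trace, trace_residual = man$trace_residual,
                 rank = man$rank, times = man$times,
                 n_sigma = man$n_sigma, chest = chest,
                 ref_curves = curves, period = man$period,
                 model = do.call(covariance_model, man$model),
                 tol = man$tol),
            class = "kl_expansion")
}
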