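#' Closed boundary curves as trigonometric polynomials
#'
#' A `closed_curve` stores a smooth closed planar curve
#' \deqn{\gamma(s) = \sum_{k=0}^{M} a_k \cos(2\pi k s) + b_k \sin(2\pi k s),
#'   \quad s \in [0,1),}
#' one cosine/sine coefficient pair per spatial component.  The
#' parameterisation is 1-periodic by construction and the stored orientation
#' is counterclockwise.  The `role` of a curve ("chest" or "pericardium")
#' fixes the sign of its unit normal so that the normal is always exterior
#' to the torso domain: outward on the chest, pointing into the cardiac
#' cavity on the pericardium.
#'
#' @param ax,bx,ay,by Numeric vectors of length `M + 1` with the cosine and
#'   sine coefficients of the x and y components (`bx[1]` and `by[1]` must
#'   be zero).
#' @param role Either `"chest"` or `"pericardium"`.
#' @param unit Length unit label, default `"mm"`.
#' @param validate Check orientation, regularity and simplicity (default
#'   `TRUE`).
#' @return An object of class `closed_curve`.
#' @export
closed_curve <- function(ax, bx, ay, by, role = c("chest", "pericardium"),
                         unit = "mm", validate = TRUE) {
  role <- match.arg(role)
  m <- length(ax) - 1L
  if (length(bx) != m + 1L || length(ay) != m + 1L || length(by) != m + 1L)
    stopf("coefficient vectors must have equal length")
  if (abs(bx[1]) > 0 || abs(by[1]) > 0)
    stopf("sine coefficients of harmonic 0 must be zero")
  crv <- structure(
    list(ax = as.numeric(ax), bx = as.numeric(bx),
         ay = as.numeric(ay), by = as.numeric(by),
         order = m, role = role, unit = unit),
    class = "closed_curve")
  if (validate) {
    ng <- max(256L, 8L * (m + 1L))
    ev <- eval_curve(crv, (seq_len(ng) - 1) / ng)
    if (min(ev$speed) <= 0)
      stopf("curve is not regular: vanishing tangent on the check grid")
    if (signed_polygon_area(ev$point) <= 0)
      stopf("curve must be oriented counterclockwise")
    if (!is_simple_polygon(ev$point))
      stopf("curve self-intersects on the check grid")
  }
  crv
}

#' @export
print.closed_curve <- function(x, ...) {
  ev <- eval_curve(x, (0:255) / 256)
  cat(sprintf("closed_curve: role=%s, order M=%d, length~%.2f %s\n",
              x$role, x$order, sum(ev$speed) / 256, x$unit))
  invisible(x)
}

#' Evaluate a closed curve and its differential geometry
#'
#' @param curve A [closed_curve()].
#' @param s Numeric vector of parameters (any reals; the curve is
#'   1-periodic).
#' @return A list with `point`, `tangent` (unit), `normal` (unit, exterior
#'   to the torso domain), `speed` (\eqn{\|\gamma'(s)\|}) and signed
#'   `curvature` (positive for a convex counterclockwise curve).
#' @export
eval_curve <- function(curve, s) {
  k <- 0:curve$order
  ang <- outer(2 * pi * s, k)            # n x (M+1)
  cs <- cos(ang); sn <- sin(ang)
  x <- cs %*% curve$ax + sn %*% curve$bx
  y <- cs %*% curve$ay + sn %*% curve$by
  w <- 2 * pi * k
  dx <- -sn %*% (curve$ax * w) + cs %*% (curve$bx * w)
  dy <- -sn %*% (curve$ay * w) + cs %*% (curve$by * w)
  ddx <- -cs %*% (curve$ax * w^2) - sn %*% (curve$bx * w^2)
  ddy <- -cs %*% (curve$ay * w^2) - sn %*% (curve$by * w^2)
  speed <- sqrt(dx^2 + dy^2)
  kappa <- (dx * ddy - dy * ddx) / speed^3
  sgn <- if (curve$role == "chest") 1 else -1
  normal <- cbind(sgn * dy / speed, -sgn * dx / speed)
  list(point = cbind(as.numeric(x), as.numeric(y)),
       tangent = cbind(as.numeric(dx / speed), as.numeric(dy / speed)),
       normal = cbind(as.numeric(normal[, 1]), as.numeric(normal[, 2])),
       speed = as.numeric(speed),
       curvature = as.numeric(kappa))
}

# truncated-DFT coefficients of a real vector sampled on a uniform grid
dft_coefficients <- function(v) {
  n <- length(v)
  cc <- stats::fft(v) / n
  list(c = cc, n = n)
}

curve_from_dft <- function(cx, cy, m, n, role, unit = "mm",
                           balanced = FALSE, validate = TRUE) {
  idx <- seq_len(m) + 1L
  ax <- c(Re(cx[1]), 2 * Re(cx[idx]))
  bx <- c(0, -2 * Im(cx[idx]))
  ay <- c(Re(cy[1]), 2 * Re(cy[idx]))
  by <- c(0, -2 * Im(cy[idx]))
  if (balanced && n %% 2L == 0L && m == n %/% 2L) {
    # Nyquist harmonic enters as a pure cosine so the interpolant is real
    # and exact at the nodes
    ax[m + 1L] <- Re(cx[m + 1L])
    ay[m + 1L] <- Re(cy[m + 1L])
    bx[m + 1L] <- 0; by[m + 1L] <- 0
  }
  closed_curve(ax, bx, ay, by, role = role, unit = unit, validate = validate)
}

#' Fit a closed curve by least squares in a truncated Fourier basis
#'
#' Given ordered points of a simple closed polygon, parameterised uniformly
#' (`s_i = i/n`), returns the lowest truncation order whose least-squares
#' trigonometric fit attains the requested relative root-mean-square error.
#' On a uniform grid the least-squares fit equals the truncated discrete
#' Fourier transform, which is used directly.  Input orientation is
#' normalised counterclockwise.
#'
#' @param points Numeric matrix (n x 2), `n >= 8`, consistently ordered
#'   vertices of a simple closed polygon (last point distinct from first).
#' @param threshold Relative RMSE target, default `1e-3`.
#' @param role Curve role, see [closed_curve()].
#' @param unit Length unit label.
#' @return A [closed_curve()] with attributes `rel_rmse` (achieved error)
#'   and `n_points`.
#' @export
fit_fourier_curve <- function(points, threshold = 1e-3,
                              role = c("chest", "pericardium"), unit = "mm") {
  role <- match.arg(role)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 8) stopf("need at least 8 points, got %d", n)
  if (!is_simple_polygon(points))
    stopf("input polygon is not simple (self-intersecting)")
  if (signed_polygon_area(points) < 0)
    points <- points[c(1L, n:2L), , drop = FALSE]
  cx <- stats::fft(points[, 1]) / n
  cy <- stats::fft(points[, 2]) / n
  m_max <- n %/% 2L - 1L
  # spectral energy per harmonic (deviation from the mean), Parseval
  kk <- seq_len(if (n %% 2L == 0L) n %/% 2L else (n - 1L) %/% 2L)
  e <- 2 * (Mod(cx[kk + 1L])^2 + Mod(cy[kk + 1L])^2)
  if (n %% 2L == 0L) e[length(e)] <- e[length(e)] / 2  # Nyquist counted once
  tot <- sum(e)
  if (tot == 0) stopf("degenerate input: all points coincide")
  resid <- rev(cumsum(rev(e)))  # resid[k] = energy in harmonics >= k
  rel <- sqrt(c(resid[-1], 0) / tot)  # rel[m] = rel RMSE at order m
  ok <- which(rel[seq_len(m_max)] <= threshold)
  if (!length(ok))
    stopf(paste0("threshold %.3g unreachable at maximal order %d ",
                 "(achieved relative RMSE %.3g)"),
          threshold, m_max, rel[m_max])
  m <- min(ok)
  crv <- curve_from_dft(cx, cy, m, n, role, unit)
  attr(crv, "rel_rmse") <- rel[m]
  attr(crv, "n_points") <- n
  crv
}

#' Balanced trigonometric interpolant through uniformly sampled points
#'
#' Returns the closed curve of maximal (balanced) order interpolating the
#' given points exactly at `s_i = i/n`; for even `n` the Nyquist harmonic
#' is represented as a pure cosine.
#'
#' @inheritParams fit_fourier_curve
#' @param validate Run the curve validity checks (default `TRUE`).
#' @return A [closed_curve()].
#' @export
interp_closed_curve <- function(points, role = c("chest", "pericardium"),
                                unit = "mm", validate = TRUE) {
  role <- match.arg(role)
  points <- as.matrix(points)
  n <- nrow(points)
  cx <- stats::fft(points[, 1]) / n
  cy <- stats::fft(points[, 2]) / n
  m <- n %/% 2L
  curve_from_dft(cx, cy, m, n, role, unit, balanced = TRUE,
                 validate = validate)
}

#' Write / read a closed curve as CSV
#'
#' The file has columns `component,k,cos,sin` with `component` in
#' `{x,y}` and `k` the harmonic index; the curve role and unit are kept in
#' comment-free extra columns of the first row via attributes in the
#' geometry manifest, not in the CSV itself.
#'
#' @param curve A [closed_curve()].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns a
#'   [closed_curve()].
#' @export
write_curve <- function(curve, path) {
  k <- 0:curve$order
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  df <- rbind(
    data.frame(component = "x", k = k, cos = fmt(curve$ax),
               sin = fmt(curve$bx)),
    data.frame(component = "y", k = k, cos = fmt(curve$ay),
               sin = fmt(curve$by)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param role,unit Role and unit to attach on read.
#' @export
read_curve <- function(path, role = c("chest", "pericardium"), unit = "mm") {
  role <- match.arg(role)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component", "k", "cos", "sin")
  if (!all(need %in% names(df)))
    stopf("malformed curve file %s: expected columns %s", path,
          paste(need, collapse = ","))
  dx <- df[df$component == "x", ]
  dy <- df[df$component == "y", ]
  dx <- dx[order(dx$k), ]; dy <- dy[order(dy$k), ]
  closed_curve(dx$cos, dx$sin, dy$cos, dy$sin, role = role, unit = unit)
}

#' Collocation nodes on the unit parameter interval
#'
#' @param n Number of points.
#' @return Numeric vector `s_i = i/n`, `i = 0, ..., n-1`.
#' @export
collocation_grid <- function(n) (seq_len(n) - 1) / n

#' Curve length and enclosed area
#'
#' Trapezoidal estimates on an `n`-point parameter grid; spectrally
#' accurate for trigonometric curves.
#'
#' @param curve A [closed_curve()].
#' @param n Grid size.
#' @return Length / enclosed (positive, counterclockwise) area.
#' @export
curve_length <- function(curve, n = 512L) {
  sum(eval_curve(curve, collocation_grid(n))$speed) / n
}

#' @rdname curve_length
#' @export
curve_area <- function(curve, n = 512L) {
  s <- collocation_grid(n)
  k <- 0:curve$order
  ang <- outer(2 * pi * s, k)
  cs <- cos(ang); sn <- sin(ang)
  x <- as.numeric(cs %*% curve$ax + sn %*% curve$bx)
  y <- as.numeric(cs %*% curve$ay + sn %*% curve$by)
  w <- 2 * pi * k
  dx <- as.numeric(-sn %*% (curve$ax * w) + cs %*% (curve$bx * w))
  dy <- as.numeric(-sn %*% (curve$ay * w) + cs %*% (curve$by * w))
  sum(x * dy - y * dx) / (2 * n)
}
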