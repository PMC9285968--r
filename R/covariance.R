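#' Matern spatial covariance kernel
#'
#' Closed forms for the smoothness indices used by the deformation model:
#' `nu = 5/2` gives
#' \eqn{\sigma^2 (1 + \sqrt5 d/\rho + 5d^2/(3\rho^2)) e^{-\sqrt5 d/\rho}},
#' `nu = Inf` the squared-exponential limit
#' \eqn{\sigma^2 e^{-d^2/(2\rho^2)}}.
#'
#' @param d Distances (same unit as `rho`, mm), `d >= 0`.
#' @param nu Smoothness index: `2.5` or `Inf`.
#' @param rho Correlation length (mm), default 50.
#' @param sigma2 Marginal variance, default 4/3.
#' @return Covariance values.
#' @export
matern_kernel <- function(d, nu, rho = 50, sigma2 = 4 / 3) {
  if (any(d < 0)) stopf("distances must be non-negative")
  if (identical(nu, 2.5) || identical(nu, 5 / 2)) {
    q <- sqrt(5) * d / rho
    sigma2 * (1 + q + q^2 / 3) * exp(-q)
  } else if (is.infinite(nu)) {
    sigma2 * exp(-d^2 / (2 * rho^2))
  } else {
    stopf("unsupported smoothness index nu = %s (use 5/2 or Inf)",
          format(nu))
  }
}

#' Periodic temporal covariance factor
#'
#' The heartbeat interval `[0, T)` is mapped to the circle by
#' `eta(t) = 2 pi t / T`; the geodesic distance
#' `theta = arccos(cos(eta(t) - eta(t')))` enters the sine-power kernel
#' `k(theta) = (cos(theta) + 1) / 2`, which is positive definite on the
#' circle and makes the deformation field periodic over the heartbeat.
#'
#' @param t,tp Times in ms (vectorised, recycled).
#' @param period Heartbeat duration T (ms).
#' @return Covariance factors in `[0, 1]`.
#' @export
temporal_kernel <- function(t, tp, period) {
  if (period <= 0) stopf("period must be positive")
  theta <- acos(pmin(pmax(cos(2 * pi * (t - tp) / period), -1), 1))
  (cos(theta) + 1) / 2
}

#' Space-time covariance model of the deformation field
#'
#' Tensor product of the sine-power temporal kernel and a
#' component-diagonal Matern spatial kernel: smoothness `5/2` for the
#' first spatial component, the Gaussian limit for the second, no
#' correlation between components.
#'
#' @param rho Spatial correlation length (mm).
#' @param sigma2 Spatial marginal variance.
#' @param nu Smoothness indices of the two components.
#' @param period Heartbeat duration T (ms).
#' @return An object of class `covariance_model`.
#' @export
covariance_model <- function(rho = 50, sigma2 = 4 / 3, nu = c(2.5, Inf),
                             period = 690) {
  if (rho <= 0 || sigma2 <= 0) stopf("rho and sigma2 must be positive")
  structure(list(rho = rho, sigma2 = sigma2, nu = nu, period = period),
            class = "covariance_model")
}

#' Covariance between two space-time points
#'
#' @param z,zp Lists with fields `x` (position, length-2) and `t` (ms).
#' @param model A [covariance_model()].
#' @return A diagonal 2 x 2 covariance matrix.
#' @export
covariance_entry <- function(z, zp, model = covariance_model()) {
  d <- sqrt(sum((z$x - zp$x)^2))
  kt <- temporal_kernel(z$t, zp$t, model$period)
  diag(kt * c(matern_kernel(d, model$nu[1], model$rho, model$sigma2),
              matern_kernel(d, model$nu[2], model$rho, model$sigma2)), 2)
}
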