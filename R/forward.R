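#' Parameters of the analytic pericardial potential
#'
#' The prescribed extracellular potential emulates a left bundle branch
#' block: activation starts at the right-ventricular free wall (`s = 0`)
#' and propagates symmetrically to the left-ventricular free wall
#' (`s = 0.5`) over `conduction_span` ms, followed by a plateau of
#' duration `apd` and repolarisation.  The waveform is a difference of
#' logistic fronts attached to the curvilinear coordinate `s`, periodic in
#' time with period `period`.
#'
#' @param amplitude Potential amplitude (arbitrary units).
#' @param conduction_span Activation time at `s = 0.5` (ms).
#' @param apd Action-potential (plateau) duration (ms).
#' @param w_depol Depolarisation front width (ms).
#' @param w_repol Repolarisation front width (ms).
#' @param period Heartbeat duration T (ms).
#' @return Named list of parameters.
#' @export
potential_params <- function(amplitude = 1, conduction_span = 150,
                             apd = 250, w_depol = 5, w_repol = 30,
                             period = 690) {
  list(amplitude = amplitude, conduction_span = conduction_span,
       apd = apd, w_depol = w_depol, w_repol = w_repol, period = period)
}

#' Activation time of the prescribed potential
#'
#' @param s Curvilinear coordinate (any reals; 1-periodic).
#' @param params See [potential_params()].
#' @return Activation time in ms: `2 * conduction_span * min(s, 1 - s)`.
#' @export
activation_time <- function(s, params = potential_params()) {
  sm <- s %% 1
  2 * params$conduction_span * pmin(sm, 1 - sm)
}

#' Analytic pericardial potential u(s, t)
#'
#' @param s Curvilinear coordinate(s).
#' @param t Time(s) in ms; recycled against `s`.
#' @param params See [potential_params()].
#' @return Potential values, elementwise over recycled `(s, t)`.
#' @export
reference_potential <- function(s, t, params = potential_params()) {
  tau <- activation_time(s, params)
  tt <- t %% params$period
  params$amplitude *
    (stats::plogis((tt - tau) / params$w_depol) -
       stats::plogis((tt - tau - params$apd) / params$w_repol))
}

#' Pericardial potential field on a space-time grid
#'
#' @param n_sigma Number of collocation points in `s`.
#' @param times Time instants (ms).
#' @param params See [potential_params()].
#' @return Matrix `n_sigma x length(times)` of potential values.
#' @export
potential_field <- function(n_sigma, times, params = potential_params()) {
  s <- collocation_grid(n_sigma)
  outer(s, times, reference_potential, params = params)
}

#' Solve the forward problem on one geometry snapshot
#'
#' Chest trace of the harmonic extension of the pericardial values `u`
#' (homogeneous unit-conductivity torso, zero Neumann data on the chest).
#'
#' @param blocks Assembled [assemble_blocks()] for the snapshot.
#' @param u Pericardial values at the Sigma collocation points.
#' @return Chest trace vector of length `n_gamma`.
#' @export
forward_solve <- function(blocks, u) {
  solve_bvp(blocks, u)$rho0_gamma
}

#' Add measurement noise to a chest recording
#'
#' Adds iid zero-mean Gaussian noise of the given variance to every
#' space-time sample and reports the resulting signal-to-noise ratio
#' `10 log10(mean(y^2) / variance)` in dB.
#'
#' @param y Chest potential matrix (`n_gamma x n_t`) or vector.
#' @param variance Noise variance (potential squared units).
#' @param seed Integer seed (reproducible).
#' @return An object of class `chest_recording`: list with `y` (noisy
#'   data), `variance`, `seed` and `snr_db`.
#' @export
add_noise <- function(y, variance, seed = 1L) {
  if (variance < 0) stopf("variance must be non-negative")
  y <- as.matrix(y)
  noisy <- if (variance == 0) y else
    y + with_seed(seed, matrix(stats::rnorm(length(y), 0, sqrt(variance)),
                               nrow(y), ncol(y)))
  structure(list(y = noisy, variance = variance, seed = as.integer(seed),
                 snr_db = if (variance > 0)
                   10 * log10(mean(y^2) / variance) else Inf),
            class = "chest_recording")
}
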