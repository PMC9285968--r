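#' Space-time reference geometry
#'
#' Bundles the fixed chest curve with one pericardium curve per stored time
#' instant over one heartbeat of period `period` (ms).  Invariants: times
#' are sorted in `[0, period)`, and every pericardium curve lies strictly
#' inside the chest with positive clearance.
#'
#' @param chest A [closed_curve()] with role `"chest"`.
#' @param pericardium List of [closed_curve()]s with role `"pericardium"`,
#'   one per time instant.
#' @param times Numeric vector of instants (ms), same length as
#'   `pericardium`.
#' @param period Heartbeat duration T (ms).
#' @return An object of class `space_time_geometry` with fields `chest`,
#'   `pericardium`, `times`, `period` and `hold_all` (bounding box).
#' @export
space_time_geometry <- function(chest, pericardium, times, period) {
  if (chest$role != "chest") stopf("first curve must have role 'chest'")
  if (length(pericardium) != length(times))
    stopf("one pericardium curve per time instant required")
  if (any(diff(times) <= 0) || times[1] < 0 || times[length(times)] >= period)
    stopf("times must satisfy 0 <= t_0 < ... < t_{nT-1} < period")
  chest_pts <- eval_curve(chest, collocation_grid(512L))$point
  for (j in seq_along(pericardium)) {
    crv <- pericardium[[j]]
    if (crv$role != "pericardium")
      stopf("curve %d must have role 'pericardium'", j)
    pts <- eval_curve(crv, collocation_grid(256L))$point
    inside <- pracma::inpolygon(pts[, 1], pts[, 2],
                                chest_pts[, 1], chest_pts[, 2])
    if (!all(inside))
      stopf("pericardium at t=%g is not inside the chest", times[j])
    d2 <- outer(pts[, 1], chest_pts[, 1], "-")^2 +
      outer(pts[, 2], chest_pts[, 2], "-")^2
    if (min(d2) <= 0)
      stopf("pericardium at t=%g touches the chest", times[j])
  }
  all_pts <- rbind(chest_pts,
                   do.call(rbind, lapply(pericardium, function(crv)
                     eval_curve(crv, collocation_grid(128L))$point)))
  structure(list(chest = chest, pericardium = pericardium,
                 times = as.numeric(times), period = as.numeric(period),
                 hold_all = apply(all_pts, 2, range)),
            class = "space_time_geometry")
}

#' @export
print.space_time_geometry <- function(x, ...) {
  cat(sprintf(
    "space_time_geometry: %d pericardium instants over T=%g ms\n",
    length(x$times), x$period))
  invisible(x)
}

#' Default parameters of the synthetic torso generator
#'
#' Scales emulate a mid-ventricular short-axis torso cross-section: a fixed
#' smooth chest oval of semi-axes 180 x 120 mm and a pericardium of mean
#' radius 45 mm whose enclosed area oscillates periodically over one
#' heartbeat of `period = 690` ms, maximal at diastole (`t = 0`) and
#' minimal at systole (`t_systole = 270` ms), sampled at `n_t = 50`
#' instants.  The pericardium centre places the heart close to the
#' anterior chest wall (about 15 mm clearance), as in short-axis
#' anatomy, which is what makes the chest potential genuinely sensitive
#' to the shape uncertainty near that wall.
#'
#' @param period Heartbeat duration (ms).
#' @param n_t Number of stored time instants.
#' @param t_systole Time of minimal pericardial area (ms).
#' @param chest_axes Chest semi-axes (mm).
#' @param chest_perturb Amplitude (mm) of a low-order radial perturbation of
#'   the chest oval.
#' @param peri_center Pericardium centre (mm).
#' @param peri_radius Pericardium mean radius (mm).
#' @param peri_harmonics Relative amplitudes of the pericardium radial
#'   harmonics 2 and 3.
#' @param area_amplitude Relative amplitude of the periodic radius
#'   modulation.
#' @param seed Integer seed for the (small) randomised harmonic phases.
#' @return Named list of parameters.
#' @export
torso_params <- function(period = 690, n_t = 50L, t_systole = 270,
                         chest_axes = c(180, 120), chest_perturb = 5,
                         peri_center = c(-30, 55), peri_radius = 45,
                         peri_harmonics = c(0.10, 0.05),
                         area_amplitude = 0.06, seed = 1L) {
  list(period = period, n_t = as.integer(n_t), t_systole = t_systole,
       chest_axes = chest_axes, chest_perturb = chest_perturb,
       peri_center = peri_center, peri_radius = peri_radius,
       peri_harmonics = peri_harmonics, area_amplitude = area_amplitude,
       seed = as.integer(seed))
}

# smooth 1-periodic modulation f(eta), eta = 2*pi*t/T, with a stationary
# maximum f=1 at eta=0 and a stationary minimum at eta_s (solved from a
# 2x2 linear system for the sin/sin2 corrections of cos(eta))
area_waveform <- function(eta, eta_s) {
  d <- sin(eta_s) / (2 * (cos(2 * eta_s) - cos(eta_s)))
  cvec <- -2 * d
  cos(eta) + cvec * sin(eta) + d * sin(2 * eta)
}

#' Synthesise a space-time torso geometry
#'
#' Builds a deterministic (seeded) chest + moving pericardium geometry with
#' the anatomical scales of [torso_params()].  The pericardial area is
#' maximal at `t = 0` and minimal at the stored instant nearest
#' `t_systole`.
#'
#' @param params Parameter list from [torso_params()].
#' @return A [space_time_geometry()].
#' @export
synthesize_torso <- function(params = torso_params()) {
  p <- params
  phases <- with_seed(p$seed, stats::runif(3, 0, 2 * pi))
  ns <- 64L
  s <- collocation_grid(ns)
  th <- 2 * pi * s
  # chest: oval with a mild 3rd-harmonic radial perturbation
  rad <- 1 + (p$chest_perturb / mean(p$chest_axes)) * cos(3 * th + phases[1])
  chest_pts <- cbind(p$chest_axes[1] * rad * cos(th),
                     p$chest_axes[2] * rad * sin(th))
  chest <- interp_closed_curve(chest_pts, role = "chest")
  # pericardium reference shape: perturbed circle about peri_center
  rshape <- 1 + p$peri_harmonics[1] * cos(2 * th + phases[2]) +
    p$peri_harmonics[2] * cos(3 * th + phases[3])
  base <- cbind(cos(th) * rshape, sin(th) * rshape)
  times <- (seq_len(p$n_t) - 1) * p$period / p$n_t
  eta_s <- 2 * pi * p$t_systole / p$period
  f <- area_waveform(2 * pi * times / p$period, eta_s)
  scl <- 1 + p$area_amplitude * f
  if (which.max(scl) != 1L)
    stopf("area modulation is not maximal at t=0; adjust parameters")
  if (which.min(scl) != which.min(abs(times - p$t_systole)))
    stopf("area modulation minimum is not at the systole instant")
  pericardium <- lapply(scl, function(sc) {
    pts <- cbind(p$peri_center[1] + p$peri_radius * sc * base[, 1],
                 p$peri_center[2] + p$peri_radius * sc * base[, 2])
    interp_closed_curve(pts, role = "pericardium")
  })
  space_time_geometry(chest, pericardium, times, p$period)
}

# evaluate the balanced trigonometric interpolant of the rows of `values`
# (nT x p, samples on the uniform grid j/nT of a 1-periodic function) at
# fraction x in [0,1)
trig_interp_rows <- function(values, x) {
  nt <- nrow(values)
  cc <- stats::mvfft(values) / nt
  kk <- 0:(nt - 1)
  kk <- ifelse(kk <= nt %/% 2, kk, kk - nt)
  phase <- exp(2i * pi * kk * x)
  if (nt %% 2L == 0L) {
    ny <- nt %/% 2L + 1L
    phase[ny] <- cos(2 * pi * (nt %/% 2L) * x)
  }
  Re(drop(phase %*% cc))
}

#' Pericardium curve at an arbitrary time
#'
#' Periodic trigonometric interpolation (in time) of the stored coefficient
#' arrays; exact at the stored instants.  Times outside `[0, T)` are
#' reduced modulo `T`.  Requires the stored instants to form a uniform grid
#' (as produced by [synthesize_torso()]).
#'
#' @param geometry A [space_time_geometry()].
#' @param t Time in ms.
#' @return A [closed_curve()].
#' @export
pericardium_at_time <- function(geometry, t) {
  nt <- length(geometry$times)
  t <- t %% geometry$period
  j <- which(abs(geometry$times - t) < 1e-9 * geometry$period)
  if (length(j)) return(geometry$pericardium[[j[1]]])
  if (nt == 1L) return(geometry$pericardium[[1]])
  dt <- diff(c(geometry$times, geometry$period))
  if (max(abs(dt - dt[1])) > 1e-9 * geometry$period)
    stopf("time interpolation requires a uniform time grid")
  m <- max(vapply(geometry$pericardium, function(crv) crv$order, 0L))
  pad <- function(v) c(v, rep(0, m + 1L - length(v)))
  coef_mat <- t(vapply(geometry$pericardium, function(crv)
    c(pad(crv$ax), pad(crv$bx), pad(crv$ay), pad(crv$by)),
    numeric(4L * (m + 1L))))
  v <- trig_interp_rows(coef_mat, t / geometry$period)
  i <- function(block) v[(block - 1L) * (m + 1L) + seq_len(m + 1L)]
  bx <- i(2); by <- i(4); bx[1] <- 0; by[1] <- 0
  closed_curve(i(1), bx, i(3), by, role = "pericardium",
               unit = geometry$pericardium[[1]]$unit, validate = FALSE)
}

#' Write / read a space-time geometry directory
#'
#' One CSV per curve (see [write_curve()]) plus a JSON manifest listing the
#' chest file, the pericardium files with their times, and the period.
#'
#' @param geometry A [space_time_geometry()].
#' @param dir Output directory (created if needed).
#' @return `write_geometry` returns `dir` invisibly; `read_geometry`
#'   returns a [space_time_geometry()].
#' @export
write_geometry <- function(geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curve(geometry$chest, file.path(dir, "chest.csv"))
  files <- sprintf("pericardium_%03d.csv", seq_along(geometry$times) - 1L)
  for (j in seq_along(files))
    write_curve(geometry$pericardium[[j]], file.path(dir, files[j]))
  manifest <- list(chest = "chest.csv",
                   pericardium = files,
                   times = geometry$times,
                   period = geometry$period,
                   unit = geometry$chest$unit)
  jsonlite::write_json(manifest, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "geometry.json"),
                             simplifyVector = TRUE)
  chest <- read_curve(file.path(dir, man$chest), role = "chest",
                      unit = man$unit)
  pericardium <- lapply(man$pericardium, function(f)
    read_curve(file.path(dir, f), role = "pericardium", unit = man$unit))
  space_time_geometry(chest, pericardium, man$times, man$period)
}
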