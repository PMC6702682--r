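#' Central-difference numerical Hessian
#'
#' Second derivatives of a scalar function by central differences,
#' symmetrized as `(H + t(H)) / 2`. With `richardson = TRUE` each entry is
#' Richardson-extrapolated from steps `step` and `step / 2`.
#'
#' @param fn scalar function of a numeric vector (or a `surface_backend`,
#'   in which case its energy function is used).
#' @param x expansion point.
#' @param step finite-difference step in each coordinate's native unit.
#' @param richardson logical; fourth-order extrapolation.
#' @return symmetric matrix `length(x) x length(x)`.
#' @export
numerical_hessian <- function(fn, x, step = 1e-3, richardson = FALSE) {
  if (inherits(fn, "surface_backend")) {
    s <- fn
    fn <- function(q) surface_energy(s, q)
  }
  stopifnot(step > 0)
  h2 <- function(h) {
    n <- length(x)
    H <- matrix(0, n, n)
    f0 <- fn(x)
    for (i in seq_len(n)) {
      ei <- replace(numeric(n), i, h)
      H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
      if (i < n) for (j in (i + 1):n) {
        ej <- replace(numeric(n), j, h)
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
    H
  }
  H <- if (richardson) (4 * h2(step / 2) - h2(step)) / 3 else h2(step)
  (H + t(H)) / 2
}

#' Harmonic frequencies from a Hessian
#'
#' Mass-weights the Hessian (`H[i,j] / sqrt(m_i m_j)`), diagonalizes, and
#' maps each eigenvalue to `sign(lambda) * sqrt(abs(lambda)) * conv`,
#' sorted ascending. Imaginary modes are reported as negative reals (a
#' transition state shows exactly one negative frequency).
#'
#' In the package's natural-unit convention (energies in cm^-1, hbar = 1,
#' unit-scale coordinates) `conv = 1` returns wavenumbers directly. For a
#' Hessian in hartree/bohr^2 with masses in amu use
#' `conv = unit_constants[["hessian_au_to_wavenumber"]]`.
#'
#' @param hessian symmetric matrix.
#' @param masses positive per-DOF masses.
#' @param conv multiplicative conversion of `sqrt(lambda)` to cm^-1.
#' @return list with `frequencies` (ascending, cm^-1) and `modes`
#'   (mass-weighted normal modes, one column per frequency).
#' @export
harmonic_frequencies <- function(hessian, masses = rep(1, nrow(hessian)),
                                 conv = 1) {
  H <- as.matrix(hessian)
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("hessian is not symmetric within tolerance")
  stopifnot(all(masses > 0), length(masses) == nrow(H))
  w <- 1 / sqrt(masses)
  Hmw <- H * outer(w, w)
  e <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  freq <- sign(e$values) * sqrt(abs(e$values)) * conv
  ord <- order(freq)
  list(frequencies = freq[ord], modes = e$vectors[, ord, drop = FALSE])
}

#' Stationary point container
#'
#' @param geometry coordinate vector.
#' @param energy energy (cm^-1, relative to the surface's declared zero).
#' @param hessian symmetric matrix at the geometry.
#' @param frequencies,modes output of [harmonic_frequencies()].
#' @param kind `"minimum"`, `"ts"` or `"higher"`.
#' @return object of class `stationary_point`.
#' @export
stationary_point <- function(geometry, energy, hessian, frequencies, modes,
                             kind = c("minimum", "ts", "higher")) {
  kind <- match.arg(kind)
  n_neg <- sum(frequencies < 0)
  if (kind == "minimum" && n_neg != 0L)
    stop("minimum declared but negative frequencies present")
  if (kind == "ts" && n_neg != 1L)
    stop("transition state declared but negative-frequency count is not one")
  structure(list(geometry = geometry, energy = energy, hessian = hessian,
                 frequencies = frequencies, modes = modes, kind = kind),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("stationary point (%s), E = %.4f cm-1\n", x$kind, x$energy))
  cat("  frequencies (cm-1):", paste(sprintf("%.1f", x$frequencies),
                                     collapse = " "), "\n")
  invisible(x)
}

#' Newton refinement of a stationary point
#'
#' Full-Newton iterations `x <- x - solve(H, g)` until the gradient
#' infinity norm falls below `tol`; this converges to minima and saddle
#' points alike from a guess in the right basin. The Hessian signature of
#' the converged point is checked against the requested `kind`; a mismatch
#' is reported with a warning and the actual kind returned.
#'
#' @param surface a `surface_backend`.
#' @param guess starting coordinates.
#' @param kind expected character of the point.
#' @param tol gradient infinity-norm threshold (cm^-1 per coordinate unit).
#' @param max_iter maximum Newton iterations.
#' @param step Hessian finite-difference step.
#' @return a [stationary_point()]; attribute `iterations` records the count.
#' @export
refine_stationary <- function(surface, guess, kind = c("minimum", "ts"),
                              tol = 1e-6, max_iter = 50L, step = 1e-4) {
  kind <- match.arg(kind)
  x <- as.numeric(guess)
  for (it in 0:max_iter) {
    g <- surface_gradient(surface, x)
    if (max(abs(g)) < tol) break
    if (it == max_iter)
      stop(sprintf("Newton refinement did not converge in %d iterations (|g|_inf = %.3g)",
                   max_iter, max(abs(g))))
    H <- numerical_hessian(surface, x, step = step)
    x <- x - solve(H, g)
  }
  H <- numerical_hessian(surface, x, step = step, richardson = TRUE)
  hf <- harmonic_frequencies(H, surface$masses)
  n_neg <- sum(hf$frequencies < 0)
  actual <- if (n_neg == 0L) "minimum" else if (n_neg == 1L) "ts" else "higher"
  if (actual != kind)
    warning(sprintf("converged to a %s (%d negative frequencies), not the requested %s",
                    actual, n_neg, kind))
  sp <- stationary_point(x, surface_energy(surface, x), H, hf$frequencies,
                         hf$modes, kind = actual)
  attr(sp, "iterations") <- it
  sp
}

#' Microcanonical normal-mode sampling at a minimum
#'
#' Distributes a total vibrational energy classically and randomly over the
#' normal modes: per-mode energies are a seeded uniform draw on the simplex
#' (normalized exponential variates), and each mode receives a harmonic
#' displacement/velocity at a random phase,
#' `Q_k = sqrt(2 E_k) / omega_k * sin(theta)`,
#' `P_k = sqrt(2 E_k) * cos(theta)`. The harmonic energies sum exactly to
#' the request; the anharmonic residual of the actual surface energy is
#' recorded in attribute `energy_residual`.
#'
#' @param sp a [stationary_point()] of kind `"minimum"`.
#' @param total_energy total vibrational energy (cm^-1, > 0).
#' @param seed RNG seed.
#' @param masses per-DOF masses (default from the `surface`, else unit).
#' @param surface optional backend, used to report the anharmonic residual.
#' @param phases optional fixed phases (radians), overriding the draw.
#' @return list with `geometry`, `velocities`, `mode_energies`, `phases`.
#' @export
normal_mode_sample <- function(sp, total_energy, seed = 1L, masses = NULL,
                               surface = NULL, phases = NULL) {
  stopifnot(inherits(sp, "stationary_point"))
  if (sp$kind != "minimum")
    stop("normal-mode sampling requires a minimum (no imaginary modes)")
  stopifnot(total_energy > 0)
  if (is.null(masses))
    masses <- if (!is.null(surface)) surface$masses else rep(1, length(sp$geometry))
  n <- length(sp$geometry)
  draws <- with_seed(seed, list(e = stats::rexp(n), th = stats::runif(n, 0, 2 * pi)))
  e_mode <- total_energy * draws$e / sum(draws$e)
  if (is.null(phases)) phases <- draws$th
  omega <- sp$frequencies
  Qd <- sqrt(2 * e_mode) / omega * sin(phases)
  Pd <- sqrt(2 * e_mode) * cos(phases)
  w <- 1 / sqrt(masses)
  geometry <- sp$geometry + w * drop(sp$modes %*% Qd)
  velocities <- w * drop(sp$modes %*% Pd)
  out <- list(geometry = geometry, velocities = velocities,
              mode_energies = e_mode, phases = phases)
  if (!is.null(surface)) {
    actual <- surface_energy(surface, geometry) - sp$energy +
      0.5 * sum(masses * velocities^2)
    attr(out, "energy_residual") <- actual - total_energy
  }
  out
}

#' Velocity-Verlet propagation on a surface
#'
#' Microcanonical integration with the standard velocity-Verlet scheme.
#' Every step is stored, including the initial frame, so a run of
#' `n_steps` produces `n_steps + 1` frames.
#'
#' @param surface a `surface_backend` (analytic gradient used if the
#'   family provides one).
#' @param state list with `geometry` and `velocities` (e.g. from
#'   [normal_mode_sample()]).
#' @param dt time step, in the unit named by `time_unit`.
#' @param n_steps number of steps.
#' @param masses per-DOF masses (default from the surface).
#' @param time_unit `"fs"` (default; converted internally to the natural
#'   time unit of the hbar = 1, energy-in-cm^-1 convention, 1 fs =
#'   `unit_constants["fs_to_natural_time"]`) or `"natural"` for
#'   closed-form work in natural units directly. A mode of wavenumber
#'   `w` cm^-1 has period `1e7 / (2.9979e10 w)` fs (about 33 fs at
#'   1000 cm^-1), so a 5 fs step resolves typical vibrations.
#' @return object of class `trajectory`: list with `time` (fs), `geometry`
#'   (frame-by-DOF matrix), `potential`, `kinetic`, `total_energy`
#'   (initial), `fluctuation` (maximal relative total-energy deviation,
#'   the bounded oscillation a symplectic integrator exhibits) and `drift`
#'   (secular relative energy change between the final and initial frame).
#' @export
propagate_verlet <- function(surface, state, dt, n_steps, masses = NULL,
                             time_unit = c("fs", "natural")) {
  stopifnot(dt > 0, n_steps >= 1)
  time_unit <- match.arg(time_unit)
  dt_in <- dt
  if (time_unit == "fs")
    dt <- dt * unit_constants[["fs_to_natural_time"]]
  if (is.null(masses)) masses <- surface$masses
  q <- as.numeric(state$geometry)
  v <- as.numeric(state$velocities)
  nf <- n_steps + 1L
  Q <- matrix(NA_real_, nf, length(q))
  pe <- ke <- numeric(nf)
  a <- -surface_gradient(surface, q) / masses
  Q[1, ] <- q; pe[1] <- surface_energy(surface, q); ke[1] <- 0.5 * sum(masses * v^2)
  for (s in seq_len(n_steps)) {
    q <- q + v * dt + 0.5 * a * dt^2
    a_new <- -surface_gradient(surface, q) / masses
    v <- v + 0.5 * (a + a_new) * dt
    a <- a_new
    Q[s + 1L, ] <- q
    pe[s + 1L] <- surface_energy(surface, q)
    ke[s + 1L] <- 0.5 * sum(masses * v^2)
  }
  tot <- pe + ke
  scale <- max(abs(tot[1]), 1e-10)
  structure(list(time = (0:n_steps) * dt_in, geometry = Q, potential = pe,
                 kinetic = ke, total_energy = tot[1],
                 fluctuation = max(abs(tot - tot[1])) / scale,
                 drift = abs(tot[nf] - tot[1]) / scale,
                 dt = dt_in, time_unit = time_unit, n_steps = n_steps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, dt = %g fs, E = %.4f cm-1, drift %.2e (fluctuation %.2e)\n",
              length(x$time), x$dt, x$total_energy, x$drift, x$fluctuation))
  invisible(x)
}

#' Re-evaluate trajectory energies with another surface
#'
#' Overlay check: energies along a trajectory propagated on one surface are
#' recomputed with a second surface (e.g. a refitted parametrization) and
#' compared frame by frame.
#'
#' @param traj a [propagate_verlet()] trajectory.
#' @param surface the surface to re-evaluate with.
#' @return list with `reference` and `reevaluated` energy vectors and their
#'   `rmse`.
#' @export
trajectory_energy_compare <- function(traj, surface) {
  e2 <- surface_energies(surface, traj$geometry)
  list(reference = traj$potential, reevaluated = e2,
       rmse = sqrt(mean((e2 - traj$potential)^2)))
}

#' Export a trajectory as a CSV energy table (and optionally XYZ frames)
#'
#' @param traj a trajectory.
#' @param csv_path path for the `time, potential, kinetic, total` table.
#' @param xyz_path optional multi-frame XYZ path; requires `elements` and a
#'   coordinate count divisible by 3.
#' @param elements element symbols for the XYZ export.
#' @return invisible `csv_path`.
#' @export
export_trajectory <- function(traj, csv_path, xyz_path = NULL, elements = NULL) {
  utils::write.csv(data.frame(time = traj$time, potential = traj$potential,
                              kinetic = traj$kinetic,
                              total = traj$potential + traj$kinetic),
                   csv_path, row.names = FALSE)
  if (!is.null(xyz_path)) {
    nf <- ncol(traj$geometry)
    if (nf %% 3L != 0L || is.null(elements))
      stop("XYZ export needs 3N coordinates and element symbols")
    frames <- lapply(seq_len(nrow(traj$geometry)), function(i)
      matrix(traj$geometry[i, ], ncol = 3, byrow = TRUE))
    write_xyz(frames, xyz_path, elements,
              comments = sprintf("t = %g fs", traj$time))
  }
  invisible(csv_path)
}
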