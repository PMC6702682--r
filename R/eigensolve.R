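#' Dense product-grid vibrational Hamiltonian
#'
#' Builds the direct-product DVR Hamiltonian
#' `H = sum_k (1 / 2 m_k) T^(k) (x) I + diag(V)` for up to three degrees of
#' freedom, with `T^(k)` the grid's `-d^2/dq^2` matrix. The first DOF is
#' the fastest-running index of the composite basis (column-major
#' vectorization). This dense eigensolver replaces full multiconfiguration
#' machinery for low-dimensional validation; the kinetic operator is
#' diagonal-mass Cartesian-like, curvilinear kinetic couplings are out of
#' scope.
#'
#' @param grids list of 1-3 [build_dvr()] grids.
#' @param masses positive per-DOF masses.
#' @param potential potential values: a numeric array on the grid, a
#'   [tucker_potential()], or an energy backend (function of coordinates or
#'   surface object).
#' @param dim_cap guard on the composite dimension (dense storage grows as
#'   its square).
#' @return object of class `grid_hamiltonian`: list with `matrix`
#'   (symmetric), `grids`, `masses`, `dim`.
#' @export
build_hamiltonian <- function(grids, masses, potential, dim_cap = 20000L) {
  if (inherits(grids, "dvr_grid")) grids <- list(grids)
  n <- grid_sizes(grids)
  f <- length(n)
  stopifnot(f >= 1L, f <= 3L, length(masses) == f)
  if (any(masses <= 0)) stop("masses must be positive")
  N <- prod(as.numeric(n))
  if (N > dim_cap) stop(sprintf("composite dimension %d exceeds cap %d", N, dim_cap))

  V <- if (inherits(potential, "tucker_potential")) {
    sop_full_tensor(potential)
  } else if (is.array(potential) || (is.numeric(potential) && f == 1L)) {
    array(potential, dim = n)
  } else {
    tensor_from_backend(potential, grids)
  }
  if (!identical(as.integer(dim(V)), as.integer(n)))
    stop("potential array shape does not match the grids")

  H <- diag(as.vector(V), N, N)
  for (k in seq_len(f)) {
    mats <- lapply(seq_len(f), function(j)
      if (j == k) grids[[k]]$kinetic / (2 * masses[k]) else diag(n[j]))
    H <- H + Reduce(kronecker, rev(mats))  # first DOF fastest (column-major)
  }
  H <- (H + t(H)) / 2
  structure(list(matrix = H, grids = grids, masses = masses, dim = N),
            class = "grid_hamiltonian")
}

#' Lowest vibrational eigenvalues of a grid Hamiltonian
#'
#' @param H a [build_hamiltonian()] object (or a bare symmetric matrix).
#' @param k number of levels (`< dim`).
#' @return object of class `eigen_report`: list with `zpe` (absolute
#'   ground-state energy), `levels` (length `k`, ascending, relative to
#'   the ground state so `levels[1] = 0`), and `vectors` (grid amplitudes,
#'   one column per level).
#' @export
lowest_eigenpairs <- function(H, k = 20L) {
  M <- if (inherits(H, "grid_hamiltonian")) H$matrix else as.matrix(H)
  if (k >= nrow(M)) stop("k must be smaller than the Hamiltonian dimension")
  e <- eigen(M, symmetric = TRUE)
  idx <- nrow(M):(nrow(M) - k + 1L)  # eigen() sorts descending
  vals <- e$values[idx]
  structure(list(zpe = vals[1], levels = vals - vals[1],
                 vectors = e$vectors[, idx, drop = FALSE]),
            class = "eigen_report")
}

#' @export
print.eigen_report <- function(x, ...) {
  cat(sprintf("eigenreport: ZPE = %.4f cm-1, %d levels\n", x$zpe,
              length(x$levels)))
  print(round(x$levels, 2))
  invisible(x)
}

#' RMSE and mean absolute deviation between two level ladders
#'
#' Both ladders are compared entry by entry over their full length,
#' including the leading zero ground-state row, which is the convention
#' that reproduces published comparison tables for referenced levels.
#' `mad` here is the mean absolute deviation.
#'
#' @param levels,reference_levels equal-length numeric vectors of energies
#'   relative to their ground states.
#' @return list with `rmse` and `mad` (cm^-1).
#' @export
eigen_rmse <- function(levels, reference_levels) {
  if (length(levels) != length(reference_levels))
    stop("level vectors must have equal length")
  d <- levels - reference_levels
  list(rmse = sqrt(mean(d^2)), mad = mean(abs(d)))
}

#' Spectrum from the autocorrelation function of a propagated state
#'
#' Propagates an initial grid amplitude vector by spectral expansion in the
#' Hamiltonian's eigenpairs, forms the autocorrelation
#' `a(t) = <psi(0)|psi(t)> = sum_n |c_n|^2 exp(-i E_n t)`, applies a
#' cos^2 window, and returns its Fourier transform on an energy axis with
#' the located peaks. Energies and the time axis are conjugate in natural
#' units (`hbar = 1`).
#'
#' @param psi0 normalized initial amplitude vector on the grid.
#' @param H a [build_hamiltonian()] object or symmetric matrix.
#' @param t_max propagation time.
#' @param dt time step.
#' @param energy_grid energies at which to evaluate the spectrum (default:
#'   a fine grid spanning the populated eigenvalues).
#' @return list with `energy`, `intensity`, `peaks` (energies of local
#'   maxima with intensity above 5% of the maximum, i.e. above the Hann
#'   window's sidelobe level), `weights` (per eigenvalue populations
#'   `|c_n|^2`).
#' @export
autocorrelation_spectrum <- function(psi0, H, t_max, dt, energy_grid = NULL) {
  M <- if (inherits(H, "grid_hamiltonian")) H$matrix else as.matrix(H)
  psi0 <- as.numeric(psi0)
  nrm <- sqrt(sum(psi0^2))
  if (abs(nrm - 1) > 1e-8) stop("initial vector must be normalized")
  e <- eigen(M, symmetric = TRUE)
  cn2 <- drop(crossprod(e$vectors, psi0))^2
  pop <- cn2 > 1e-12
  tt <- seq(0, t_max, by = dt)
  a <- vapply(tt, function(t) sum(cn2 * exp(-1i * e$values * t)),
              complex(1))
  w <- cos(pi * tt / (2 * t_max))^2
  if (is.null(energy_grid)) {
    rng <- range(e$values[pop])
    pad <- 0.1 * (diff(rng) + 1)
    energy_grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 2048L)
  }
  intensity <- vapply(energy_grid, function(om)
    Re(sum(w * a * exp(1i * om * tt)) * dt), numeric(1))
  i <- 2:(length(intensity) - 1L)
  # local maxima, tolerant of flat-topped (plateau) peaks; adjacent plateau
  # points collapse to their mean energy
  is_peak <- intensity[i] >= intensity[i - 1L] &
    intensity[i] >= intensity[i + 1L] &
    (intensity[i] > intensity[i - 1L] | intensity[i] > intensity[i + 1L]) &
    intensity[i] > 0.05 * max(intensity)  # above the ~2.7% Hann sidelobes
  pk_idx <- i[is_peak]
  peaks <- if (length(pk_idx)) {
    grp <- cumsum(c(1L, diff(pk_idx) > 1L))
    as.numeric(tapply(energy_grid[pk_idx], grp, mean))
  } else numeric()
  list(energy = energy_grid, intensity = intensity, peaks = peaks,
       weights = cn2)
}

#' Published benchmark vibrational levels for the HONO cis-trans system
#'
#' The 21 lowest vibrational eigenvalues (ground state referenced to zero)
#' of the 6D HONO cis-trans isomerization surface, as reported in the
#' literature for four parametrizations: the unmodified PM7 semiempirical
#' surface, two reparametrized surfaces fitted on 53 and 1084 reference
#' points, and the coupled-cluster-quality analytical reference surface.
#' Shipped as a plain-text fixture for validating [eigen_rmse()].
#'
#' @return data frame with columns `pm7`, `srp53`, `srp1084`, `analytical`
#'   (cm^-1), 21 rows.
#' @export
hono_reference_levels <- function() {
  path <- system.file("extdata", "hono_levels.tsv", package = "sopes",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

#' Published primitive-grid definition for 6D HONO
#'
#' The DVR grid used in the literature for HONO in internal coordinates:
#' per degree of freedom the DVR family (harmonic-oscillator Hermite or
#' cosine), point count and coordinate range (lengths in bohr, the torsion
#' in radians over `[0, pi]`).
#'
#' @param build logical; also construct the [build_dvr()] grids.
#' @return data frame with columns `dof`, `dvr`, `n`, `first`, `last`
#'   (and, with `build = TRUE`, attribute `grids`).
#' @export
hono_grid_definition <- function(build = FALSE) {
  path <- system.file("extdata", "hono_grid.tsv", package = "sopes",
                      mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#")
  if (build) {
    kinds <- c(HO = "harmonic", cos = "cosine")
    attr(df, "grids") <- lapply(seq_len(nrow(df)), function(i)
      build_dvr(kinds[[df$dvr[i]]], df$n[i], c(df$first[i], df$last[i])))
  }
  df
}
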