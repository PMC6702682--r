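#' Named parameter vector with box bounds
#'
#' The parameters of a parametrized energy backend (semiempirical-style):
#' named values with per-parameter lower/upper bounds. The dimension
#' depends only on the surface family, not on the system size.
#'
#' @param names character labels.
#' @param values numeric values.
#' @param lower,upper per-parameter bounds (recycled if scalar).
#' @return object of class `param_vector`.
#' @export
param_vector <- function(names, values, lower = -Inf, upper = Inf) {
  stopifnot(length(names) == length(values))
  lower <- rep_len(as.numeric(lower), length(values))
  upper <- rep_len(as.numeric(upper), length(values))
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12))
    stop("parameter values outside bounds")
  structure(list(names = as.character(names), values = as.numeric(values),
                 lower = lower, upper = upper),
            class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  df <- data.frame(name = x$names, value = x$values,
                   lower = x$lower, upper = x$upper)
  cat(sprintf("param_vector with %d parameters\n", length(x$values)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Box bounds at a relative half-width around reference parameters
#'
#' @param pv a [param_vector()].
#' @param width relative half-width (default 0.5, i.e. +/-50%). Parameters
#'   with value zero get a degenerate box and stay fixed.
#' @return a `param_vector` with the same values and widened bounds.
#' @export
default_param_bounds <- function(pv, width = 0.5) {
  half <- width * abs(pv$values)
  param_vector(pv$names, pv$values, pv$values - half, pv$values + half)
}

#' Multiplicative perturbation of a parameter vector
#'
#' Each value is scaled by a seeded uniform factor in
#' `[1 - relative_scale, 1 + relative_scale]`; results escaping the bounds
#' are clipped and flagged. Plays the role of a degraded starting
#' parametrization for recovery experiments.
#'
#' @param pv a [param_vector()] (bounds respected).
#' @param relative_scale maximal relative perturbation (`>= 0`).
#' @param seed RNG seed.
#' @return a `param_vector` with attributes `percent_deviation` (per
#'   parameter, vs the input) and `clipped` (logical).
#' @export
perturb_params <- function(pv, relative_scale, seed = 1L) {
  stopifnot(inherits(pv, "param_vector"), relative_scale >= 0)
  fac <- with_seed(seed, runif(length(pv$values), 1 - relative_scale,
                               1 + relative_scale))
  vals <- pv$values * fac
  clipped <- vals < pv$lower | vals > pv$upper
  vals <- pmin(pmax(vals, pv$lower), pv$upper)
  out <- param_vector(pv$names, vals, pv$lower, pv$upper)
  attr(out, "percent_deviation") <-
    ifelse(pv$values != 0, 100 * (vals - pv$values) / pv$values, 0)
  attr(out, "clipped") <- clipped
  if (any(clipped))
    warning(sprintf("%d perturbed parameters clipped to bounds", sum(clipped)))
  out
}

# --- toy torsion surface family --------------------------------------------

#' Analytic torsion-coupled chain surface (toy backend)
#'
#' A parametrized analytic surface family standing in for a real electronic
#' structure backend: `f - 1` "chain" coordinates (bond-length-like)
#' harmonically bound around torsion-dependent reference values, bilinearly
#' coupled, plus a two-term torsional Fourier potential:
#' \deqn{V = \sum_k \tfrac12 a_k (q_k - r_k(\phi))^2
#'         + \sum_{k<l} b_{kl} (q_k - r_k)(q_l - r_l)
#'         + c_1 (1 - \cos\phi) + c_2 (1 - \cos 2\phi)}
#' with \eqn{r_k(\phi) = q0_k + d_k \cos\phi}. With `c1 = 0` and `c2 > 0`
#' the surface has two minima (at torsion 0 and pi, a cis/trans surrogate)
#' separated by a barrier of height `2 c2` at `phi = pi/2`; with all
#' couplings zero it is separable. Energies are in cm^-1, chain coordinates
#' in abstract length units, the torsion in radians (periodic, period 2 pi).
#'
#' @param f number of degrees of freedom (the last one is the torsion).
#' @param a curvatures of the chain wells (length `f - 1`).
#' @param d torsion-coupling amplitudes of the reference values.
#' @param b upper-triangle bilinear couplings (length `choose(f-1, 2)`,
#'   order (1,2), (1,3), ..., (2,3), ...).
#' @param c1,c2 torsional Fourier coefficients (cm^-1).
#' @param q0 chain reference values at `phi = pi/2`.
#' @param masses per-DOF masses (default unit).
#' @param morse_beta optional per-chain-DOF Morse range parameters: with
#'   `beta_k` set, the harmonic well `a_k u^2 / 2` is replaced by the
#'   Morse well `D_k (1 - exp(-beta_k u))^2` with `D_k = a_k / (2
#'   beta_k^2)`, which preserves the curvature `a_k` at the bottom (and
#'   all stationary points of the family) while making the surface
#'   genuinely anharmonic. `NULL` keeps the harmonic form.
#' @return object of classes `toy_torsion_surface`, `surface_backend`.
#' @export
toy_torsion_surface <- function(f = 3L, a, d, b, c1 = 0, c2, q0,
                                masses = rep(1, f), morse_beta = NULL) {
  f <- as.integer(f)
  nc <- f - 1L
  np <- (nc * (nc - 1L)) %/% 2L
  stopifnot(f >= 2L, length(a) == nc, length(d) == nc, length(q0) == nc,
            length(b) == np, length(masses) == f, all(masses > 0))
  if (!is.null(morse_beta))
    stopifnot(length(morse_beta) == nc, all(morse_beta > 0))
  B <- matrix(0, nc, nc)
  if (np > 0) { B[upper.tri(B)] <- b; B <- B + t(B) }
  structure(list(f = f, a = as.numeric(a), d = as.numeric(d),
                 b = as.numeric(b), B = B, c1 = as.numeric(c1),
                 c2 = as.numeric(c2), q0 = as.numeric(q0),
                 morse_beta = if (!is.null(morse_beta)) as.numeric(morse_beta),
                 masses = as.numeric(masses),
                 coord_names = c(paste0("q", seq_len(nc)), "phi"),
                 periodic = c(rep(FALSE, nc), TRUE),
                 period = c(rep(NA_real_, nc), 2 * pi)),
            class = c("toy_torsion_surface", "surface_backend"))
}

#' @export
print.toy_torsion_surface <- function(x, ...) {
  cat(sprintf("toy torsion surface: %d DOFs (%d chain + torsion), barrier 2*c2 = %.1f cm-1\n",
              x$f, x$f - 1L, 2 * x$c2))
  invisible(x)
}

#' Energy, gradient and parameter access of a surface backend
#'
#' `surface_energy()` evaluates one geometry; `surface_energies()` a matrix
#' of geometries (one row each); `surface_gradient()` returns the analytic
#' gradient where the family provides one, otherwise central differences.
#'
#' @param surface a `surface_backend` object.
#' @param q numeric coordinate vector (length `surface$f`).
#' @param ... passed to methods.
#' @return energy in cm^-1 (or gradient vector).
#' @export
surface_energy <- function(surface, q, ...) UseMethod("surface_energy")

#' @rdname surface_energy
#' @export
surface_energy.toy_torsion_surface <- function(surface, q, ...) {
  drop(surface_energies(surface, matrix(q, nrow = 1)))
}

#' @rdname surface_energy
#' @param Q numeric matrix, one geometry per row.
#' @export
surface_energies <- function(surface, Q, ...) UseMethod("surface_energies")

#' @export
surface_energies.toy_torsion_surface <- function(surface, Q, ...) {
  Q <- as.matrix(Q)
  stopifnot(ncol(Q) == surface$f)
  nc <- surface$f - 1L
  phi <- Q[, surface$f]
  r <- matrix(surface$q0, nrow(Q), nc, byrow = TRUE) +
    outer(cos(phi), surface$d)
  u <- Q[, seq_len(nc), drop = FALSE] - r
  wells <- if (is.null(surface$morse_beta)) {
    0.5 * drop((u^2) %*% surface$a)
  } else {
    bet <- surface$morse_beta
    D <- surface$a / (2 * bet^2)
    m <- (1 - exp(-sweep(u, 2, bet, `*`)))^2
    drop(m %*% D)
  }
  e <- wells + 0.5 * rowSums((u %*% surface$B) * u) +
    surface$c1 * (1 - cos(phi)) + surface$c2 * (1 - cos(2 * phi))
  as.numeric(e)
}

#' @export
surface_energies.surface_backend <- function(surface, Q, ...) {
  apply(as.matrix(Q), 1, function(q) surface_energy(surface, q))
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, q, ...) UseMethod("surface_gradient")

#' @export
surface_gradient.toy_torsion_surface <- function(surface, q, ...) {
  nc <- surface$f - 1L
  phi <- q[surface$f]
  r <- surface$q0 + surface$d * cos(phi)
  u <- q[seq_len(nc)] - r
  g_well <- if (is.null(surface$morse_beta)) {
    surface$a * u
  } else {
    ex <- exp(-surface$morse_beta * u)
    (surface$a / surface$morse_beta) * ex * (1 - ex)
  }
  g_chain <- g_well + drop(surface$B %*% u)
  g_phi <- sum(g_chain * surface$d * sin(phi)) +
    surface$c1 * sin(phi) + 2 * surface$c2 * sin(2 * phi)
  c(g_chain, g_phi)
}

#' @export
surface_gradient.surface_backend <- function(surface, q, step = 1e-6, ...) {
  vapply(seq_along(q), function(k) {
    qp <- q; qm <- q
    qp[k] <- qp[k] + step; qm[k] <- qm[k] - step
    (surface_energy(surface, qp) - surface_energy(surface, qm)) / (2 * step)
  }, numeric(1))
}

#' Parameter-vector view of a toy surface
#'
#' @param surface a [toy_torsion_surface()].
#' @return a [param_vector()] with names `a*`, `d*`, `b*`, `c1`, `c2`, `q0*`.
#' @export
surface_params <- function(surface) {
  stopifnot(inherits(surface, "toy_torsion_surface"))
  nc <- surface$f - 1L
  bn <- if (nc > 1) {
    pr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
    paste0("b", pr[, 1], pr[, 2])
  } else character()
  # b stored in upper.tri (column-major) order; reorder to row-major labels
  nm <- c(paste0("a", 1:nc), paste0("d", 1:nc), bn, "c1", "c2",
          paste0("q0", 1:nc))
  vals <- c(surface$a, surface$d, surface$B[upper.tri(surface$B)][order_ut(nc)],
            surface$c1, surface$c2, surface$q0)
  if (!is.null(surface$morse_beta)) {
    nm <- c(nm, paste0("beta", 1:nc))
    vals <- c(vals, surface$morse_beta)
  }
  param_vector(nm, vals)
}

# permutation taking column-major upper-triangle order to row-major label order
order_ut <- function(nc) {
  if (nc < 2) return(integer())
  pr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  order(pr[, 1], pr[, 2])
}

#' Replace the parameters of a toy surface
#'
#' @param surface a [toy_torsion_surface()].
#' @param values numeric vector in [surface_params()] order, or a
#'   `param_vector`.
#' @return a new surface with the same structure and masses.
#' @export
set_surface_params <- function(surface, values) {
  stopifnot(inherits(surface, "toy_torsion_surface"))
  if (inherits(values, "param_vector")) values <- values$values
  nc <- surface$f - 1L
  np <- (nc * (nc - 1L)) %/% 2L
  has_morse <- !is.null(surface$morse_beta)
  stopifnot(length(values) == 2L * nc + np + 2L + nc + if (has_morse) nc else 0L)
  i <- 0L
  a <- values[i + 1:nc]; i <- i + nc
  d <- values[i + 1:nc]; i <- i + nc
  b_row <- if (np > 0) values[i + 1:np] else numeric(); i <- i + np
  c1 <- values[i + 1L]; c2 <- values[i + 2L]; i <- i + 2L
  q0 <- values[i + 1:nc]; i <- i + nc
  bet <- if (has_morse) values[i + 1:nc]
  b <- b_row
  if (np > 0) b[order_ut(nc)] <- b_row  # back to column-major storage
  toy_torsion_surface(surface$f, a = a, d = d, b = b, c1 = c1, c2 = c2,
                      q0 = q0, masses = surface$masses, morse_beta = bet)
}

#' Deterministic reference instance of the toy family
#'
#' Draws a fixed, documented parameter set (per seed) with magnitudes
#' typical of a small covalent molecule: chain curvatures giving harmonic
#' wavenumbers of roughly 550-1400 cm^-1 at unit mass, a torsional barrier
#' of 3000-5000 cm^-1 (`c1 = 0`, symmetric double well), bilinear couplings
#' up to 10% of the geometric-mean curvature, and torsion-dependent
#' reference-value shifts of 0.04-0.12 length units.
#'
#' @param seed RNG seed selecting the instance.
#' @param f number of DOFs (3 or 6 are the intended sizes).
#' @param morse logical; draw Morse range parameters (`beta` in 2-4 per
#'   length unit) so the chain wells are anharmonic. The harmonic default
#'   is the family's stated form; the Morse variant exists because the
#'   quadratic family is exactly low-rank in Tucker form, which makes it
#'   unsuitable for studying decomposition error versus coarse-grid
#'   density.
#' @return a [toy_torsion_surface()].
#' @export
toy_reference <- function(seed = 0L, f = 3L, morse = FALSE) {
  nc <- f - 1L
  np <- (nc * (nc - 1L)) %/% 2L
  with_seed(seed, {
    a <- runif(nc, 3e5, 2e6)
    d <- runif(nc, 0.04, 0.12)
    q0 <- runif(nc, 1.0, 2.5)
    pr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
    b <- if (np > 0)
      runif(np, -0.1, 0.1) * sqrt(a[pr[, 1]] * a[pr[, 2]]) else numeric()
    c2 <- runif(1, 1500, 2500)
    bet <- if (morse) runif(nc, 2, 4)
    toy_torsion_surface(f, a = a, d = d, b = b, c1 = 0, c2 = c2, q0 = q0,
                        morse_beta = bet)
  })
}

# --- external program adapter ----------------------------------------------

#' Adapter exposing an external energy program as a surface backend
#'
#' Dispatches one external process run per geometry: the input template is
#' instantiated with the geometry and current parameter values, the program
#' is invoked, and the energy parsed from its standard output with a
#' regular expression. Results are cached by (geometry, parameters) so
#' repeated geometries launch no additional processes.
#'
#' @param program_spec list with elements `command` (executable path),
#'   `args` (optional character vector), `input_template` (string
#'   containing `{{geometry}}` and optionally `{{params}}` placeholders),
#'   `input_file` (name of the input file written into `workdir`),
#'   `energy_pattern` (regex whose first capture group is the energy),
#'   optional `f` (DOF count) and `params` (a [param_vector()]).
#' @param workdir working directory for input files.
#' @return object of classes `external_backend`, `surface_backend`.
#' @export
external_adapter <- function(program_spec, workdir = tempdir()) {
  stopifnot(is.list(program_spec), !is.null(program_spec$command),
            !is.null(program_spec$energy_pattern))
  if (is.null(program_spec$input_template))
    program_spec$input_template <- "{{geometry}}\n{{params}}\n"
  if (is.null(program_spec$input_file)) program_spec$input_file <- "input.dat"
  structure(list(spec = program_spec, workdir = workdir,
                 params = program_spec$params,
                 f = program_spec$f,
                 cache = new.env(parent = emptyenv()),
                 launches = local({ e <- new.env(); e$n <- 0L; e })),
            class = c("external_backend", "surface_backend"))
}

#' @export
surface_energy.external_backend <- function(surface, q, ...) {
  pvals <- if (!is.null(surface$params)) surface$params$values else numeric()
  key <- paste(sprintf("%.15g", c(q, pvals)), collapse = ",")
  if (!is.null(v <- surface$cache[[key]])) return(v)
  input <- surface$spec$input_template
  input <- gsub("{{geometry}}", paste(sprintf("%.15g", q), collapse = " "),
                input, fixed = TRUE)
  input <- gsub("{{params}}", paste(sprintf("%.15g", pvals), collapse = " "),
                input, fixed = TRUE)
  infile <- file.path(surface$workdir, surface$spec$input_file)
  writeLines(input, infile)
  surface$launches$n <- surface$launches$n + 1L
  out <- suppressWarnings(
    system2(surface$spec$command, c(surface$spec$args, infile),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("external backend exited with status %d at geometry (%s)",
                 status, paste(signif(q, 6), collapse = ", ")))
  m <- regmatches(out, regexec(surface$spec$energy_pattern, out))
  hits <- Filter(function(x) length(x) >= 2, m)
  if (length(hits) == 0L)
    stop(sprintf("could not parse energy from external output at geometry (%s)",
                 paste(signif(q, 6), collapse = ", ")))
  v <- suppressWarnings(as.numeric(hits[[1]][2]))
  if (is.na(v))
    stop(sprintf("external backend returned non-numeric energy at geometry (%s)",
                 paste(signif(q, 6), collapse = ", ")))
  surface$cache[[key]] <- v
  v
}

# --- XYZ-style geometry exchange -------------------------------------------

#' Write / read multi-frame XYZ files
#'
#' Plain XYZ: per frame an atom count line, a comment line, then one
#' `element x y z` line per atom. Used to exchange geometries with
#' external programs and to export trajectories.
#'
#' @param frames a list of numeric `n_atoms x 3` matrices (or one matrix).
#' @param path file path.
#' @param elements character vector of element symbols.
#' @param comments per-frame comment lines.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` a list with
#'   `frames` (list of matrices), `elements`, `comments`.
#' @export
write_xyz <- function(frames, path, elements, comments = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(comments)) comments <- rep("", length(frames))
  lines <- unlist(lapply(seq_along(frames), function(i) {
    m <- frames[[i]]
    c(nrow(m), comments[i],
      sprintf("%-3s %18.12f %18.12f %18.12f", elements, m[, 1], m[, 2], m[, 3]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- as.integer(trimws(lines[i]))
    if (is.na(na)) stop("malformed XYZ: expected atom count at line ", i)
    comments <- c(comments, lines[i + 1L])
    block <- lines[i + 1L + seq_len(na)]
    tok <- strsplit(trimws(block), "\\s+")
    elements <- vapply(tok, `[`, character(1), 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames <- c(frames, list(xyz))
    i <- i + 2L + na
  }
  list(frames = frames, elements = elements, comments = comments)
}
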