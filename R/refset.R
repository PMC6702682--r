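#' Reference dataset of geometries with energies and class tags
#'
#' The container for fitting/validation points: a geometry matrix (one row
#' per entry), optional reference energies and frequencies, a class tag per
#' entry from the vocabulary `core`, `1D`, `2D`, `rnd(fD)`, `LIIC`,
#' `rnd(LIIC)`, `asymp`, and a stage id.
#'
#' @param geometry numeric matrix (entries by DOFs) or vector (one entry).
#' @param energy optional numeric reference energies (cm^-1, relative).
#' @param frequencies optional list of reference frequency vectors.
#' @param tag class tag(s), recycled.
#' @param stage stage id (character), recycled.
#' @param provenance named list (pivot, displacement spec, seed, ...).
#' @return object of class `reference_dataset`.
#' @export
reference_dataset <- function(geometry, energy = NULL, frequencies = NULL,
                              tag = "core", stage = NA_character_,
                              provenance = list()) {
  if (!is.matrix(geometry)) geometry <- matrix(geometry, nrow = 1)
  n <- nrow(geometry)
  if (!is.null(energy)) {
    stopifnot(length(energy) == n)
    if (any(!is.finite(energy))) stop("reference energies must be finite")
  }
  tags <- c("core", "1D", "2D", "rnd(fD)", "LIIC", "rnd(LIIC)", "asymp")
  tag <- rep_len(as.character(tag), n)
  if (n > 0 && !all(tag %in% tags))
    stop("class tag outside the declared vocabulary: ",
         paste(setdiff(tag, tags), collapse = ", "))
  structure(list(geometry = geometry, energy = energy,
                 frequencies = frequencies, tag = tag,
                 stage = rep_len(as.character(stage), n),
                 provenance = provenance),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("reference dataset: %d entries, %d DOFs\n",
              nrow(x$geometry), ncol(x$geometry)))
  if (nrow(x$geometry)) print(table(tag = x$tag))
  invisible(x)
}

#' Number of entries in a reference dataset
#' @param ds a [reference_dataset()].
#' @return integer count.
#' @export
dataset_size <- function(ds) nrow(ds$geometry)

#' Concatenate reference datasets (no deduplication)
#' @param ... reference datasets.
#' @return a single `reference_dataset`.
#' @export
combine_datasets <- function(...) {
  parts <- Filter(function(d) dataset_size(d) > 0, list(...))
  if (length(parts) == 0L) stop("no non-empty datasets to combine")
  geom <- do.call(rbind, lapply(parts, `[[`, "geometry"))
  has_e <- vapply(parts, function(d) !is.null(d$energy), logical(1))
  energy <- if (all(has_e)) unlist(lapply(parts, `[[`, "energy")) else NULL
  reference_dataset(geom, energy = energy,
                    tag = unlist(lapply(parts, `[[`, "tag")),
                    stage = unlist(lapply(parts, `[[`, "stage")),
                    provenance = list(parts = lapply(parts, `[[`, "provenance")))
}

#' Displacement grids around a pivot geometry
#'
#' Order-1 sets displace one selected DOF at a time, leaving the remaining
#' coordinates fixed at the pivot; order-2 sets form product grids over all
#' DOF pairs. Displacement levels are `n_per_dof` nonzero multiples of
#' `delta`, alternating outward (`+1, -1, +2, -2, ...` times `delta`), so
#' the pivot itself is never duplicated into the counts.
#'
#' @param pivot a [stationary_point()] or bare coordinate vector.
#' @param order 1 or 2.
#' @param dofs DOF indices to displace (default all).
#' @param deltas per-DOF step sizes (recycled over `dofs`).
#' @param n_per_dof number of nonzero displacement levels per DOF.
#' @param bounds optional 2-row matrix (lower; upper) per DOF; out-of-bound
#'   displacements are clipped and counted in attribute `clipped`.
#' @return a `reference_dataset` tagged `"1D"` or `"2D"`.
#' @export
grid_displacements <- function(pivot, order = 1L, dofs = NULL, deltas,
                               n_per_dof, bounds = NULL) {
  x0 <- if (inherits(pivot, "stationary_point")) pivot$geometry else as.numeric(pivot)
  f <- length(x0)
  if (is.null(dofs)) dofs <- seq_len(f)
  order <- as.integer(order)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  stopifnot(all(deltas > 0), n_per_dof >= 0)
  deltas <- rep_len(deltas, length(dofs))
  if (n_per_dof == 0L)
    return(reference_dataset(matrix(numeric(), 0, f), tag = character(),
                             provenance = list(order = order)))
  j <- seq_len(n_per_dof)
  mult <- ifelse(j %% 2L == 1L, (j + 1L) %/% 2L, -(j %/% 2L))
  rows <- list()
  if (order == 1L) {
    for (i in seq_along(dofs)) {
      for (m in mult) {
        x <- x0; x[dofs[i]] <- x[dofs[i]] + m * deltas[i]
        rows[[length(rows) + 1L]] <- x
      }
    }
  } else {
    pairs <- utils::combn(seq_along(dofs), 2)
    for (p in seq_len(ncol(pairs))) {
      i1 <- pairs[1, p]; i2 <- pairs[2, p]
      for (m1 in mult) for (m2 in mult) {
        x <- x0
        x[dofs[i1]] <- x[dofs[i1]] + m1 * deltas[i1]
        x[dofs[i2]] <- x[dofs[i2]] + m2 * deltas[i2]
        rows[[length(rows) + 1L]] <- x
      }
    }
  }
  G <- do.call(rbind, rows)
  clipped <- 0L
  if (!is.null(bounds)) {
    lo <- matrix(bounds[1, ], nrow(G), f, byrow = TRUE)
    hi <- matrix(bounds[2, ], nrow(G), f, byrow = TRUE)
    clipped <- sum(G < lo | G > hi)
    if (clipped > 0) warning(sprintf("%d displaced coordinates clipped to bounds", clipped))
    G <- pmin(pmax(G, lo), hi)
  }
  ds <- reference_dataset(G, tag = if (order == 1L) "1D" else "2D",
                          provenance = list(pivot = x0, order = order,
                                            dofs = dofs, deltas = deltas,
                                            n_per_dof = n_per_dof))
  attr(ds, "clipped") <- clipped
  ds
}

#' Seeded random geometries in the full-dimensional box
#'
#' @param bounds 2-row matrix: first row lower, second row upper bounds per
#'   DOF.
#' @param n number of points (`>= 0`).
#' @param seed RNG seed; identical seeds reproduce identical geometries.
#' @return a `reference_dataset` tagged `"rnd(fD)"`.
#' @export
random_fD <- function(bounds, n, seed = 1L) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2L, n >= 0)
  f <- ncol(bounds)
  G <- if (n == 0L) matrix(numeric(), 0, f) else with_seed(seed, {
    matrix(stats::runif(n * f, rep(bounds[1, ], each = n),
                        rep(bounds[2, ], each = n)), nrow = n)
  })
  reference_dataset(G, tag = rep("rnd(fD)", n),
                    provenance = list(bounds = bounds, n = n, seed = seed))
}

#' Linear interpolation path in internal coordinates
#'
#' Straight-line interpolation between two geometries sharing a coordinate
#' system; periodic coordinates are interpolated along the shorter arc and
#' wrapped into `[0, period)`.
#'
#' @param from,to endpoint geometries ([stationary_point()] or vectors).
#' @param n_points number of path points including both endpoints
#'   (default 50).
#' @param periodic logical per-DOF periodicity flags (default none).
#' @param period period of the periodic coordinates (radians).
#' @return object of class `liic_path`: list with `endpoints`, `points`
#'   (matrix), `X` (interpolation ordinate in `[0, 1]`).
#' @export
liic <- function(from, to, n_points = 50L, periodic = NULL, period = 2 * pi) {
  a <- if (inherits(from, "stationary_point")) from$geometry else as.numeric(from)
  b <- if (inherits(to, "stationary_point")) to$geometry else as.numeric(to)
  if (length(a) != length(b)) stop("endpoint dimension mismatch")
  stopifnot(n_points >= 2L)
  if (is.null(periodic)) periodic <- rep(FALSE, length(a))
  X <- seq(0, 1, length.out = n_points)
  delta <- b - a
  wrapped <- periodic
  delta[wrapped] <- ((b[wrapped] - a[wrapped] + period / 2) %% period) - period / 2
  P <- matrix(a, n_points, length(a), byrow = TRUE) + outer(X, delta)
  P[, wrapped] <- P[, wrapped] %% period
  structure(list(endpoints = list(from = from, to = to), points = P, X = X,
                 periodic = periodic, period = period),
            class = "liic_path")
}

#' Distortion cloud around an interpolated reaction path
#'
#' For path point `i` with ordinate `X_i`, the distortion directions are
#' the blend `(1 - X_i) * modes_init + X_i * modes_fin` of the endpoint
#' normal-mode matrices (optionally with the reaction-coordinate-like mode
#' excluded), and each cloud geometry is
#' `R_i + sum_j f_j * DeltaQ_i[, j]` with independent seeded uniform
#' factors `f_j` in `(-factor_scale, +factor_scale)`.
#'
#' @param path a [liic()] path.
#' @param modes_init,modes_fin mode matrices (DOFs by modes) of the two
#'   endpoints.
#' @param n_per_point cloud geometries per path point.
#' @param factor_scale half-width of the uniform random factors.
#' @param seed RNG seed.
#' @param exclude_mode optional column index removed from both mode
#'   matrices (e.g. the mode along the path).
#' @return a `reference_dataset` holding the path points (tag `"LIIC"`)
#'   followed by the cloud (tag `"rnd(LIIC)"`).
#' @export
liic_cloud <- function(path, modes_init, modes_fin, n_per_point = 4L,
                       factor_scale = 0.1, seed = 1L, exclude_mode = NULL) {
  stopifnot(inherits(path, "liic_path"), n_per_point >= 0, factor_scale >= 0)
  Mi <- as.matrix(modes_init); Mf <- as.matrix(modes_fin)
  if (!all(dim(Mi) == dim(Mf))) stop("mode matrices must share shape")
  if (!is.null(exclude_mode)) {
    if (exclude_mode < 1L || exclude_mode > ncol(Mi))
      stop("exclude_mode index invalid")
    Mi <- Mi[, -exclude_mode, drop = FALSE]
    Mf <- Mf[, -exclude_mode, drop = FALSE]
  }
  n_path <- nrow(path$points)
  nm <- ncol(Mi)
  cloud <- with_seed(seed, {
    out <- vector("list", n_path * n_per_point)
    k <- 0L
    for (i in seq_len(n_path)) {
      D <- (1 - path$X[i]) * Mi + path$X[i] * Mf
      for (r in seq_len(n_per_point)) {
        fj <- stats::runif(nm, -factor_scale, factor_scale)
        k <- k + 1L
        out[[k]] <- path$points[i, ] + drop(D %*% fj)
      }
    }
    out
  })
  ds_path <- reference_dataset(path$points, tag = "LIIC",
                               provenance = list(n_points = n_path))
  if (n_per_point == 0L) return(ds_path)
  ds_cloud <- reference_dataset(do.call(rbind, cloud), tag = "rnd(LIIC)",
                                provenance = list(n_per_point = n_per_point,
                                                  factor_scale = factor_scale,
                                                  seed = seed))
  combine_datasets(ds_path, ds_cloud)
}

#' Retain dataset entries at or below an energy cutoff
#'
#' @param ds a [reference_dataset()].
#' @param backend_or_values a backend to evaluate energies with, or a
#'   numeric vector of energies; `NULL` uses the stored reference
#'   energies.
#' @param cutoff inclusive relative-energy cutoff (cm^-1).
#' @return the filtered dataset; attribute `removed` counts dropped
#'   entries.
#' @export
filter_by_energy <- function(ds, backend_or_values = NULL, cutoff) {
  e <- if (is.null(backend_or_values)) {
    if (is.null(ds$energy)) stop("no energies stored and no backend given")
    ds$energy
  } else if (is.numeric(backend_or_values)) {
    stopifnot(length(backend_or_values) == dataset_size(ds))
    backend_or_values
  } else {
    surface_energies(backend_or_values, ds$geometry)
  }
  keep <- e <= cutoff
  if (!any(keep)) warning("energy filter removed every entry")
  out <- reference_dataset(ds$geometry[keep, , drop = FALSE],
                           energy = if (!is.null(ds$energy)) ds$energy[keep],
                           tag = ds$tag[keep], stage = ds$stage[keep],
                           provenance = c(ds$provenance, list(cutoff = cutoff)))
  attr(out, "removed") <- sum(!keep)
  out
}

#' Assemble a fitting stage from component datasets
#'
#' Concatenates the components, assigns the stage id, deduplicates by
#' geometry (two entries closer than one part in 1e10 coordinate-wise are
#' one point), and attaches a stage ledger giving the class composition.
#'
#' @param components list of [reference_dataset()]s.
#' @param stage_id character stage identifier.
#' @return a `reference_dataset` with attribute `ledger` (data frame:
#'   stage, class string, per-class counts, total).
#' @export
assemble_stage <- function(components, stage_id) {
  stopifnot(is.list(components), length(components) >= 1L)
  prior <- unlist(lapply(components, `[[`, "stage"))
  if (any(!is.na(prior) & prior == stage_id))
    stop(sprintf("clashing stage id '%s': a component already carries it", stage_id))
  ds <- do.call(combine_datasets, components)
  key <- apply(signif(ds$geometry, 10), 1, paste, collapse = "|")
  keep <- !duplicated(key)
  out <- reference_dataset(ds$geometry[keep, , drop = FALSE],
                           energy = if (!is.null(ds$energy)) ds$energy[keep],
                           tag = ds$tag[keep],
                           stage = stage_id,
                           provenance = ds$provenance)
  comp <- table(out$tag)
  attr(out, "ledger") <- data.frame(
    stage = stage_id,
    class = paste(names(comp)[order(match(names(comp),
      c("1D", "2D", "rnd(fD)", "LIIC", "rnd(LIIC)", "asymp", "core")))],
      collapse = " + "),
    n = dataset_size(out))
  attr(out, "composition") <- comp
  out
}

#' Write / read a reference dataset as CSV
#'
#' Columns `q1 ... qf`, `energy`, `tag`, `stage`.
#' @param ds a [reference_dataset()].
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$geometry)
  names(df) <- paste0("q", seq_len(ncol(ds$geometry)))
  df$energy <- if (is.null(ds$energy)) NA_real_ else ds$energy
  df$tag <- ds$tag
  df$stage <- ds$stage
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qcols <- grep("^q[0-9]+$", names(df))
  energy <- if (all(is.na(df$energy))) NULL else df$energy
  reference_dataset(as.matrix(df[, qcols, drop = FALSE]), energy = energy,
                    tag = df$tag, stage = df$stage)
}
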