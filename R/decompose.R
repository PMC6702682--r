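#' Potential density matrix of a grid tensor
#'
#' The Gram-type matrix obtained by summing products of potential values
#' over all degrees of freedom except `dof`:
#' `rho[k, k'] = sum_I V[I, k] V[I, k']`, where `I` runs over the composite
#' index of the remaining DOFs. With a second tensor `values2` the mixed
#' matrix is formed, with rows indexed by the grid of `values` (fine) and
#' columns by the grid of `values2` (coarse); the two tensors must share
#' the composite summation grid.
#'
#' @param values numeric array of potential values on a (full, coarse or
#'   partial) direct-product grid.
#' @param dof degree of freedom (mode) kept uncontracted.
#' @param values2 optional second array for the mixed fine-by-coarse case.
#' @return object of class `potential_density_matrix`: list with `dof`,
#'   `matrix` (symmetric PSD, or rectangular in the mixed case) and
#'   `mixed` flag.
#' @export
density_matrix <- function(values, dof, values2 = NULL) {
  if (is.null(dim(values))) values <- array(values, dim = length(values))
  d <- dim(values)
  dof <- as.integer(dof)
  if (dof < 1L || dof > length(d)) stop("dof out of range")
  A <- unfold_tensor(values, dof)
  if (is.null(values2)) {
    m <- tcrossprod(A)
    m <- (m + t(m)) / 2
    mixed <- FALSE
  } else {
    if (is.null(dim(values2))) values2 <- array(values2, dim = length(values2))
    d2 <- dim(values2)
    if (length(d2) != length(d) || any(d2[-dof] != d[-dof]))
      stop("values2 must match values on all DOFs except 'dof'")
    m <- tcrossprod(A, unfold_tensor(values2, dof))
    mixed <- TRUE
  }
  structure(list(dof = dof, matrix = m, mixed = mixed),
            class = "potential_density_matrix")
}

# mode-n unfolding: I_mode x prod(rest), rest in original mode order
unfold_tensor <- function(A, mode) {
  d <- dim(A)
  B <- aperm(A, c(mode, seq_along(d)[-mode]))
  dim(B) <- c(d[mode], prod(d[-mode]))
  B
}

# eigenvalue-thresholded pseudo-inverse of a symmetric PSD matrix
psd_pinv <- function(S, rcond = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  thr <- rcond * max(abs(e$values[1]), .Machine$double.xmin)
  keep <- e$values > thr
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Exact POTFIT Tucker decomposition of a full-grid tensor
#'
#' Per degree of freedom, the factor matrix holds the leading eigenvectors
#' ("natural potentials") of the potential density matrix; the core tensor
#' is the input contracted with the transposed factors. At full ranks the
#' reconstruction is exact to roundoff; at truncated ranks the squared L2
#' reconstruction error over the grid is bounded by the sum of discarded
#' density-matrix eigenvalues per DOF.
#'
#' @param values full-grid numeric array (intended for `<= ~1e6` points).
#' @param ranks per-DOF integer ranks `m_k <= N_k`; `NULL` keeps full rank.
#' @param grids optional list of [build_dvr()] grids for the result.
#' @return a [tucker_potential()] with `meta$builder = "potfit"` and
#'   `meta$discarded_weight` (per-DOF sum of discarded eigenvalues).
#' @export
potfit_exact <- function(values, ranks = NULL, grids = NULL) {
  if (is.null(dim(values))) values <- array(values, dim = length(values))
  d <- dim(values)
  f <- length(d)
  if (is.null(ranks)) ranks <- d
  ranks <- as.integer(ranks)
  if (length(ranks) != f || any(ranks < 1L)) stop("need one positive rank per DOF")
  if (any(ranks > d)) stop("rank exceeds grid size")
  factors <- vector("list", f)
  discarded <- numeric(f)
  for (k in seq_len(f)) {
    rho <- density_matrix(values, k)$matrix
    e <- eigen(rho, symmetric = TRUE)
    factors[[k]] <- e$vectors[, seq_len(ranks[k]), drop = FALSE]
    discarded[k] <- sum(pmax(e$values[-seq_len(ranks[k])], 0))
  }
  core <- values
  for (k in seq_len(f)) core <- mode_product(core, t(factors[[k]]), k)
  tucker_potential(core, factors, grids = grids,
                   meta = list(builder = "potfit", ranks = ranks,
                               discarded_weight = discarded))
}

# --- backend plumbing -------------------------------------------------------

#' Wrap a stored full-grid tensor as an energy backend
#'
#' @param values full-grid numeric array.
#' @param grids list of [build_dvr()] grids matching `dim(values)`.
#' @return an object usable as the `backend` argument of
#'   [mgpf_decompose()] and [rmse_on_grid()].
#' @export
tensor_backend <- function(values, grids) {
  if (is.null(dim(values))) values <- array(values, dim = length(values))
  stopifnot(identical(dim(values), as.integer(grid_sizes(grids))))
  structure(list(values = values, grids = grids), class = "tensor_backend")
}

# evaluate a backend at grid index `index` with coordinates `q`
eval_backend <- function(backend, q, index = NULL) {
  if (inherits(backend, "tensor_backend")) {
    if (is.null(index)) stop("tensor backend requires a grid index")
    return(backend$values[matrix(as.integer(index), nrow = 1)])
  }
  if (inherits(backend, "surface_backend"))
    return(surface_energy(backend, q))
  if (is.function(backend))
    return(backend(q))
  stop("unsupported backend type")
}

grid_coords <- function(grids, index)
  vapply(seq_along(index), function(k) grids[[k]]$points[index[k]], numeric(1))

# full-grid tensor from a backend (small grids only)
tensor_from_backend <- function(backend, grids) {
  if (inherits(backend, "tensor_backend")) return(backend$values)
  n <- grid_sizes(grids)
  idx <- as.matrix(expand.grid(lapply(n, seq_len)))
  vals <- apply(idx, 1, function(i) eval_backend(backend, grid_coords(grids, i), i))
  array(vals, dim = n)
}

#' Multigrid POTFIT decomposition from coarse and partial grids only
#'
#' Bottom-up multigrid decomposition: the backend is evaluated on the
#' coarse direct-product grid (giving the core tensor `V`) and on each
#' per-DOF partial grid (fine along that DOF, coarse along the others).
#' For each DOF, the coarse potential density matrix `rho` and the mixed
#' fine-by-coarse `rho'` are formed by contraction over the coarse grids of
#' the remaining DOFs, and the transformation matrix
#' `gamma = rho' %*% pinv(rho)` extends the coarse core tensor to the full
#' primitive grid as `V x_1 gamma^(1)T ... x_f gamma^(f)T`. The backend is
#' never evaluated on the full primitive grid; evaluations are cached by
#' grid index and performed in lexicographic order.
#'
#' @param backend an energy backend: a `function(q)` of the coordinate
#'   vector, a [tensor_backend()], or a surface object with a
#'   [surface_energy()] method.
#' @param multigrid a [make_multigrid()] structure.
#' @param rcond relative eigenvalue threshold for the pseudo-inverse of
#'   `rho` (fraction of the largest eigenvalue).
#' @param rmse_sample number of random primitive-grid points on which to
#'   report a sampled RMSE of the decomposition (0 to skip).
#' @param rmse_seed RNG seed for the RMSE sample.
#' @return object of class `mgpf_result`: list with `potential` (a
#'   [tucker_potential()]), `gammas`, `n_calls`, `rho_condition` (per-DOF
#'   retained-eigenvalue condition numbers) and `rmse_report`.
#' @export
mgpf_decompose <- function(backend, multigrid, rcond = 1e-12,
                           rmse_sample = 200L, rmse_seed = 1L) {
  stopifnot(inherits(multigrid, "multigrid"))
  grids <- multigrid$primitive
  n <- grid_sizes(grids)
  f <- length(n)
  coarse <- multigrid$coarse_index_sets
  m <- vapply(coarse, length, integer(1))

  cache <- new.env(parent = emptyenv())
  n_calls <- 0L
  eval_cached <- function(index) {
    key <- paste(index, collapse = ",")
    if (!is.null(v <- cache[[key]])) return(v)
    v <- eval_backend(backend, grid_coords(grids, index), index)
    if (!is.finite(v))
      stop(sprintf("backend failed (non-finite energy) at grid index (%s)", key))
    n_calls <<- n_calls + 1L
    cache[[key]] <- v
    v
  }
  eval_tensor <- function(index_sets) {
    idx <- as.matrix(expand.grid(index_sets))  # first index fastest = column-major
    vals <- apply(idx, 1, eval_cached)
    array(vals, dim = vapply(index_sets, length, integer(1)))
  }

  v_coarse <- eval_tensor(coarse)
  gammas <- vector("list", f)
  rho_condition <- numeric(f)
  for (k in seq_len(f)) {
    partial_sets <- coarse
    partial_sets[[k]] <- seq_len(n[k])
    v_partial <- eval_tensor(partial_sets)
    rho <- density_matrix(v_coarse, k)$matrix
    rho_mixed <- density_matrix(v_partial, k, v_coarse)$matrix
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    kept <- ev[ev > rcond * max(ev[1], .Machine$double.xmin)]
    rho_condition[k] <- if (length(kept)) kept[1] / kept[length(kept)] else Inf
    gammas[[k]] <- rho_mixed %*% psd_pinv(rho, rcond)
  }

  pot <- tucker_potential(v_coarse, gammas, grids = grids,
                          meta = list(builder = "mgpf", stride = multigrid$stride,
                                      policy = multigrid$policy, ranks = m,
                                      n_calls = n_calls))
  rmse_report <- if (rmse_sample > 0L)
    rmse_on_grid(pot, backend, points = list(n = rmse_sample, seed = rmse_seed))
  else NULL
  structure(list(potential = pot, gammas = gammas, n_calls = n_calls,
                 rho_condition = rho_condition, rmse_report = rmse_report),
            class = "mgpf_result")
}

#' @export
print.mgpf_result <- function(x, ...) {
  cat(sprintf("MGPF decomposition: %d backend calls, ranks %s\n", x$n_calls,
              paste(dim(x$potential$core), collapse = "x")))
  if (!is.null(x$rmse_report))
    cat(sprintf("  sampled RMSE %.3g (n = %d)\n",
                x$rmse_report$rmse, x$rmse_report$n))
  invisible(x)
}

#' Root-mean-square error of a Tucker potential against its backend
#'
#' @param pot a [tucker_potential()] carrying its grids.
#' @param backend the reference backend (see [mgpf_decompose()]).
#' @param points `"full"` for every primitive point (small grids only), an
#'   integer matrix of grid indices (one row per point), or
#'   `list(n =, seed =)` for a seeded uniform sample of indices.
#' @return list with `rmse`, `max_abs_error`, `min_energy` (minimum backend
#'   energy seen, to flag values below a declared global minimum), `n`.
#' @export
rmse_on_grid <- function(pot, backend, points = "full") {
  stopifnot(inherits(pot, "tucker_potential"), !is.null(pot$grids))
  n <- grid_sizes(pot$grids)
  if (is.character(points) && identical(points, "full")) {
    if (prod(as.numeric(n)) > 2e6) stop("full grid too large; use a sample")
    ref <- tensor_from_backend(backend, pot$grids)
    fit <- sop_full_tensor(pot)
    err <- as.vector(fit) - as.vector(ref)
    return(list(rmse = sqrt(mean(err^2)), max_abs_error = max(abs(err)),
                min_energy = min(ref), n = length(err), points = "full"))
  }
  if (is.list(points) && !is.null(points$n)) {
    if (points$n < 1L) stop("empty point set")
    idx <- with_seed(points$seed, {
      vapply(n, function(nk) sample.int(nk, points$n, replace = TRUE),
             integer(points$n))
    })
    if (points$n == 1L) idx <- matrix(idx, nrow = 1)
  } else {
    idx <- as.matrix(points)
    if (nrow(idx) == 0L) stop("empty point set")
  }
  ref <- apply(idx, 1, function(i) eval_backend(backend, grid_coords(pot$grids, i), i))
  fit <- apply(idx, 1, function(i) sop_evaluate(pot, i))
  err <- fit - ref
  list(rmse = sqrt(mean(err^2)), max_abs_error = max(abs(err)),
       min_energy = min(ref), n = nrow(idx), points = "sampled")
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
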