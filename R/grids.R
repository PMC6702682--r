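#' Discrete variable representation (DVR) primitive grids
#'
#' Constructs a one-dimensional DVR grid with its points and the analytic
#' kinetic-energy matrix (the matrix representation of `-d^2/dq^2`, mass
#' free; divide by `2 m` to obtain the kinetic operator of a particle of
#' mass `m`).
#'
#' Two DVR families are supported:
#' \describe{
#'   \item{harmonic}{Hermite (harmonic-oscillator) DVR. The grid points are
#'     scaled Gauss-Hermite nodes, obtained by diagonalizing the position
#'     operator in the first `n_points` oscillator eigenfunctions. The
#'     scaling is chosen so that the outermost nodes coincide with
#'     `range[1]` and `range[2]`; with `range = NULL` the natural
#'     (unit-frequency, unit-mass) nodes are used unscaled.}
#'   \item{cosine}{Cosine DVR on `[range[1], range[2]]` (even particle-in-a-
#'     box basis, zero-derivative ends), appropriate for angles such as a
#'     torsion over `[0, pi]`. Points are the `n_points` equidistant
#'     midpoints of the interval.}
#' }
#'
#' @param kind `"harmonic"` or `"cosine"`.
#' @param n_points number of grid points (`>= 1`).
#' @param range ordered numeric pair `(first, last)`; for the harmonic DVR
#'   `NULL` selects the natural Gauss-Hermite nodes.
#' @return An object of class `dvr_grid`: a list with elements `kind`,
#'   `n_points`, `range`, `points` (strictly increasing) and `kinetic`
#'   (symmetric `n_points x n_points` matrix of `-d^2/dq^2`).
#' @export
#' @examples
#' g <- build_dvr("harmonic", 18, c(1.30, 2.45))   # an OH-stretch-like grid
#' range(g$points)                                  # 1.30 2.45
#' a <- build_dvr("cosine", 32, c(0, pi))           # a torsion grid
build_dvr <- function(kind = c("harmonic", "cosine"), n_points, range = NULL) {
  kind <- match.arg(kind)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop("n_points must be a positive integer")
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2])
      stop("range must be an ordered finite pair (first < last)")
  }

  if (kind == "harmonic") {
    hd <- hermite_dvr_natural(n_points)
    if (is.null(range)) {
      pts <- hd$points
      kin <- hd$kinetic
      range <- c(pts[1], pts[n_points])
      if (n_points == 1L) range <- c(pts - 0.5, pts + 0.5)
    } else if (n_points == 1L) {
      pts <- mean(range)
      kin <- hd$kinetic
    } else {
      span <- hd$points[n_points] - hd$points[1]
      s <- diff(range) / span
      pts <- mean(range) + s * hd$points  # natural nodes are symmetric about 0
      kin <- hd$kinetic / s^2
    }
  } else {
    if (is.null(range)) stop("cosine DVR requires an explicit range")
    L <- diff(range)
    i <- seq_len(n_points)
    pts <- range[1] + (i - 0.5) * L / n_points
    j <- 0:(n_points - 1L)
    # U[j+1, i]: orthonormal cosine basis sampled at the midpoints (DCT-II)
    U <- sqrt(2 / n_points) * cos(outer(j, i - 0.5) * pi / n_points)
    U[1, ] <- 1 / sqrt(n_points)
    tj <- (j * pi / L)^2
    kin <- crossprod(U, tj * U)
    kin <- (kin + t(kin)) / 2
  }

  structure(list(kind = kind, n_points = n_points, range = range,
                 points = as.numeric(pts), kinetic = kin),
            class = "dvr_grid")
}

# Natural (unit-mass, unit-frequency) Hermite DVR: diagonalize the position
# operator in the lowest-n oscillator basis; kinetic from P^2 = diag(2n+1) - X^2.
hermite_dvr_natural <- function(n) {
  if (n == 1L)
    return(list(points = 0, kinetic = matrix(1, 1, 1)))
  X <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) X[i, i + 1L] <- X[i + 1L, i] <- sqrt(i / 2)
  e <- eigen(X, symmetric = TRUE)
  ord <- order(e$values)
  pts <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  P2 <- diag(2 * (0:(n - 1L)) + 1) - X %*% X
  kin <- crossprod(U, P2 %*% U)
  kin <- (kin + t(kin)) / 2
  list(points = pts, kinetic = kin)
}

#' @export
print.dvr_grid <- function(x, ...) {
  cat(sprintf("DVR grid: %s, %d points on [%g, %g]\n",
              x$kind, x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' Total size of a direct-product primitive grid
#'
#' @param grids a list of [build_dvr()] grids (or a bare integer vector of
#'   per-DOF point counts).
#' @return the product of the per-DOF grid sizes, as a double (direct
#'   product grids overflow 32-bit integers quickly).
#' @export
#' @examples
#' primitive_grid_size(c(18, 13, 13, 16, 18, 32))  # 28035072
primitive_grid_size <- function(grids) {
  n <- grid_sizes(grids)
  if (length(n) == 0L) stop("empty grid list")
  prod(as.numeric(n))
}

grid_sizes <- function(grids) {
  if (is.numeric(grids)) return(as.integer(grids))
  if (inherits(grids, "dvr_grid")) grids <- list(grids)
  vapply(grids, function(g) g$n_points, integer(1))
}

#' Coarse and partial subgrids for multigrid tensor decomposition
#'
#' Builds the multigrid structure used by [mgpf_decompose()]: per degree of
#' freedom, a coarse index set containing every `stride`-th primitive point,
#' and a partial grid that is full (fine) along that degree of freedom and
#' coarse along all others.
#'
#' @param grids list of [build_dvr()] grids, one per degree of freedom.
#' @param stride positive integer subsampling step; `1` makes the coarse
#'   grid identical to the primitive one.
#' @param policy coarse-point selection rule. `"from_first"` keeps indices
#'   `1, 1+stride, 1+2*stride, ...`; `"from_first_plus_endpoint"` adds the
#'   last primitive index when the progression misses it.
#' @return An object of class `multigrid`: list with `primitive` (the input
#'   grids), `stride`, `policy`, `coarse_index_sets` (list of integer
#'   vectors, 1-based), `coarse_size`, and `partial_sizes` (per-DOF partial
#'   grid sizes `N_k * prod(coarse sizes of the others)`).
#' @export
#' @examples
#' gs <- lapply(c(12, 12, 12), function(n) build_dvr("harmonic", n, c(-1, 1)))
#' mg <- make_multigrid(gs, stride = 3)
#' mg$coarse_size  # 64
make_multigrid <- function(grids, stride = 1L,
                           policy = c("from_first", "from_first_plus_endpoint")) {
  policy <- match.arg(policy)
  if (inherits(grids, "dvr_grid")) grids <- list(grids)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  n <- grid_sizes(grids)
  if (stride >= min(n))
    warning(sprintf("stride %d leaves a single coarse point along the smallest DOF (N = %d)",
                    stride, min(n)))
  coarse <- lapply(n, function(nk) {
    idx <- seq.int(1L, nk, by = stride)
    if (policy == "from_first_plus_endpoint" && idx[length(idx)] != nk)
      idx <- c(idx, nk)
    idx
  })
  m <- vapply(coarse, length, integer(1))
  partial <- vapply(seq_along(n), function(k) {
    as.numeric(n[k]) * prod(as.numeric(m[-k]))
  }, numeric(1))
  structure(list(primitive = grids, stride = stride, policy = policy,
                 coarse_index_sets = coarse,
                 coarse_size = prod(as.numeric(m)),
                 partial_sizes = partial),
            class = "multigrid")
}

#' @export
print.multigrid <- function(x, ...) {
  m <- vapply(x$coarse_index_sets, length, integer(1))
  cat(sprintf("multigrid: %d DOFs, stride %d (%s)\n", length(m), x$stride, x$policy))
  cat("  primitive sizes:", paste(grid_sizes(x$primitive), collapse = " x "), "\n")
  cat("  coarse sizes:   ", paste(m, collapse = " x "),
      sprintf(" (%s points)", format(x$coarse_size, big.mark = ",")), "\n")
  invisible(x)
}
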