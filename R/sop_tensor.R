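#' Tucker-format (sum-of-products) potential container
#'
#' A potential on a direct-product grid stored in Tucker form: an
#' f-dimensional core tensor `C` of shape `m_1 x ... x m_f` contracted with
#' per-DOF factor matrices `v^(k)` of shape `N_k x m_k` whose columns are
#' single-particle potentials,
#' `V(i_1,...,i_f) = sum_j C[j_1,...,j_f] prod_k v^(k)[i_k, j_k]`.
#' Storage is `prod(m) + sum(N_k * m_k)` numbers, orders of magnitude below
#' the `prod(N_k)` of the raw tensor for typical molecular grids.
#'
#' @param core numeric array (a plain vector is treated as 1D).
#' @param factors list of numeric matrices, `factors[[k]]` of shape
#'   `N_k x m_k` with `m_k = dim(core)[k]`.
#' @param grids optional list of [build_dvr()] grids (`N_k` must match).
#' @param meta named list of provenance fields; `energy_units` defaults to
#'   `"cm-1"` and `reference` records what the energy zero refers to.
#' @return object of class `tucker_potential`.
#' @export
tucker_potential <- function(core, factors, grids = NULL, meta = list()) {
  if (is.null(dim(core))) core <- array(core, dim = length(core))
  dc <- dim(core)
  if (length(factors) != length(dc))
    stop("need one factor matrix per core mode")
  for (k in seq_along(factors)) {
    f <- as.matrix(factors[[k]])
    if (ncol(f) != dc[k])
      stop(sprintf("factor %d has %d columns; core extent is %d", k, ncol(f), dc[k]))
    if (ncol(f) > nrow(f))
      stop(sprintf("factor %d rank %d exceeds grid size %d", k, ncol(f), nrow(f)))
    factors[[k]] <- f
  }
  if (!is.null(grids)) {
    ng <- grid_sizes(grids)
    nf <- vapply(factors, nrow, integer(1))
    if (!identical(ng, nf))
      stop("grid sizes do not match factor row counts")
  }
  if (is.null(meta$energy_units)) meta$energy_units <- "cm-1"
  structure(list(core = core, factors = factors, grids = grids, meta = meta),
            class = "tucker_potential")
}

#' @export
print.tucker_potential <- function(x, ...) {
  n <- vapply(x$factors, nrow, integer(1))
  m <- dim(x$core)
  cat(sprintf("Tucker potential: %d DOFs, grid %s, ranks %s\n",
              length(n), paste(n, collapse = "x"), paste(m, collapse = "x")))
  cat(sprintf("  storage %s numbers vs %s full-grid points\n",
              format(prod(m) + sum(n * m), big.mark = ","),
              format(prod(as.numeric(n)), big.mark = ",")))
  if (!is.null(x$meta$builder)) cat("  builder:", x$meta$builder, "\n")
  invisible(x)
}

#' n-mode product of a tensor with a matrix
#'
#' Contracts `tensor` along `mode` with `matrix`: the result has the same
#' shape except that extent `I_mode` is replaced by `nrow(matrix)`, with
#' `R[..., j, ...] = sum_i matrix[j, i] * A[..., i, ...]`. Applying an
#' identity matrix is a no-op.
#'
#' @param tensor numeric array.
#' @param matrix numeric matrix with `ncol(matrix)` equal to the tensor
#'   extent along `mode`.
#' @param mode integer mode index (1-based).
#' @return numeric array.
#' @export
mode_product <- function(tensor, matrix, mode) {
  if (is.null(dim(tensor))) tensor <- array(tensor, dim = length(tensor))
  d <- dim(tensor)
  mode <- as.integer(mode)
  if (mode < 1L || mode > length(d)) stop("mode out of range")
  M <- as.matrix(matrix)
  if (ncol(M) != d[mode])
    stop(sprintf("matrix has %d columns; tensor extent along mode %d is %d",
                 ncol(M), mode, d[mode]))
  perm <- c(mode, seq_along(d)[-mode])
  A <- aperm(tensor, perm)
  dim(A) <- c(d[mode], prod(d[-mode]))
  R <- M %*% A
  dim(R) <- c(nrow(M), d[-mode])
  aperm(R, order(perm))
}

#' Evaluate a Tucker potential at a primitive-grid index
#'
#' @param pot a [tucker_potential()].
#' @param index integer vector of 1-based grid indices, one per DOF.
#' @return the potential value at that grid point.
#' @export
sop_evaluate <- function(pot, index) {
  stopifnot(inherits(pot, "tucker_potential"))
  f <- length(pot$factors)
  index <- as.integer(index)
  if (length(index) != f) stop("index length must equal the number of DOFs")
  n <- vapply(pot$factors, nrow, integer(1))
  if (any(index < 1L | index > n)) stop("index out of primitive-grid bounds")
  v <- as.vector(pot$core)
  d <- dim(pot$core)
  # contract modes right-to-left so the leading stride stays contiguous
  for (k in f:1) {
    row <- pot$factors[[k]][index[k], ]
    dim(v) <- c(prod(d[seq_len(k - 1L)]), d[k])
    v <- drop(v %*% row)
  }
  as.numeric(v)
}

#' Reconstruct the full tensor represented by a Tucker potential
#'
#' Intended for small grids (validation); memory is `prod(N_k)` doubles.
#' @param pot a [tucker_potential()].
#' @return numeric array of shape `N_1 x ... x N_f`.
#' @export
sop_full_tensor <- function(pot) {
  stopifnot(inherits(pot, "tucker_potential"))
  out <- pot$core
  for (k in seq_along(pot$factors))
    out <- mode_product(out, pot$factors[[k]], k)
  out
}

# ---------------------------------------------------------------------------
# SOP file format (text and binary dialects)
#
# Text dialect ("SOPES-SOP 1 text"):
#   line 1   : SOPES-SOP 1 <dialect>
#   line 2   : ndof <f>
#   line 3   : core <m_1> ... <m_f>
#   per DOF  : grid <k> <kind|none> <N_k> <first> <last>
#   meta     : meta <key> <value>          (one per entry, character/numeric)
#   checksum : checksum <n_payload> <hash>
#   payload  : core values (column-major), then each factor matrix
#              (column-major), one value per line, %.17g so the text
#              round-trip is bit exact.
# Binary dialect: same header as text (ASCII), payload appended as
# little-endian 8-byte IEEE doubles after the "endheader" line.
# Indices and ranges are 1-based and closed throughout.
# ---------------------------------------------------------------------------

sop_payload <- function(pot) {
  c(as.vector(pot$core), unlist(lapply(pot$factors, as.vector), use.names = FALSE))
}

# order-sensitive 32-bit rolling checksum over the formatted payload
sop_checksum <- function(values) {
  s <- sprintf("%.17g", values)
  h <- 0
  for (chunk in split(s, ceiling(seq_along(s) / 4096))) {
    ints <- vapply(chunk, function(x) sum(utf8ToInt(x) * seq_len(nchar(x))), numeric(1))
    for (v in ints) h <- (h * 31 + v) %% 2147483647
  }
  formatC(h, format = "d")
}

#' Write / read a Tucker potential in the package's SOP file format
#'
#' The text dialect round-trips bit exactly; the binary dialect stores the
#' payload as little-endian 8-byte reals (1e-15 relative round trip). The
#' header carries grid definitions, ranks, units and a checksum; a
#' truncated or edited file fails the checksum on read.
#'
#' @param pot a [tucker_potential()].
#' @param path file path.
#' @param dialect `"text"` or `"binary"`.
#' @return `write_sop` returns `path` invisibly; `read_sop` returns the
#'   reconstructed `tucker_potential`.
#' @export
write_sop <- function(pot, path, dialect = c("text", "binary")) {
  stopifnot(inherits(pot, "tucker_potential"))
  dialect <- match.arg(dialect)
  f <- length(pot$factors)
  hdr <- c(sprintf("SOPES-SOP 1 %s", dialect),
           sprintf("ndof %d", f),
           paste("core", paste(dim(pot$core), collapse = " ")))
  for (k in seq_len(f)) {
    g <- if (!is.null(pot$grids)) pot$grids[[k]] else NULL
    hdr <- c(hdr, if (is.null(g))
      sprintf("grid %d none %d NA NA", k, nrow(pot$factors[[k]]))
      else sprintf("grid %d %s %d %.17g %.17g", k, g$kind, g$n_points,
                   g$range[1], g$range[2]))
  }
  for (key in names(pot$meta)) {
    val <- pot$meta[[key]]
    if (is.character(val) || is.numeric(val))
      hdr <- c(hdr, paste("meta", key, paste(format(val, digits = 17), collapse = ",")))
  }
  payload <- sop_payload(pot)
  hdr <- c(hdr, sprintf("checksum %d %s", length(payload), sop_checksum(payload)),
           "endheader")
  if (dialect == "text") {
    writeLines(c(hdr, sprintf("%.17g", payload)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(payload, con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_sop
#' @export
read_sop <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of file in SOP header")
    if (line == "endheader") break
    hdr <- c(hdr, line)
  }
  magic <- strsplit(hdr[1], " ")[[1]]
  if (length(magic) != 3L || magic[1] != "SOPES-SOP")
    stop("not a SOPES-SOP file")
  dialect <- magic[3]
  f <- as.integer(strsplit(hdr[2], " ")[[1]][2])
  dims <- as.integer(strsplit(hdr[3], " ")[[1]][-1])
  if (length(dims) != f) stop("header core-shape/ndof disagreement")

  grids <- vector("list", f); have_grid <- FALSE
  nk <- integer(f)
  meta <- list()
  n_payload <- NA_integer_; checksum <- NA_character_
  for (line in hdr[-(1:3)]) {
    tok <- strsplit(line, " ")[[1]]
    if (tok[1] == "grid") {
      k <- as.integer(tok[2]); nk[k] <- as.integer(tok[4])
      if (tok[3] != "none") {
        grids[[k]] <- build_dvr(tok[3], nk[k], as.numeric(tok[5:6]))
        have_grid <- TRUE
      }
    } else if (tok[1] == "meta") {
      val <- paste(tok[-(1:2)], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      meta[[tok[2]]] <- if (!is.na(num)) num else val
    } else if (tok[1] == "checksum") {
      n_payload <- as.integer(tok[2]); checksum <- tok[3]
    }
  }
  expected <- prod(dims) + sum(nk * dims)
  if (is.na(n_payload) || n_payload != expected)
    stop("header/payload shape disagreement")

  payload <- if (dialect == "text") {
    as.numeric(readLines(con))
  } else {
    readBin(con, "double", n = n_payload + 1L, size = 8, endian = "little")
  }
  if (length(payload) != n_payload)
    stop(sprintf("SOP payload truncated or padded: %d values, expected %d",
                 length(payload), n_payload))
  if (dialect == "text" && !identical(sop_checksum(payload), checksum))
    stop("SOP checksum mismatch: file corrupted")

  core <- array(payload[seq_len(prod(dims))], dim = dims)
  off <- prod(dims)
  factors <- vector("list", f)
  for (k in seq_len(f)) {
    nv <- nk[k] * dims[k]
    factors[[k]] <- matrix(payload[off + seq_len(nv)], nrow = nk[k])
    off <- off + nv
  }
  tucker_potential(core, factors, grids = if (have_grid) grids else NULL,
                   meta = meta)
}
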