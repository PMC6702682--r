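#' Exponential step weighting function
#'
#' Weight 1 for arguments up to `alpha`, decaying (or growing) as
#' `exp(beta * (x - alpha))` beyond it; continuous at `x = alpha`. With
#' `beta < 0` this down-weights high-energy points or large frequency
#' deviations.
#'
#' @param x argument (reference energy, or frequency deviation).
#' @param alpha threshold below which the weight is 1.
#' @param beta exponential rate beyond the threshold.
#' @return numeric weight(s), positive.
#' @export
step_weight <- function(x, alpha, beta) {
  ifelse(x <= alpha, 1, exp(beta * (x - alpha)))
}

#' Objective specification for backend reparametrization
#'
#' Bundles everything the fit objective needs: the surface template whose
#' parameters are varied, the reference dataset (energies), optional
#' harmonic-frequency terms, and the weighting parameters of
#' [step_weight()].
#'
#' Energies on both sides are taken relative to `ref_geometry` (default:
#' the dataset entry with the lowest reference energy), so the objective
#' compares relative energies as a reparametrization should. When the
#' dataset does not contain the geometry its reference energies are
#' measured from (displacement grids exclude their pivot, for instance),
#' pass that geometry explicitly: a mismatched energy zero biases the fit
#' by a constant and shifts the recovered parameters.
#'
#' @param surface the template `surface_backend` (a [toy_torsion_surface()]
#'   for the built-in family).
#' @param dataset a [reference_dataset()] with reference energies.
#' @param freq_terms list of `list(sp =, ref =)` pairs: a reference
#'   [stationary_point()] (its geometry is the refinement start) and the
#'   reference frequency vector; frequencies are recomputed at each trial
#'   parameter set and compared mode-by-mode after ascending sort.
#' @param alpha_E,beta_E energy weight parameters; `alpha_E = NULL` uses
#'   the maximum reference energy (no down-weighting inside the set). A
#'   barrier-height estimate is the intended setting.
#' @param alpha_F,beta_F frequency-deviation weight parameters (cm^-1).
#' @param ref_geometry energy-reference geometry.
#' @param penalty objective value returned when an evaluation fails
#'   (keeps derivative-free searches alive).
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(surface, dataset, freq_terms = list(),
                           alpha_E = NULL, beta_E = -1e-3,
                           alpha_F = 100, beta_F = -1e-2,
                           ref_geometry = NULL, penalty = 1e6) {
  stopifnot(inherits(dataset, "reference_dataset"), dataset_size(dataset) > 0)
  if (is.null(dataset$energy)) stop("dataset must carry reference energies")
  if (is.null(alpha_E)) alpha_E <- max(dataset$energy)
  if (is.null(ref_geometry))
    ref_geometry <- dataset$geometry[which.min(dataset$energy), ]
  structure(list(surface = surface, dataset = dataset,
                 freq_terms = freq_terms,
                 alpha_E = alpha_E, beta_E = beta_E,
                 alpha_F = alpha_F, beta_F = beta_F,
                 ref_geometry = ref_geometry, penalty = penalty),
            class = "objective_spec")
}

# energy and frequency residuals at parameter vector zeta; NULL on failure
spec_residuals <- function(zeta, spec, with_freq = TRUE) {
  s <- tryCatch(set_surface_params(spec$surface, zeta), error = function(e) NULL)
  if (is.null(s)) return(NULL)
  e <- surface_energies(s, spec$dataset$geometry) -
    surface_energy(s, spec$ref_geometry)
  if (any(!is.finite(e))) return(NULL)
  res_e <- e - spec$dataset$energy
  res_f <- ref_f <- numeric()
  if (with_freq && length(spec$freq_terms)) {
    for (term in spec$freq_terms) {
      fr <- tryCatch({
        sp <- suppressWarnings(
          refine_stationary(s, term$sp$geometry, kind = term$sp$kind,
                            max_iter = 30L))
        sort(sp$frequencies)
      }, error = function(e) NULL)
      if (is.null(fr) || length(fr) != length(term$ref)) return(NULL)
      res_f <- c(res_f, fr - sort(term$ref))
      ref_f <- c(ref_f, sort(term$ref))
    }
  }
  list(energy = res_e, freq = res_f,
       w_e = step_weight(spec$dataset$energy, spec$alpha_E, spec$beta_E),
       w_f = if (length(res_f)) step_weight(abs(res_f), spec$alpha_F, spec$beta_F)
             else numeric())
}

#' Two-term weighted mean-square objective
#'
#' The weighted mean of squared energy residuals plus the weighted mean of
#' squared frequency residuals (no square root; RMSE reporting is separate,
#' see [fit_rmse()]). Frequencies are recomputed at `zeta` by refining the
#' stationary points of the trial surface. A failed evaluation returns the
#' penalty value with attribute `failed`.
#'
#' @param zeta numeric parameter vector (the template's parameter order).
#' @param spec an [objective_spec()].
#' @return non-negative objective value; zero iff every weighted residual
#'   vanishes.
#' @export
chi0 <- function(zeta, spec) {
  r <- spec_residuals(zeta, spec)
  if (is.null(r)) return(structure(spec$penalty, failed = TRUE))
  val <- sum(r$w_e * r$energy^2) / length(r$energy)
  if (length(r$freq))
    val <- val + sum(r$w_f * r$freq^2) / length(r$freq)
  val
}

#' Single-term concatenated objective
#'
#' The simpler variant: energy and frequency residuals are concatenated
#' into one vector and a single weighted mean square over `n + m` entries
#' is returned. Equal to [chi0()] only in special balanced cases.
#'
#' @inheritParams chi0
#' @return non-negative objective value.
#' @export
chi1 <- function(zeta, spec) {
  r <- spec_residuals(zeta, spec)
  if (is.null(r)) return(structure(spec$penalty, failed = TRUE))
  sum(c(r$w_e, r$w_f) * c(r$energy, r$freq)^2) /
    (length(r$energy) + length(r$freq))
}

#' Unweighted energy RMSE of a parameter set on a dataset
#'
#' The reported fit quality: the square root of the plain mean squared
#' relative-energy residual, distinct from the weighted objective.
#'
#' @param zeta parameter vector.
#' @param spec an [objective_spec()] (frequencies ignored).
#' @return RMSE in cm^-1.
#' @export
fit_rmse <- function(zeta, spec) {
  r <- spec_residuals(zeta, spec, with_freq = FALSE)
  if (is.null(r)) return(NA_real_)
  sqrt(mean(r$energy^2))
}

# split a bounds specification into lower/upper vectors
split_bounds <- function(bounds, d) {
  if (inherits(bounds, "param_vector")) return(list(lo = bounds$lower, up = bounds$upper))
  if (is.matrix(bounds)) return(list(lo = bounds[1, ], up = bounds[2, ]))
  if (is.list(bounds)) return(list(lo = rep_len(bounds$lower, d),
                                   up = rep_len(bounds$upper, d)))
  stop("unsupported bounds specification")
}

#' Bound-constrained derivative-free local optimization (BOBYQA)
#'
#' Quadratic-model trust-region descent within the box; parameters with
#' degenerate bounds (lower equal to upper) are held fixed. The returned
#' objective is never worse than at the start.
#'
#' @param objective `function(zeta)` returning a scalar.
#' @param bounds a [param_vector()], 2-row matrix, or
#'   `list(lower =, upper =)`.
#' @param start starting parameter vector (within bounds).
#' @param max_evals objective-evaluation budget.
#' @return list with `par`, `value`, `evals`.
#' @export
local_optimize <- function(objective, bounds, start, max_evals = 2000L) {
  start <- as.numeric(start)
  b <- split_bounds(bounds, length(start))
  if (any(start < b$lo - 1e-12) || any(start > b$up + 1e-12))
    stop("start outside bounds")
  free <- which(b$up > b$lo)
  f0 <- objective(start)
  if (length(free) == 0L) return(list(par = start, value = f0, evals = 1L))
  evals <- 0L
  # optimize in box-normalized coordinates: parameter magnitudes differ by
  # orders of magnitude, and BOBYQA uses a single trust-region radius
  lo <- b$lo[free]; w <- b$up[free] - lo
  wrapped <- function(zf) {
    z <- start; z[free] <- lo + zf * w
    evals <<- evals + 1L
    as.numeric(objective(z))
  }
  fit <- tryCatch(
    nloptr::bobyqa((start[free] - lo) / w, wrapped,
                   lower = rep(0, length(free)), upper = rep(1, length(free)),
                   control = list(maxeval = as.integer(max_evals),
                                  xtol_rel = 1e-12)),
    error = function(e) NULL)
  par <- start; value <- f0
  if (!is.null(fit) && is.finite(fit$value) && fit$value <= f0) {
    par[free] <- lo + fit$par * w
    value <- fit$value
  }
  list(par = par, value = value, evals = evals)
}

#' Multistart global optimization with single-linkage clustering
#'
#' A documented multi-level single-linkage scheme: seeded uniform starts in
#' the box are ranked by objective value; walking through them in order, a
#' start within the critical linkage distance of an already-clustered
#' better point joins that cluster (its basin is assumed explored), while
#' cluster-distinct starts seed local BOBYQA descents. The critical
#' distance shrinks as starts accumulate, so for a large enough budget
#' every basin gets one local search.
#'
#' @param objective `function(zeta)` scalar objective.
#' @param bounds box bounds (see [local_optimize()]).
#' @param n_starts number of seeded uniform starts (`<= max_evals`).
#' @param max_evals total objective-evaluation budget across the start
#'   ranking and all local descents.
#' @param seed RNG seed for the starts.
#' @return list with `par`, `value`, `evals`, and `clusters` (data frame:
#'   one row per local descent with its start value, final value, evals).
#' @export
global_optimize <- function(objective, bounds, n_starts = 20L,
                            max_evals = 4000L, seed = 1L) {
  stopifnot(max_evals >= n_starts)
  d <- if (inherits(bounds, "param_vector")) length(bounds$values)
       else if (is.matrix(bounds)) ncol(bounds) else length(bounds$lower)
  b <- split_bounds(bounds, d)
  free <- b$up > b$lo
  width <- ifelse(free, b$up - b$lo, 0)
  starts <- with_seed(seed, {
    matrix(stats::runif(n_starts * d, rep(b$lo, each = n_starts),
                        rep(pmax(b$up, b$lo), each = n_starts)),
           nrow = n_starts)
  })
  vals <- apply(starts, 1, function(z) as.numeric(objective(z)))
  if (all(!is.finite(vals))) stop("all starts failed to evaluate")
  ord <- order(vals)
  budget <- max_evals - n_starts
  diam <- sqrt(sum(width^2))

  clustered <- matrix(numeric(0), ncol = d)
  descents <- list()
  best <- list(par = starts[ord[1], ], value = vals[ord[1]])
  for (rank in seq_along(ord)) {
    i <- ord[rank]
    if (!is.finite(vals[i])) next
    r_crit <- diam * (log(rank + 1) / (rank + 1))^(1 / max(sum(free), 1))
    if (nrow(clustered) > 0) {
      dist_min <- min(sqrt(rowSums(sweep(clustered, 2, starts[i, ])^2)))
      if (dist_min < r_crit) {
        clustered <- rbind(clustered, starts[i, ])
        next
      }
    }
    if (budget <= 0) break
    this_budget <- max(50L, as.integer(budget / max(1, 4 - length(descents))))
    this_budget <- min(this_budget, budget)
    loc <- local_optimize(objective, bounds, starts[i, ], max_evals = this_budget)
    budget <- budget - loc$evals
    clustered <- rbind(clustered, starts[i, ], loc$par)
    descents[[length(descents) + 1L]] <-
      data.frame(cluster = length(descents) + 1L, start_value = vals[i],
                 value = loc$value, evals = loc$evals)
    if (loc$value < best$value) best <- loc[c("par", "value")]
  }
  list(par = best$par, value = best$value,
       evals = n_starts + sum(vapply(descents, `[[`, numeric(1), "evals")),
       clusters = if (length(descents)) do.call(rbind, descents)
                  else data.frame())
}

#' Staged refit protocol: one global stage, then warm-started local stages
#'
#' Stage 1 runs the global multistart search followed by a local polish on
#' the first (smallest) dataset; every later stage runs a local
#' optimization only, warm-started from the previous stage's best
#' parameters. Per stage the ledger records the point count, optimizer,
#' evaluation count, objective value, unweighted energy RMSE, and the
#' percent deviation of each parameter from the protocol's start.
#'
#' @param stages list of [reference_dataset()]s (with reference energies),
#'   ordered by stage.
#' @param surface the template surface whose parameters are fitted.
#' @param start a [param_vector()] with bounds: the degraded starting
#'   parametrization.
#' @param objective `"chi1"` (default) or `"chi0"`.
#' @param freq_terms optional frequency terms passed to every stage's
#'   [objective_spec()].
#' @param n_starts,global_evals stage-1 global budget.
#' @param local_evals per-stage local budget.
#' @param seed seed for the global starts.
#' @param ... further arguments to [objective_spec()].
#' @return object of class `fit_ledger`: list with `records` (data frame),
#'   `best` (a `param_vector`), `stage_params` (list), `start`.
#' @export
staged_fit <- function(stages, surface, start, objective = c("chi1", "chi0"),
                       freq_terms = list(), n_starts = 20L,
                       global_evals = 4000L, local_evals = 2000L,
                       seed = 1L, ...) {
  objective <- match.arg(objective)
  chi_fun <- if (objective == "chi1") chi1 else chi0
  stopifnot(length(stages) >= 1L, inherits(start, "param_vector"))
  zeta <- start$values
  records <- list()
  stage_params <- list()
  for (s in seq_along(stages)) {
    spec <- objective_spec(surface, stages[[s]], freq_terms = freq_terms, ...)
    obj <- function(z) chi_fun(z, spec)
    res <- tryCatch({
      if (s == 1L) {
        g <- global_optimize(obj, start, n_starts = n_starts,
                             max_evals = global_evals, seed = seed)
        l <- local_optimize(obj, start, g$par, max_evals = local_evals)
        if (l$value <= obj(zeta)) l else list(par = zeta, value = obj(zeta),
                                              evals = g$evals)
      } else {
        local_optimize(obj, start, zeta, max_evals = local_evals)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("stage %d failed: %s; returning ledger so far", s,
                      conditionMessage(res)))
      break
    }
    zeta <- res$par
    stage_params[[s]] <- zeta
    dev <- ifelse(start$values != 0,
                  100 * (zeta - start$values) / start$values, 0)
    records[[s]] <- data.frame(
      stage = s, n_points = dataset_size(stages[[s]]),
      optimizer = if (s == 1L) "global+local" else "local",
      evals = res$evals, chi = res$value,
      rmse = fit_rmse(zeta, spec),
      max_param_dev_pct = max(abs(dev)))
  }
  structure(list(records = do.call(rbind, records),
                 best = param_vector(start$names, zeta, start$lower, start$upper),
                 stage_params = stage_params, start = start),
            class = "fit_ledger")
}

#' @export
print.fit_ledger <- function(x, ...) {
  cat("staged fit ledger:\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Cumulative RMSE curve over ascending energy cutoffs
#'
#' For each cutoff, the unweighted RMSE over the dataset entries whose
#' reference energy does not exceed it; empty bins are omitted and
#' flagged.
#'
#' @param dataset a [reference_dataset()] with reference energies.
#' @param surface the fitted surface to evaluate.
#' @param cutoffs ascending energies (cm^-1).
#' @param ref_geometry energy-reference geometry (default: lowest-energy
#'   entry).
#' @return data frame with `cutoff`, `n`, `rmse`; attribute `omitted`
#'   lists cutoffs with no entries.
#' @export
cumulative_rmse <- function(dataset, surface, cutoffs, ref_geometry = NULL) {
  stopifnot(!is.unsorted(cutoffs))
  if (is.null(ref_geometry))
    ref_geometry <- dataset$geometry[which.min(dataset$energy), ]
  e <- surface_energies(surface, dataset$geometry) -
    surface_energy(surface, ref_geometry)
  res <- e - dataset$energy
  rows <- lapply(cutoffs, function(ct) {
    sel <- dataset$energy <= ct
    if (!any(sel)) return(NULL)
    data.frame(cutoff = ct, n = sum(sel), rmse = sqrt(mean(res[sel]^2)))
  })
  omitted <- cutoffs[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cutoff = numeric(), n = integer(),
                                      rmse = numeric())
  attr(out, "omitted") <- omitted
  out
}
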