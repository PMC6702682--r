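# a controlled objective spec where the energy residuals are known exactly:
# reference energies are the template's own relative energies shifted by
# `resid`, so chi at the template parameters has residuals equal to -resid
spec_with_residuals <- function(resid, surface = toy_reference(0, 3), ...) {
  n <- length(resid)
  set.seed(41)
  G <- cbind(matrix(rep(surface$q0, each = n + 1), n + 1) +
               matrix(runif((n + 1) * 2, -0.02, 0.02), n + 1),
             c(0, runif(n, 0.2, 1.2)))
  e <- surface_energies(surface, G) - surface_energy(surface, G[1, , drop = TRUE])
  ds <- reference_dataset(G[-1, , drop = FALSE], energy = e[-1] - resid)
  objective_spec(surface, ds, ref_geometry = G[1, ], ...)
}

test_that("the step weight is a continuous exponential shoulder", {
  expect_identical(step_weight(5, alpha = 5, beta = -2), 1)
  expect_equal(step_weight(5 + 1e-12, alpha = 5, beta = -2), 1,
               tolerance = 1e-9)
  expect_true(all(step_weight(c(-3, 0, 2, 7), alpha = 10, beta = 0) == 1))
  expect_equal(step_weight(2, alpha = 0, beta = -1), exp(-2))
  expect_true(all(step_weight(seq(-5, 20, 0.5), 3, -0.7) > 0))
})

test_that("chi0 matches the two-term weighted mean-square arithmetic", {
  # residuals (3, 4) with unit weights: (9 + 16) / 2
  spec <- spec_with_residuals(c(3, 4), beta_E = 0)
  z <- surface_params(spec$surface)$values
  expect_equal(chi0(z, spec), 12.5, tolerance = 1e-8)
  expect_equal(chi1(z, spec), 12.5, tolerance = 1e-8)

  # perfect data: both objectives vanish at the true parameters
  spec0 <- spec_with_residuals(c(0, 0, 0), beta_E = 0)
  expect_lt(chi0(z, spec0), 1e-12)
  expect_lt(chi1(z, spec0), 1e-12)

  # objectives are invariant under dataset permutation
  spec_p <- spec0
  perm <- c(3, 1, 2)
  spec_p$dataset <- reference_dataset(spec0$dataset$geometry[perm, ],
                                      energy = spec0$dataset$energy[perm])
  zp <- z * c(rep(1.01, length(z) - 1), 1)
  expect_equal(chi1(zp, spec0), chi1(zp, spec_p), tolerance = 1e-10)

  # objectives are nonnegative everywhere
  set.seed(42)
  for (r in 1:5) {
    zr <- z * runif(length(z), 0.9, 1.1)
    expect_gte(chi0(zr, spec), 0)
    expect_gte(chi1(zr, spec), 0)
  }
})

test_that("chi0 and chi1 differ when energy and frequency terms are unbalanced", {
  s <- toy_reference(0, 3)
  sp_min <- refine_stationary(s, c(s$q0 + s$d, 0), "minimum")
  spec <- spec_with_residuals(c(3, 4, 5), surface = s, beta_E = 0)
  spec$freq_terms <- list(list(sp = sp_min, ref = sp_min$frequencies + 10))
  z <- surface_params(s)$values
  v0 <- chi0(z, spec)   # n = 3 energies, m = 3 frequencies, separate means
  v1 <- chi1(z, spec)   # single mean over 6 entries
  expect_equal(v0, mean(c(9, 16, 25)) + mean(rep(100, 3)), tolerance = 1e-6)
  expect_equal(v1, mean(c(9, 16, 25, rep(100, 3))), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(v0, v1)))
})

test_that("failed evaluations return the finite penalty value, flagged", {
  spec <- spec_with_residuals(c(1, 2))
  bad <- numeric(3)  # wrong parameter dimension: surface rebuild fails
  v <- chi0(bad, spec)
  expect_identical(as.numeric(v), spec$penalty)
  expect_true(isTRUE(attr(v, "failed")))
  expect_identical(as.numeric(chi1(bad, spec)), spec$penalty)
})

test_that("local optimization descends and respects degenerate bounds", {
  # quadratic bowl: recovered to high accuracy
  quad <- function(z) sum((z - c(0.3, -0.2))^2)
  res <- local_optimize(quad, list(lower = c(-1, -1), upper = c(1, 1)),
                        start = c(0.9, 0.9), max_evals = 2000)
  expect_lt(max(abs(res$par - c(0.3, -0.2))), 1e-8)

  # starting at the optimum is never made worse
  res0 <- local_optimize(quad, list(lower = c(-1, -1), upper = c(1, 1)),
                         start = c(0.3, -0.2), max_evals = 200)
  expect_lte(res0$value, quad(c(0.3, -0.2)) + 1e-15)

  # fixed parameters (equal bounds) never move
  res2 <- local_optimize(function(z) sum(z^2),
                         list(lower = c(-1, 0.5), upper = c(1, 0.5)),
                         start = c(0.8, 0.5), max_evals = 500)
  expect_identical(res2$par[2], 0.5)
  expect_lt(abs(res2$par[1]), 1e-6)

  expect_error(local_optimize(quad, list(lower = c(0, 0), upper = c(1, 1)),
                              start = c(2, 0.5)), "outside")
})

test_that("multistart clustering finds global minima of multiwell objectives", {
  # convex bowl: any seed recovers the analytic minimizer
  bowl <- function(z) sum((z - c(0.2, 0.7))^2) + 1
  for (seed in c(1, 7)) {
    g <- global_optimize(bowl, list(lower = c(-2, -2), upper = c(2, 2)),
                         n_starts = 10, max_evals = 2000, seed = seed)
    expect_lt(max(abs(g$par - c(0.2, 0.7))), 1e-6)
    expect_gte(nrow(g$clusters), 1L)
  }

  # rugged multiwell (Ackley-like): beats the best of 100 random draws
  ack <- function(z) {
    -20 * exp(-0.2 * sqrt(mean(z^2))) - exp(mean(cos(2 * pi * z))) +
      20 + exp(1) + 0.05 * sum((z - 0.5)^2)
  }
  g <- global_optimize(ack, list(lower = c(-4, -4), upper = c(4, 4)),
                       n_starts = 30, max_evals = 4000, seed = 2)
  set.seed(3)
  rand_best <- min(apply(matrix(runif(200, -4, 4), 100, 2), 1, ack))
  expect_lte(g$value, rand_best)

  # a single start reduces to one local descent
  g1 <- global_optimize(bowl, list(lower = c(-2, -2), upper = c(2, 2)),
                        n_starts = 1, max_evals = 1000, seed = 1)
  expect_identical(nrow(g1$clusters), 1L)
  expect_lt(max(abs(g1$par - c(0.2, 0.7))), 1e-6)
})

test_that("parameters are recovered from a degraded start on a small dataset", {
  ref <- toy_reference(0, 3)
  truth <- surface_params(ref)
  bounds <- default_param_bounds(truth, 0.5)
  start <- perturb_params(bounds, 0.2, seed = 11)

  sps <- toy_stationary_points(ref)
  deltas <- c(1.5 * ref$a^(-1 / 4), 0.25)
  d1 <- do.call(combine_datasets,
                lapply(sps, grid_displacements, order = 1, deltas = deltas,
                       n_per_dof = 4))
  d2 <- do.call(combine_datasets,
                lapply(sps, grid_displacements, order = 2, deltas = deltas,
                       n_per_dof = 3))
  ds <- assemble_stage(list(d1, d2), "fit")  # ~100 1D + 2D points
  ds$energy <- surface_energies(ref, ds$geometry) - sps$min1$energy
  # displacement sets exclude their pivot, so the energy zero (the minimum)
  # must be passed explicitly; the lowest *entry* is not the minimum
  spec <- objective_spec(ref, ds, ref_geometry = sps$min1$geometry)
  obj <- function(z) chi1(z, spec)

  loc <- local_optimize(obj, bounds, start$values, max_evals = 4000)
  expect_lte(loc$value, obj(start$values))
  rel <- sqrt(sum((loc$par - truth$values)^2)) / sqrt(sum(truth$values^2))
  expect_lt(rel, 0.02)
  expect_lt(fit_rmse(loc$par, spec), 0.01 * diff(range(ds$energy)))
})

test_that("staged fits are warm-started and never regress on fixed data", {
  ref <- toy_reference(1, 3)
  truth <- surface_params(ref)
  bounds <- default_param_bounds(truth, 0.5)
  start <- perturb_params(bounds, 0.15, seed = 3)
  sps <- toy_stationary_points(ref)
  stages3 <- build_reference_stages(ref, sps, seed = 5)[c(1, 2, 3)]

  led <- staged_fit(stages3, ref, start, n_starts = 10, global_evals = 1200,
                    local_evals = 1200, seed = 9)
  expect_identical(nrow(led$records), 3L)
  expect_identical(led$records$optimizer,
                   c("global+local", "local", "local"))

  # held-out validation: the final stage fits no worse than the first
  val <- random_fD(rbind(c(ref$q0 - 0.1, 0), c(ref$q0 + 0.1, pi)), 100,
                   seed = 31)
  val$energy <- surface_energies(ref, val$geometry) - sps$min1$energy
  vspec <- objective_spec(ref, val)
  expect_lte(fit_rmse(led$stage_params[[3]], vspec),
             fit_rmse(led$stage_params[[1]], vspec) + 1e-9)

  # refitting the same dataset from the previous best cannot get worse
  spec1 <- objective_spec(ref, stages3[[1]])
  again <- local_optimize(function(z) chi1(z, spec1), bounds,
                          led$stage_params[[1]], max_evals = 400)
  expect_lte(again$value, chi1(led$stage_params[[1]], spec1) + 1e-12)
})

test_that("cumulative RMSE curves bin by reference energy", {
  ref <- toy_reference(0, 3)
  ds <- random_fD(rbind(c(ref$q0 - 0.08, 0), c(ref$q0 + 0.08, pi)), 100,
                  seed = 13)
  ds$energy <- surface_energies(ref, ds$geometry)

  # perfect fit: identically zero curve
  curve <- cumulative_rmse(ds, ref, c(1000, 5000, 1e5),
                           ref_geometry = c(ref$q0 + ref$d, 0))
  expect_true(all(curve$rmse < 1e-9))

  # one cutoff above everything reproduces the global RMSE
  pert <- set_surface_params(ref, surface_params(ref)$values * 1.01)
  spec <- objective_spec(ref, ds, ref_geometry = c(ref$q0 + ref$d, 0))
  g_rmse <- fit_rmse(surface_params(pert)$values, spec)
  curve2 <- cumulative_rmse(ds, pert, max(ds$energy),
                            ref_geometry = c(ref$q0 + ref$d, 0))
  expect_equal(curve2$rmse, g_rmse, tolerance = 1e-8)

  # cutoffs below every energy are omitted and flagged
  curve3 <- cumulative_rmse(ds, pert, c(-10, max(ds$energy)),
                            ref_geometry = c(ref$q0 + ref$d, 0))
  expect_identical(nrow(curve3), 1L)
  expect_identical(attr(curve3, "omitted"), -10)
})
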