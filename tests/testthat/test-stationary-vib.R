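test_that("numerical Hessians reproduce closed-form second derivatives", {
  # 1D quadratic
  H1 <- numerical_hessian(function(x) 0.5 * 3.7 * x^2, 0.2)
  expect_equal(H1[1, 1], 3.7, tolerance = 1e-8)

  # separable toy: off-diagonal chain-torsion blocks vanish at the minimum
  s0 <- toy_torsion_surface(3, a = c(4e5, 9e5), d = c(0, 0), b = 0, c1 = 0,
                            c2 = 2000, q0 = c(1.5, 2.0))
  Hs <- numerical_hessian(s0, c(1.5, 2.0, 0), step = 1e-4)
  expect_lt(max(abs(Hs[upper.tri(Hs)])), 1e-6 * max(abs(diag(Hs))))

  # bilinear coupling appears exactly as the cross entry
  s <- toy_reference(0, 3)
  Hb <- numerical_hessian(s, c(s$q0 + s$d, 0), step = 1e-4)
  expect_equal(Hb[1, 2], s$B[1, 2], tolerance = 1e-6 * max(1, abs(s$B[1, 2])))
})

test_that("harmonic frequencies follow the sign-sqrt mass-weighting convention", {
  expect_equal(harmonic_frequencies(matrix(640000, 1, 1))$frequencies, 800)
  # mass scaling: omega = sqrt(k / m)
  expect_equal(harmonic_frequencies(matrix(640000, 1, 1),
                                    masses = 4)$frequencies, 400)
  # one negative eigenvalue = transition-state signature, printed negative
  H <- diag(c(-360000, 250000))
  fr <- harmonic_frequencies(H)$frequencies
  expect_identical(sum(fr < 0), 1L)
  expect_equal(fr, c(-600, 500))
  # decoupled toy: frequencies are sqrt(a) at unit mass
  s0 <- toy_torsion_surface(3, a = c(4e5, 9e5), d = c(0, 0), b = 0, c1 = 0,
                            c2 = 2000, q0 = c(1.5, 2.0))
  sp <- refine_stationary(s0, c(1.5, 2.0, 0), "minimum")
  expect_equal(sort(sp$frequencies)[2:3], sqrt(c(4e5, 9e5)), tolerance = 1e-6)
  expect_equal(min(sp$frequencies), sqrt(4 * 2000), tolerance = 1e-6)

  expect_error(harmonic_frequencies(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("frequencies are equivariant under DOF relabeling", {
  s <- toy_reference(0, 3)
  H <- numerical_hessian(s, c(s$q0 + s$d, 0), step = 1e-4)
  perm <- c(3, 1, 2)
  f1 <- harmonic_frequencies(H)$frequencies
  f2 <- harmonic_frequencies(H[perm, perm])$frequencies
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("stationary refinement finds minima and saddles and reports failure", {
  s <- toy_reference(0, 3)
  # start exactly at the minimum: returns immediately
  sp <- refine_stationary(s, c(s$q0 + s$d, 0), "minimum")
  expect_identical(attr(sp, "iterations"), 0L)
  expect_identical(sp$kind, "minimum")
  expect_true(all(sp$frequencies > 0))

  # converges to the saddle from a displaced guess near phi = pi/2
  ts <- refine_stationary(s, c(s$q0 + 0.01, pi / 2 + 0.05), "ts")
  expect_identical(sp_neg <- sum(ts$frequencies < 0), 1L)
  expect_equal(ts$energy, 2 * s$c2, tolerance = 1e-6)

  # tiny iteration budget from far away fails loudly
  expect_error(
    refine_stationary(s, c(s$q0 + 0.5, 1.0), "minimum", max_iter = 1L,
                      tol = 1e-10),
    "did not converge")

  # wrong-index convergence is reported, not silently accepted
  expect_warning(refine_stationary(s, c(s$q0, pi / 2), "minimum"),
                 "not the requested")
})

test_that("normal-mode sampling partitions the energy exactly over modes", {
  s <- toy_reference(0, 3)
  sp <- refine_stationary(s, c(s$q0 + s$d, 0), "minimum")

  st <- normal_mode_sample(sp, 500, seed = 2, surface = s)
  expect_equal(sum(st$mode_energies), 500)
  st2 <- normal_mode_sample(sp, 500, seed = 3, surface = s)
  expect_false(identical(st$mode_energies, st2$mode_energies))
  expect_equal(sum(st2$mode_energies), 500)

  # at low energy the harmonic picture holds: residual below 1% of the request
  low <- normal_mode_sample(sp, 20, seed = 2, surface = s)
  expect_lt(abs(attr(low, "energy_residual")), 0.01 * 20)

  # 1D closed form: phase at the turning point gives sqrt(2E/k), zero velocity
  s1 <- toy_torsion_surface(2, a = 1e6, d = 0, b = numeric(), c1 = 0,
                            c2 = 1e6, q0 = 1.5)
  sp1 <- refine_stationary(s1, c(1.5, 0), "minimum")
  k_chain <- 1e6
  st1 <- normal_mode_sample(sp1, 100, seed = 1, phases = c(pi / 2, pi / 2))
  mode_chain <- which.max(abs(sp1$modes[1, ]))
  disp <- abs(st1$geometry[1] - 1.5)
  expect_equal(disp, sqrt(2 * st1$mode_energies[mode_chain] / k_chain),
               tolerance = 1e-8)
  expect_lt(max(abs(st1$velocities)), 1e-10)

  ts <- refine_stationary(s, c(s$q0, pi / 2), "ts")
  expect_error(normal_mode_sample(ts, 100), "minimum")
})

test_that("velocity-Verlet trajectories store every frame and conserve energy", {
  s <- toy_reference(0, 3)
  sp <- refine_stationary(s, c(s$q0 + s$d, 0), "minimum")

  # 1 ps at 5 fs stores 201 frames including t = 0
  st <- normal_mode_sample(sp, 1750, seed = 4, surface = s)
  tr <- propagate_verlet(s, st, dt = 5, n_steps = 200)
  expect_identical(length(tr$time), 201L)
  expect_identical(nrow(tr$geometry), 201L)
  expect_identical(tr$time[1], 0)

  # zero velocities at the minimum: stationary trajectory
  tr0 <- propagate_verlet(s, list(geometry = sp$geometry,
                                  velocities = numeric(3)),
                          dt = 5, n_steps = 50)
  expect_lt(max(abs(tr0$potential - tr0$potential[1])), 1e-12 * max(1, abs(sp$energy)))
  expect_lt(max(abs(tr0$geometry[51, ] - sp$geometry)), 1e-9)

  # harmonic 1D at dt = T/100: bounded fluctuation, tiny secular drift
  sh <- toy_torsion_surface(2, a = 1, d = 0, b = numeric(), c1 = 0,
                            c2 = 1e-12, q0 = 0)
  trh <- propagate_verlet(sh, list(geometry = c(sqrt(200), 0),
                                   velocities = c(0, 0)),
                          dt = 2 * pi / 100, n_steps = 1000,
                          time_unit = "natural")
  expect_lt(trh$fluctuation, 1.1 * (2 * pi / 100)^2 / 4)  # (omega dt)^2 / 4 law
  expect_lt(trh$drift, 1e-4)
})

test_that("refit surfaces track reference trajectories better than degraded ones", {
  ref <- toy_reference(0, 3)
  sp <- refine_stationary(ref, c(ref$q0 + ref$d, 0), "minimum")
  st <- normal_mode_sample(sp, 3000, seed = 5, surface = ref)
  tr <- propagate_verlet(ref, st, dt = 5, n_steps = 100)

  truth <- surface_params(ref)
  bounds <- default_param_bounds(truth, 0.5)
  degraded <- set_surface_params(ref, perturb_params(bounds, 0.2, seed = 6))
  # a mildly perturbed set stands in for a partially recovered fit
  near <- set_surface_params(ref, perturb_params(bounds, 0.005, seed = 6))

  cmp_deg <- trajectory_energy_compare(tr, degraded)
  cmp_near <- trajectory_energy_compare(tr, near)
  expect_lt(cmp_near$rmse, cmp_deg$rmse)
})

test_that("trajectory export writes the energy table and XYZ frames", {
  s <- toy_reference(0, 3)
  sp <- refine_stationary(s, c(s$q0 + s$d, 0), "minimum")
  st <- normal_mode_sample(sp, 500, seed = 1, surface = s)
  tr <- propagate_verlet(s, st, dt = 5, n_steps = 10)
  csv <- tempfile(fileext = ".csv")
  export_trajectory(tr, csv)
  tab <- utils::read.csv(csv)
  expect_identical(nrow(tab), 11L)
  expect_equal(tab$total, tab$potential + tab$kinetic)
  expect_error(export_trajectory(tr, csv, xyz_path = tempfile()), "3N")
})
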