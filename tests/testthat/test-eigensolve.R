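test_that("the DVR Hamiltonian reproduces closed-form oscillator spectra", {
  # 1D harmonic, unit mass and frequency: ZPE = 1/2, spacing 1
  g <- build_dvr("harmonic", 25, NULL)
  H <- build_hamiltonian(list(g), masses = 1,
                         potential = array(g$points^2 / 2, dim = 25L))
  er <- lowest_eigenpairs(H, 6)
  expect_lt(abs(er$zpe - 0.5), 1e-8)
  expect_equal(er$levels, 0:5, tolerance = 1e-6)

  # k = 1 returns only the zero level
  er1 <- lowest_eigenpairs(H, 1)
  expect_identical(er1$levels, 0)
  expect_error(lowest_eigenpairs(H, 25), "smaller")

  # 2D separable: eigenvalues are sums of 1D levels
  g2 <- build_dvr("harmonic", 21, NULL)
  n2 <- 21
  V2 <- outer(g2$points^2 / 2, rep(1, n2)) + outer(rep(1, n2), 2 * g2$points^2)
  H2 <- build_hamiltonian(list(g2, g2), masses = c(1, 1), potential = V2)
  er2 <- lowest_eigenpairs(H2, 6)
  # omega_1 = 1, omega_2 = 2: levels 0, 1, 2, 2, 3, 3
  expect_equal(er2$levels, c(0, 1, 2, 2, 3, 3), tolerance = 1e-6)
  expect_lt(abs(er2$zpe - 1.5), 1e-6)
})

test_that("a Tucker-decomposed potential gives the same spectrum as the raw one", {
  s <- morse_toy(0)
  grids <- default_toy_grids(s, n_chain = 8L, n_phi = 10L)
  dec <- mgpf_decompose(s, make_multigrid(grids, 2), rmse_sample = 0)
  H_direct <- build_hamiltonian(grids, s$masses, s)
  H_tucker <- build_hamiltonian(grids, s$masses, dec$potential)
  e1 <- lowest_eigenpairs(H_direct, 8)
  e2 <- lowest_eigenpairs(H_tucker, 8)
  dec_err <- rmse_on_grid(dec$potential, s, "full")$max_abs_error
  expect_lt(max(abs(e1$levels - e2$levels)), max(dec_err, 1e-8))
})

test_that("spectra improve monotonically as the coarse grid is refined", {
  s <- morse_toy(0)
  grids <- default_toy_grids(s, n_chain = 10L, n_phi = 10L)
  ref <- lowest_eigenpairs(build_hamiltonian(grids, s$masses, s), 6)
  errs <- vapply(c(5, 3, 1), function(k) {
    dec <- mgpf_decompose(s, suppressWarnings(make_multigrid(grids, k)),
                          rmse_sample = 0)
    lev <- lowest_eigenpairs(build_hamiltonian(grids, s$masses,
                                               dec$potential), 6)
    eigen_rmse(lev$levels, ref$levels)$rmse
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("a symmetric double well shows positive near-degenerate tunneling doublets", {
  # quartic double well h (x^2 - 1)^2: barrier h, wells at +-1
  g <- build_dvr("harmonic", 61, c(-2.5, 2.5))
  h_barrier <- 50
  H <- build_hamiltonian(list(g), masses = 1,
                         potential = array(h_barrier * (g$points^2 - 1)^2,
                                           dim = 61L))
  er <- lowest_eigenpairs(H, 4)
  split0 <- er$levels[2] - er$levels[1]
  gap <- er$levels[3] - er$levels[2]
  expect_gt(split0, 0)
  expect_lt(split0, 0.2 * gap)  # doublet well separated from the next pair

  # splitting is converged with respect to the grid
  g2 <- build_dvr("harmonic", 81, c(-2.8, 2.8))
  H2 <- build_hamiltonian(list(g2), masses = 1,
                          potential = array(h_barrier * (g2$points^2 - 1)^2,
                                            dim = 81L))
  er2 <- lowest_eigenpairs(H2, 4)
  expect_equal(er2$levels[2] - er2$levels[1], split0, tolerance = 1e-6)
})

test_that("eigenvalues are invariant under DOF reordering", {
  s <- morse_toy(2)
  grids <- default_toy_grids(s, n_chain = 8L, n_phi = 8L)
  V <- sopes:::tensor_from_backend(s, grids)
  H1 <- build_hamiltonian(grids, s$masses, V)
  perm <- c(2, 1, 3)
  H2 <- build_hamiltonian(grids[perm], s$masses[perm], aperm(V, perm))
  e1 <- lowest_eigenpairs(H1, 5)
  e2 <- lowest_eigenpairs(H2, 5)
  expect_equal(e1$levels, e2$levels, tolerance = 1e-8)
  expect_equal(e1$zpe, e2$zpe, tolerance = 1e-8)
})

test_that("level-ladder comparison uses all rows including the zero row", {
  lev <- c(0, 100, 200); ref <- c(0, 110, 190)
  r <- eigen_rmse(lev, ref)
  expect_equal(r$rmse, sqrt(mean(c(0, 100, 4 * 25))))
  expect_equal(r$mad, mean(c(0, 10, 10)))
  expect_error(eigen_rmse(c(0, 1), c(0, 1, 2)), "equal length")
})

test_that("autocorrelation spectra peak at the populated eigenvalues", {
  g <- build_dvr("harmonic", 21, NULL)
  H <- build_hamiltonian(list(g), masses = 1,
                         potential = array(g$points^2 / 2, dim = 21L))
  e <- eigen(H$matrix, symmetric = TRUE)
  ord <- order(e$values)
  v1 <- e$vectors[, ord[1]]; ev1 <- e$values[ord[1]]
  v2 <- e$vectors[, ord[3]]; ev2 <- e$values[ord[3]]

  # a single eigenvector gives a single peak at its eigenvalue
  sp1 <- autocorrelation_spectrum(v1, H, t_max = 60, dt = 0.05)
  expect_identical(length(sp1$peaks), 1L)
  expect_lt(abs(sp1$peaks - ev1), 0.15)

  # an equal two-eigenvector superposition gives exactly two peaks
  psi <- (v1 + v2) / sqrt(2)
  sp2 <- autocorrelation_spectrum(psi, H, t_max = 60, dt = 0.05)
  expect_identical(length(sp2$peaks), 2L)
  expect_equal(sort(sp2$peaks), c(ev1, ev2), tolerance = 0.15)

  expect_error(autocorrelation_spectrum(2 * v1, H, 10, 0.1), "normalized")
})

test_that("a one-quantum stretch excitation peaks at the corresponding levels", {
  s <- morse_toy(4)
  grids <- default_toy_grids(s, n_chain = 9L, n_phi = 9L)[c(1, 3)]
  # 2D cut: first chain coordinate and the torsion, near the phi = 0 well
  cut <- function(q) surface_energy(s, c(q[1], s$q0[2] + s$d[2] * cos(q[2]), q[2]))
  H <- build_hamiltonian(grids, s$masses[c(1, 3)], cut)
  er <- lowest_eigenpairs(H, 12)
  # displace the ground state along the stretch (crude one-quantum surrogate)
  psi0 <- er$vectors[, 1] * (grids[[1]]$points[(seq_len(H$dim) - 1) %% 9 + 1] -
                               mean(grids[[1]]$points))
  psi0 <- psi0 / sqrt(sum(psi0^2))
  all_lev <- er$zpe + er$levels
  sp <- autocorrelation_spectrum(psi0, H, t_max = 0.2, dt = 1e-4,
                                 energy_grid = seq(min(all_lev) - 200,
                                                   max(all_lev) + 200,
                                                   length.out = 4096))
  # every detected peak in the window sits near an eigenlevel of the operator
  expect_gt(length(sp$peaks), 0L)
  for (p in sp$peaks)
    expect_lt(min(abs(p - all_lev)), 30)
})

test_that("the shipped benchmark tables load with the documented shapes", {
  lev <- hono_reference_levels()
  expect_identical(dim(lev), c(21L, 4L))
  expect_true(all(lev[1, ] == 0))
  gd <- hono_grid_definition(build = TRUE)
  expect_identical(nrow(gd), 6L)
  grids <- attr(gd, "grids")
  expect_identical(primitive_grid_size(grids), 28035072)
  expect_identical(grids[[6]]$kind, "cosine")
})
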