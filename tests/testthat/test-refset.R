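test_that("displacement grids have the n-body combinatorial counts", {
  pivot <- rep(0, 6)
  d1 <- grid_displacements(pivot, order = 1, deltas = 0.1, n_per_dof = 5)
  expect_identical(dataset_size(d1), 30L)  # 6 DOFs x 5 levels
  expect_true(all(d1$tag == "1D"))
  # each entry differs from the pivot in exactly one coordinate
  expect_true(all(rowSums(d1$geometry != 0) == 1L))

  d2 <- grid_displacements(pivot, order = 2, deltas = 0.1, n_per_dof = 3)
  expect_identical(dataset_size(d2), 135L)  # 15 pairs x 3x3 grids
  expect_true(all(rowSums(d2$geometry != 0) == 2L))

  d0 <- grid_displacements(pivot, order = 1, deltas = 0.1, n_per_dof = 0)
  expect_identical(dataset_size(d0), 0L)

  expect_warning(
    grid_displacements(c(0, 0), order = 1, deltas = 1, n_per_dof = 4,
                       bounds = rbind(c(-1.5, -1.5), c(1.5, 1.5))),
    "clipped")
})

test_that("random full-D draws are reproducible per seed", {
  b <- rbind(c(0, 0, 0), c(1, 2, pi))
  expect_identical(dataset_size(random_fD(b, 0)), 0L)
  r1 <- random_fD(b, 25, seed = 4)
  r2 <- random_fD(b, 25, seed = 4)
  expect_identical(r1$geometry, r2$geometry)
  expect_false(identical(r1$geometry, random_fD(b, 25, seed = 5)$geometry))
  expect_true(all(r1$geometry >= rep(b[1, ], each = 25) &
                    r1$geometry <= rep(b[2, ], each = 25)))
})

test_that("internal-coordinate interpolation is linear with a shorter-arc rule", {
  a <- c(1, 2, 0.1); b <- c(2, 1, 0.9)
  p2 <- liic(a, b, n_points = 2)
  expect_equal(p2$points, rbind(a, b), ignore_attr = TRUE)

  p3 <- liic(a, b, n_points = 3)
  expect_equal(p3$points[2, ], (a + b) / 2)
  expect_equal(p3$X, c(0, 0.5, 1))

  # torsion from 350 to 10 degrees passes through 0, not 180
  deg <- pi / 180
  pp <- liic(c(0, 350 * deg), c(0, 10 * deg), n_points = 5,
             periodic = c(FALSE, TRUE))
  phi <- pp$points[, 2] / deg
  expect_equal(phi[3], 0, tolerance = 1e-10)
  expect_true(all(pmin(phi, 360 - phi) <= 10 + 1e-10))

  expect_error(liic(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("path distortion clouds blend endpoint modes and scale linearly", {
  set.seed(21)
  f <- 4
  Mi <- qr.Q(qr(matrix(rnorm(f * 3), f, 3)))
  Mf <- qr.Q(qr(matrix(rnorm(f * 3), f, 3)))
  path <- liic(rep(0, f), rep(1, f), n_points = 5)

  # zero factor scale collapses the cloud onto the path
  cl0 <- liic_cloud(path, Mi, Mf, n_per_point = 3, factor_scale = 0, seed = 1)
  cloud0 <- cl0$geometry[cl0$tag == "rnd(LIIC)", , drop = FALSE]
  expect_equal(cloud0, path$points[rep(1:5, each = 3), ], ignore_attr = TRUE)

  # counting: 50-point path with 4 per point gives 200 cloud + 50 path entries
  path50 <- liic(rep(0, f), rep(1, f), n_points = 50)
  cl <- liic_cloud(path50, Mi, Mf, n_per_point = 4, factor_scale = 0.1, seed = 2)
  expect_identical(sum(cl$tag == "rnd(LIIC)"), 200L)
  expect_identical(sum(cl$tag == "LIIC"), 50L)

  # endpoint blending: displacements at X = 0 lie in the span of modes_init
  cl1 <- liic_cloud(path, Mi, Mf, n_per_point = 6, factor_scale = 0.3, seed = 3)
  cloud <- cl1$geometry[cl1$tag == "rnd(LIIC)", , drop = FALSE]
  d_first <- t(cloud[1:6, , drop = FALSE]) - path$points[1, ]
  resid_i <- d_first - Mi %*% crossprod(Mi, d_first)
  expect_lt(max(abs(resid_i)), 1e-10)
  d_last <- t(cloud[25:30, , drop = FALSE]) - path$points[5, ]
  resid_f <- d_last - Mf %*% crossprod(Mf, d_last)
  expect_lt(max(abs(resid_f)), 1e-10)

  # cloud radius grows linearly with the factor scale
  scales <- c(0.05, 0.1, 0.2, 0.4)
  mean_d <- vapply(scales, function(sc) {
    cls <- liic_cloud(path, Mi, Mf, n_per_point = 40, factor_scale = sc,
                      seed = 4)
    cloud <- cls$geometry[cls$tag == "rnd(LIIC)", , drop = FALSE]
    mean(sqrt(rowSums((cloud - path$points[rep(1:5, each = 40), ])^2)))
  }, numeric(1))
  ratio <- mean_d / scales  # proportional through the origin
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)

  expect_error(liic_cloud(path, Mi, Mf, exclude_mode = 9), "invalid")
})

test_that("the energy filter is inclusive at the cutoff", {
  ds <- reference_dataset(matrix(rnorm(9), 3, 3),
                          energy = c(4000, 5000, 6000))
  kept <- filter_by_energy(ds, cutoff = 5000)
  expect_identical(dataset_size(kept), 2L)
  expect_identical(attr(kept, "removed"), 1L)
  expect_identical(dataset_size(filter_by_energy(ds, cutoff = Inf)), 3L)
  expect_warning(filter_by_energy(ds, cutoff = 1000), "every entry")
  # filtering through a backend
  s <- toy_reference(0, 3)
  ds2 <- random_fD(rbind(c(s$q0 - 0.1, 0), c(s$q0 + 0.1, pi)), 50, seed = 1)
  low <- filter_by_energy(ds2, s, cutoff = 2000)
  expect_true(all(surface_energies(s, low$geometry) <= 2000))
})

test_that("stage assembly deduplicates and ledgers the composition", {
  g <- matrix(rnorm(12), 4, 3)
  core <- reference_dataset(g, tag = "core")
  dup <- reference_dataset(g[1:2, ], tag = "1D")  # duplicates two core points
  extra <- reference_dataset(matrix(rnorm(6), 2, 3), tag = "rnd(fD)")

  st <- assemble_stage(list(core, dup, extra), "stage1")
  expect_identical(dataset_size(st), 6L)  # 4 + 2 duplicated + 2 new
  expect_true(all(st$stage == "stage1"))
  expect_identical(attr(st, "ledger")$n, 6L)
  # ledger count equals the additive class composition
  expect_identical(sum(attr(st, "composition")), 6L)

  empty <- grid_displacements(rep(0, 3), order = 1, deltas = 1, n_per_dof = 0)
  st2 <- assemble_stage(list(core, empty), "stage2")
  expect_identical(dataset_size(st2), 4L)

  expect_error(assemble_stage(list(st), "stage1"), "clashing")
})

test_that("datasets round-trip through CSV", {
  ds <- reference_dataset(matrix(rnorm(15), 5, 3),
                          energy = runif(5, 0, 100),
                          tag = c("core", "1D", "1D", "2D", "rnd(fD)"),
                          stage = "s1")
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$geometry, ds$geometry, ignore_attr = TRUE)
  expect_equal(back$energy, ds$energy)
  expect_identical(back$tag, ds$tag)
})
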