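test_that("delta profiles are coordinate-wise relative differences", {
  prof <- delta_profile(c(2, 0, 3), c(1, 4, 3))
  expect_equal(unname(prof$values), c(1, -1, 0))
  expect_equal(unname(delta_profile(c(1, 4, 3), c(1, 4, 3))$values),
               c(0, 0, 0))
  expect_error(delta_profile(c(1, 2), c(1, 0)), "ZERO_REFERENCE")
  expect_error(delta_profile(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("delta and the raw difference always share sign", {
  set.seed(7)
  for (i in 1:20) {
    x_phys <- stats::runif(15, 0.1, 100)
    x_comp <- pmax(x_phys + stats::rnorm(15, 0, 30), 0)
    prof <- delta_profile(x_comp, x_phys)
    expect_true(all(sign(prof$values) == sign(x_comp - x_phys)))
    expect_true(all(prof$values >= -1))
  }
})

test_that("top_variations ranks by absolute concentration change", {
  x_phys <- c(a = 10, b = 5, c = 8)
  x_comp <- c(a = 15, b = 6, c = 11)   # |diff| = 5, 1, 3
  tab <- top_variations(x_comp, x_phys, m = 3)
  expect_identical(tab$species, c("a", "c", "b"))
  expect_equal(tab$abs_diff_nM, c(5, 3, 1))
  expect_equal(tab$delta, c(0.5, 3 / 8, 0.2))
  # equality keeps the species order, and m truncates
  tie <- top_variations(c(a = 10, b = 5, c = 8), c(a = 10, b = 5, c = 8), m = 2)
  expect_identical(tie$species, c("a", "b"))
})

test_that("the modified geometric mean honours its identities", {
  expect_equal(geometric_index(rep(0, 8)), 0)
  expect_equal(geometric_index(rep(1, 5)), 1)
  # independent arithmetic for n = 2, d = (0, 1)
  oracle <- sqrt(1e-6 * (1 + 1e-6)) - 1e-6
  expect_equal(geometric_index(c(0, 1)), oracle, tolerance = 1e-12)
  expect_equal(oracle, 9.99001e-4, tolerance = 1e-6)
  # permutation invariance and sign insensitivity
  d <- c(0.3, -0.2, 0, 4)
  expect_equal(geometric_index(d), geometric_index(rev(d)))
  expect_equal(geometric_index(d), geometric_index(abs(d)))
  expect_gt(geometric_index(d), 0)
  expect_error(geometric_index(numeric(0)), "empty")
})

test_that("mutation intensity grows as the retained deactivation rate drops", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_phys <- solve_equilibrium(net, basis, x0, seed = 1)
  norms <- vapply(c(0, 0.3, 0.6, 1), function(l) {
    net_l <- apply_gof(net, mutation_spec("KRAS", "GoF", l))
    eq <- solve_equilibrium(net_l, find_conservation_laws(net_l), x0, seed = 1)
    max(abs(delta_profile(eq$x_e, eq_phys$x_e)$values))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  expect_equal(norms[4], 0, tolerance = 1e-8)
})

test_that("1-D dose scans find an interior optimum with baseline at zero dose", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_phys <- solve_equilibrium(net, basis, x0, seed = 1)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- solve_equilibrium(net_mut, find_conservation_laws(net_mut), x0,
                              seed = 1)
  spec <- drug_spec("DBF", "competitive", "p-Raf")
  grid <- seq(0, 200, by = 25)
  scan <- dose_scan_1d(net_mut, eq_mut$x_e, eq_phys$x_e, spec, grid, seed = 1)
  expect_length(scan$failures, 0L)
  # G at dose 0 equals G of the mutated network itself
  G0 <- geometric_index(delta_profile(eq_mut$x_e, eq_phys$x_e))
  expect_equal(scan$G_values[1], G0)
  # interior minimum: strictly below both ends
  i_min <- which.min(scan$G_values)
  expect_gt(i_min, 1L)
  expect_lt(i_min, length(grid))
  expect_identical(scan$argmin, grid[i_min])
  expect_true(all(scan$G_values >= -1e-6))
})

test_that("2-D scan marginals at zero dose reproduce the 1-D scans exactly", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_phys <- solve_equilibrium(net, basis, x0, seed = 1)
  net_mut <- apply_gof(net, mutation_spec("KRAS", "GoF", 0))
  eq_mut <- solve_equilibrium(net_mut, find_conservation_laws(net_mut), x0,
                              seed = 1)
  dbf <- drug_spec("DBF", "competitive", "p-Raf")
  tmt <- drug_spec("TMT", "allosteric", c("MEK", "p-MEK", "pp-MEK"))
  gridA <- c(0, 50, 100)
  gridB <- c(0, 300, 600)
  scan2 <- dose_scan_2d(net_mut, eq_mut$x_e, eq_phys$x_e, dbf, tmt,
                        gridA, gridB, seed = 1)
  expect_length(scan2$failures, 0L)
  scanA <- dose_scan_1d(net_mut, eq_mut$x_e, eq_phys$x_e, dbf, gridA, seed = 1)
  scanB <- dose_scan_1d(net_mut, eq_mut$x_e, eq_phys$x_e, tmt, gridB, seed = 1)
  expect_identical(unname(scan2$G_values[, 1]), scanA$G_values)
  expect_identical(unname(scan2$G_values[1, ]), scanB$G_values)
  # argmin equals exhaustive recomputation
  idx <- which(scan2$G_values == min(scan2$G_values), arr.ind = TRUE)[1, ]
  expect_equal(scan2$argmin, c(gridA[idx[1]], gridB[idx[2]]))
})

test_that("activated fraction normalises by the conserved moiety total", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  traj <- simulate_crn(net, x0, seq(0, 2000, length.out = 9))
  frac <- activated_fraction(traj, "pp-ERK", basis, "ERK")
  expect_true(all(frac >= 0 & frac <= 1 + 1e-9))
  # all mass on the active species gives fraction 1
  x_all <- x0 * 0
  x_all["pp-ERK"] <- 400
  x_all["RasGDP"] <- 100
  traj2 <- simulate_crn(net, x_all, c(0, 1e-6))
  expect_equal(activated_fraction(traj2, "pp-ERK", basis, "ERK")[1], 1)
  expect_error(activated_fraction(traj, "pp-ERK", basis, "Raf_MEK"),
               "elemental|unknown")
  expect_error(activated_fraction(traj2, "pp-ERK", basis, "MEK"),
               "zero moiety")
})
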