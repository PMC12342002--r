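test_that("mass-action fluxes follow the power law", {
  net <- crn_network(
    list(crn_species("A", 3), crn_species("B", 4), crn_species("C", 0)),
    list(crn_reaction("r1", c(A = 1, B = 1), c(C = 1), 2),
         crn_reaction("r2", c(A = 2), c(B = 1), 1),
         crn_reaction("src", stats::setNames(numeric(0), character(0)),
                      c(C = 1), 7)))
  v <- reaction_fluxes(net, c(3, 4, 0))
  expect_equal(unname(v), c(2 * 3 * 4, 3^2, 7))
  # a zero reactant shuts the flux off
  expect_equal(unname(reaction_fluxes(net, c(0, 4, 0))["r1"]), 0)
  expect_error(reaction_fluxes(net, c(-1, 4, 0)), "negative")
})

test_that("ode_rhs is S v and vanishes at detailed balance", {
  net <- fixture_pair(k_f = 2, k_r = 1)
  expect_equal(unname(ode_rhs(net, c(1, 2))), c(0, 0))
  net2 <- crn_network(
    list(crn_species("A", 5), crn_species("B", 0)),
    list(crn_reaction("ab", c(A = 1), c(B = 1), 1)))
  expect_equal(unname(ode_rhs(net2, c(5, 0))), c(-5, 5))
})

test_that("conservation rows annihilate the rhs identically", {
  net <- build_mapk_toy()
  basis <- find_conservation_laws(net)
  for (s in 1:5) {
    set.seed(s)
    x <- stats::runif(length(net$species), 0, 50)
    expect_lt(max(abs(basis$N %*% ode_rhs(net, x))), 1e-10)
  }
})

test_that("analytic Jacobian matches hand-worked and finite differences", {
  net <- crn_network(
    list(crn_species("A", 5), crn_species("B", 0)),
    list(crn_reaction("ab", c(A = 1), c(B = 1), 1)))
  expect_equal(unname(crn_jacobian(net, c(5, 0))),
               matrix(c(-1, 1, 0, 0), 2))

  bi <- crn_network(
    list(crn_species("A", 3), crn_species("B", 4), crn_species("C", 0)),
    list(crn_reaction("r", c(A = 1, B = 1), c(C = 1), 2)))
  J <- crn_jacobian(bi, c(3, 4, 0))
  expect_equal(unname(J[, "A"]), c(-8, -8, 8))   # dv/dA = k*B = 8 through S
  expect_equal(unname(J[, "B"]), c(-6, -6, 6))

  for (s in 1:5) {
    net_r <- random_mass_action_network(7, 10, seed = 100 + s)
    set.seed(s)
    x <- stats::runif(length(net_r$species), 0.5, 20)
    expect_equal(crn_jacobian(net_r, x), oracle_fd_jacobian(net_r, x),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("first-order decay matches the closed form", {
  k <- log(2)
  net <- crn_network(
    list(crn_species("A", 8), crn_species("B", 0)),
    list(crn_reaction("ab", c(A = 1), c(B = 1), k)))
  traj <- simulate_crn(net, c(8, 0), seq(0, 1 / k, length.out = 5))
  expect_equal(unname(traj$states[5, "A"]), 8 * exp(-1),
               tolerance = 1e-6)
})

test_that("purely first-order networks match the matrix exponential", {
  skip_if_not_installed("Matrix")
  net <- fixture_linear_chain()
  # rate matrix K with dx/dt = K x, assembled independently of the package
  K <- matrix(0, 3, 3)
  K[1, 1] <- -0.3; K[2, 1] <- 0.3
  K[1, 2] <- 0.1; K[2, 2] <- -0.1 - 0.05; K[3, 2] <- 0.05
  K[2, 3] <- 0.2; K[3, 3] <- -0.2
  x0 <- c(10, 0, 1)
  for (t_end in c(1, 10, 50)) {
    expected <- as.numeric(Matrix::expm(K * t_end) %*% x0)
    traj <- simulate_crn(net, x0, c(0, t_end), rtol = 1e-10, atol = 1e-14)
    expect_equal(unname(traj$states[2, ]), expected, tolerance = 1e-8)
  }
})

test_that("stiff trajectories agree with a fine-step RK4 oracle", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  t_end <- 50
  traj <- simulate_crn(net, x0, c(0, t_end), rtol = 1e-10, atol = 1e-14)
  oracle <- oracle_rk4(net, x0, t_end, n_steps = 20000)
  expect_lt(max(rel_diff(traj$states[2, ], oracle)), 1e-6)
})

test_that("moiety totals are conserved along event-free trajectories", {
  nets <- list(build_mapk_toy(), fixture_enzyme(),
               random_mass_action_network(9, 12, seed = 5))
  for (net in nets) {
    basis <- find_conservation_laws(net)
    x0 <- initial_state(net)
    traj <- simulate_crn(net, x0, seq(0, 2000, length.out = 21))
    tot0 <- as.vector(basis$N %*% x0)
    drift <- apply(traj$states, 1, function(x)
      max(abs(as.vector(basis$N %*% x) - tot0)))
    expect_lt(max(drift), 1e-6 * max(abs(tot0)))
    expect_true(all(traj$states >= 0))
  }
})

test_that("an event at t=0 equals incrementing the initial state", {
  net <- build_mapk_toy()
  x0 <- initial_state(net)
  grid <- seq(0, 500, length.out = 6)
  ev <- administration_event(0, "GEF", 5)
  traj_ev <- simulate_crn(net, x0, grid, events = list(ev))
  x0b <- x0; x0b["GEF"] <- x0b["GEF"] + 5
  traj_direct <- simulate_crn(net, x0b, grid)
  expect_equal(traj_ev$states, traj_direct$states, tolerance = 1e-10)
})

test_that("mid-course events split the integration and add the bolus", {
  net <- fixture_pair(k_f = 1, k_r = 1, total = 2)
  grid <- c(0, 5, 10, 15, 20)
  ev <- administration_event(10, "A", 4)
  traj <- simulate_crn(net, c(2, 0), grid, events = list(ev))
  # totals: 2 before the event, 6 after
  totals <- rowSums(traj$states)
  expect_equal(totals[1:3], rep(2, 3), tolerance = 1e-7)
  expect_equal(totals[4:5], rep(6, 2), tolerance = 1e-7)
  # long after the event the 1:1 equilibrium re-establishes at 3/3
  traj2 <- simulate_crn(net, c(2, 0), c(0, 10, 100), events = list(ev))
  expect_equal(unname(traj2$states[3, ]), c(3, 3), tolerance = 1e-5)
})

test_that("trajectory CSV export carries events and a time_s header", {
  net <- fixture_pair()
  traj <- simulate_crn(net, c(3, 0), c(0, 1, 2),
                       events = list(administration_event(1, "A", 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# event")
  expect_match(lines[2], "time_s")
  df <- utils::read.csv(f, comment.char = "#")
  expect_identical(nrow(df), 3L)
})

test_that("simulate_to_equilibrium reaches the closed-form pair equilibrium", {
  eq <- simulate_to_equilibrium(fixture_pair(2, 1, 3), c(3, 0))
  expect_true(eq$converged)
  expect_equal(unname(eq$x_e), c(1, 2), tolerance = 1e-8)
})

test_that("the toy cascade physiological equilibrium is strictly positive", {
  net <- build_mapk_toy()
  eq <- simulate_to_equilibrium(net, initial_state(net))
  expect_true(eq$converged)
  expect_true(all(eq$x_e > 0))
})

test_that("non-convergence within the horizon is reported, not hidden", {
  # a pure source grows without bound: no equilibrium exists
  net <- crn_network(
    list(crn_species("A", 0)),
    list(crn_reaction("src", stats::setNames(numeric(0), character(0)),
                      c(A = 1), 1)))
  expect_warning(eq <- simulate_to_equilibrium(net, 0, max_horizon_s = 1e4),
                 "horizon")
  expect_false(eq$converged)
})
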