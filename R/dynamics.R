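#' Mass-action reaction fluxes
#'
#' Under mass-action kinetics the flux of reaction j is
#' \eqn{v_j = k_j \prod_i x_i^{a_{ij}}} with \eqn{a_{ij}} the reactant
#' coefficient of species i; a zeroth-order reaction has flux \eqn{k_j}.
#'
#' @param net A `crn_network`.
#' @param x Numeric state vector (nM), length n, non-negative.
#' @return Named numeric vector of length r (nM/s).
#' @export
reaction_fluxes <- function(net, x) {
  x <- .check_state(net, x)
  v <- vapply(net$reactions, function(rx) {
    if (length(rx$reactants) == 0L) return(rx$k)
    rx$k * prod(x[names(rx$reactants)]^rx$reactants)
  }, numeric(1))
  stats::setNames(v, vapply(net$reactions, `[[`, character(1), "id"))
}

#' Right-hand side of the mass-action ODE system
#'
#' The concentration dynamics are `dx/dt = S v(x, k)`.  Because every
#' conservation row y satisfies \eqn{y^T S = 0}, the returned derivative is
#' exactly annihilated by the conservation basis.
#'
#' @inheritParams reaction_fluxes
#' @return Named numeric vector of length n (nM/s).
#' @export
ode_rhs <- function(net, x) {
  as.vector(net$S %*% reaction_fluxes(net, x)) |>
    stats::setNames(species_names(net))
}

#' Analytic Jacobian of the ODE right-hand side
#'
#' \eqn{\partial v_j / \partial x_i = k_j a_{ij} x_i^{a_{ij}-1}
#' \prod_{l \ne i} x_l^{a_{lj}}}, propagated through S.  Used by the stiff
#' integrator and by the Newton equilibrium solver.
#'
#' @inheritParams reaction_fluxes
#' @return An n x n numeric matrix.
#' @export
crn_jacobian <- function(net, x) {
  x <- .check_state(net, x)
  n <- length(x); r <- length(net$reactions)
  sp <- species_names(net)
  dv <- matrix(0, r, n, dimnames = list(NULL, sp))
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    rn <- names(rx$reactants)
    for (i in seq_along(rn)) {
      a <- rx$reactants[i]
      xi <- x[rn[i]]
      term <- rx$k * a * (if (a == 1) 1 else xi^(a - 1))
      if (length(rn) > 1L)
        term <- term * prod(x[rn[-i]]^rx$reactants[-i])
      dv[j, rn[i]] <- dv[j, rn[i]] + term
    }
  }
  J <- net$S %*% dv
  dimnames(J) <- list(sp, sp)
  J
}

.check_state <- function(net, x) {
  sp <- species_names(net)
  if (length(x) != length(sp))
    stop("state vector has length ", length(x), ", expected ", length(sp),
         call. = FALSE)
  if (any(x < 0))
    stop("negative concentration in state vector", call. = FALSE)
  stats::setNames(as.numeric(x), sp)
}

#' Create a timed administration event
#'
#' A bolus: at `time` the named species' concentration is instantaneously
#' incremented by `amount`.  Used to model drug administration some time
#' after the start of a simulation.
#'
#' @param time Seconds, >= 0.
#' @param species Species name.
#' @param amount nM, > 0.
#' @return A list of class `crn_event`.
#' @export
administration_event <- function(time, species, amount) {
  stopifnot(time >= 0, is.character(species), amount > 0)
  structure(list(time = time, species = species, amount = amount),
            class = "crn_event")
}

#' Integrate the mass-action dynamics
#'
#' Stiff-capable integration (lsoda with the analytic Jacobian) of
#' `dx/dt = S v(x, k)` over a time grid, with optional timed administration
#' events: at each event time integration halts, the named species is
#' incremented, and integration resumes.  Between events the conserved
#' moiety totals are preserved to solver tolerance; events change them by
#' design.
#'
#' @param net A `crn_network`.
#' @param x0 Initial state (nM), length n, non-negative.
#' @param t_grid Strictly increasing time grid, seconds, starting at the
#'   initial time.
#' @param events List of [administration_event()] objects, sorted by time.
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @return A list of class `crn_trajectory` with fields `times`, `states`
#'   (length(times) x n matrix, clipped to be non-negative), and `events`.
#' @export
simulate_crn <- function(net, x0, t_grid, events = list(),
                     rtol = 1e-8, atol = 1e-12) {
  x0 <- .check_state(net, x0)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points",
         call. = FALSE)
  if (inherits(events, "crn_event")) events <- list(events)
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  if (is.unsorted(ev_times)) stop("events must be sorted by time", call. = FALSE)
  sp <- species_names(net)
  for (ev in events)
    if (!ev$species %in% sp)
      stop("event species '", ev$species, "' not in network", call. = FALSE)

  # immediate events fold into the initial state
  while (length(events) && events[[1]]$time <= t_grid[1]) {
    x0[events[[1]]$species] <- x0[events[[1]]$species] + events[[1]]$amount
    events <- events[-1]
  }
  ev_times <- vapply(events, `[[`, numeric(1), "time")

  bounds <- unique(c(t_grid[1], ev_times[ev_times < max(t_grid)], max(t_grid)))
  bounds <- sort(bounds)
  times_out <- numeric(0)
  states_out <- NULL
  x <- x0
  for (s in seq_len(length(bounds) - 1L)) {
    t_a <- bounds[s]; t_b <- bounds[s + 1L]
    seg <- unique(sort(c(t_a, t_grid[t_grid > t_a & t_grid < t_b], t_b)))
    sol <- .integrate_segment(net, x, seg, rtol, atol)
    x <- stats::setNames(sol[nrow(sol), -1], sp)
    keep <- sol[, 1] %in% t_grid & !(sol[, 1] %in% times_out)
    if (any(keep)) {
      times_out <- c(times_out, sol[keep, 1])
      states_out <- rbind(states_out, sol[keep, -1, drop = FALSE])
    }
    for (ev in events)
      if (ev$time == t_b) x[ev$species] <- x[ev$species] + ev$amount
  }
  # the final grid point always belongs to the output
  if (!max(t_grid) %in% times_out) {
    times_out <- c(times_out, max(t_grid))
    states_out <- rbind(states_out, x)
  }
  states_out <- pmax(states_out, 0)
  colnames(states_out) <- sp
  structure(list(times = times_out, states = states_out, events = events),
            class = "crn_trajectory")
}

.integrate_segment <- function(net, x, times, rtol, atol) {
  x <- stats::setNames(as.numeric(x), species_names(net))
  if (length(times) == 1L) return(matrix(c(times, x), 1))
  func <- function(t, y, parms) list(as.vector(net$S %*% .fluxes_fast(net, pmax(y, 0))))
  jac <- function(t, y, parms) crn_jacobian(net, pmax(y, 0))
  out <- deSolve::lsoda(y = x, times = times, func = func, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (max(out[, 1]) < max(times))
    stop("integration failed at t = ", max(out[, 1]), " s", call. = FALSE)
  unname(as.matrix(out))
}

# reaction_fluxes without the state checks, for inner integrator loops
.fluxes_fast <- function(net, x) {
  vapply(net$reactions, function(rx) {
    if (length(rx$reactants) == 0L) return(rx$k)
    rx$k * prod(x[names(rx$reactants)]^rx$reactants)
  }, numeric(1))
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points,",
      ncol(x$states), "species, t in [", min(x$times), ",", max(x$times), "] s\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes a header `time_s` plus one column per species; administration
#' events are echoed as comment lines.
#'
#' @param traj A `crn_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ev in traj$events)
    writeLines(sprintf("# event: t=%gs +%g nM %s", ev$time, ev$amount,
                       ev$species), con)
  df <- data.frame(time_s = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Equilibrium by long-horizon integration
#'
#' Integrates the dynamics over a geometrically growing horizon until the
#' scaled right-hand-side residual
#' \eqn{\|S v(x)\|_\infty < tol_{eq} (1 + \|x\|_\infty)} holds at two
#' successive checkpoints (horizon doubling), guarding against declaring a
#' slow transient an equilibrium.
#'
#' @param net A `crn_network`.
#' @param x0 Initial state, non-negative.
#' @param tol_eq Residual tolerance (default 1e-10).
#' @param max_horizon_s Give up beyond this horizon (default 1e9 s).
#' @param rtol,atol Integrator tolerances.
#' @return A list of class `crn_equilibrium`: fields `x_e`, `residual`
#'   (2-norm of S v), `iterations` (number of horizon doublings), `method`
#'   (`"ode"`), `converged`, and `horizon_s`.
#' @seealso [solve_equilibrium()] for the direct root-finding route.
#' @export
simulate_to_equilibrium <- function(net, x0, tol_eq = 1e-10,
                                    max_horizon_s = 1e9,
                                    rtol = 1e-8, atol = 1e-12) {
  x <- .check_state(net, x0)
  horizon <- 100
  elapsed <- 0
  hits <- 0L
  iters <- 0L
  repeat {
    sol <- .integrate_segment(net, x, c(0, horizon), rtol, atol)
    x <- pmax(sol[nrow(sol), -1], 0)
    elapsed <- elapsed + horizon
    iters <- iters + 1L
    res <- max(abs(ode_rhs(net, x)))
    if (res < tol_eq * (1 + max(abs(x)))) hits <- hits + 1L else hits <- 0L
    if (hits >= 2L) break
    if (elapsed >= max_horizon_s) {
      warning("no equilibrium within horizon ", max_horizon_s,
              " s (residual ", signif(res, 3), "); possible oscillation or slow mode",
              call. = FALSE)
      return(structure(list(x_e = stats::setNames(x, species_names(net)),
                            residual = sqrt(sum(ode_rhs(net, x)^2)),
                            iterations = iters, method = "ode",
                            converged = FALSE, horizon_s = elapsed),
                       class = "crn_equilibrium"))
    }
    horizon <- horizon * 2
  }
  structure(list(x_e = stats::setNames(x, species_names(net)),
                 residual = sqrt(sum(ode_rhs(net, x)^2)),
                 iterations = iters, method = "ode",
                 converged = TRUE, horizon_s = elapsed),
            class = "crn_equilibrium")
}

#' @export
print.crn_equilibrium <- function(x, ...) {
  cat("Equilibrium (", x$method, "): residual ", signif(x$residual, 3),
      if (isTRUE(x$converged)) ", converged" else ", NOT converged", "\n",
      sep = "")
  invisible(x)
}
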