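# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own code paths: fixed-step RK4 instead of lsoda, finite
# differences instead of the analytic Jacobian, support enumeration instead
# of double description.

fixture_pair <- function(k_f = 2, k_r = 1, total = 3)
  build_reversible_pair(k_f, k_r, total)

# E + S <-> ES -> E + P, the classic enzymatic cycle with p = 2 laws
fixture_enzyme <- function() {
  crn_network(
    list(crn_species("E", 2, composition = "E"),
         crn_species("S", 5, composition = "S"),
         crn_species("ES", 0, composition = c("E", "S")),
         crn_species("P", 0, composition = "S")),
    list(crn_reaction("bind", c(E = 1, S = 1), c(ES = 1), 1e-3),
         crn_reaction("unbind", c(ES = 1), c(E = 1, S = 1), 1e-2),
         crn_reaction("cat", c(ES = 1), c(E = 1, P = 1), 0.1)))
}

# open system with a zeroth-order source and first-order sink: no moiety
fixture_open <- function() {
  crn_network(
    list(crn_species("A", 0)),
    list(crn_reaction("source", stats::setNames(numeric(0), character(0)),
                      c(A = 1), 2),
         crn_reaction("sink", c(A = 1),
                      stats::setNames(numeric(0), character(0)), 0.5)))
}

# purely first-order reversible chain A <-> B <-> C: linear dynamics
fixture_linear_chain <- function() {
  crn_network(
    list(crn_species("A", 10), crn_species("B", 0), crn_species("C", 1)),
    list(crn_reaction("ab", c(A = 1), c(B = 1), 0.3),
         crn_reaction("ba", c(B = 1), c(A = 1), 0.1),
         crn_reaction("bc", c(B = 1), c(C = 1), 0.05),
         crn_reaction("cb", c(C = 1), c(B = 1), 0.2)))
}

# fixed-step classical RK4, an integrator independent of deSolve
oracle_rk4 <- function(net, x0, t_end, n_steps) {
  h <- t_end / n_steps
  x <- stats::setNames(as.numeric(x0), species_names(net))
  f <- function(y) ode_rhs(net, pmax(y, 0))
  for (i in seq_len(n_steps)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# central-difference Jacobian of the ODE right-hand side
oracle_fd_jacobian <- function(net, x, h_rel = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- max(xm[i] - h, 0)
    J[, i] <- (ode_rhs(net, xp) - ode_rhs(net, xm)) / (xp[i] - xm[i])
  }
  J
}

# brute-force extreme rays of {y >= 0 : t(S) y = 0} for n <= 6 species:
# enumerate candidate supports, keep those carrying a one-dimensional
# sign-constant null vector, then discard non-minimal supports
oracle_semipositive_rays <- function(S) {
  n <- nrow(S)
  stopifnot(n <= 6)
  rays <- list()
  for (mask in 1:(2^n - 1)) {
    J <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    A <- t(S[J, , drop = FALSE])            # r x |J|
    sv <- svd(A, nu = 0, nv = length(J))
    tolr <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
    rank <- sum(sv$d >= tolr)
    if (length(J) - rank != 1) next
    v <- sv$v[, length(J)]
    if (any(abs(v) < 1e-10)) next           # support not exact
    if (all(v > 0) || all(v < 0)) {
      y <- numeric(n); y[J] <- abs(v) / min(abs(v))
      rays <- c(rays, list(y))
    }
  }
  if (!length(rays)) return(matrix(0, 0, n))
  R <- do.call(rbind, rays)
  supp <- lapply(seq_len(nrow(R)), function(i) which(R[i, ] != 0))
  keep <- vapply(seq_along(supp), function(i)
    !any(vapply(seq_along(supp), function(j)
      j != i && all(supp[[j]] %in% supp[[i]]) &&
        length(supp[[j]]) < length(supp[[i]]), logical(1))), logical(1))
  R[keep, , drop = FALSE]
}

# is y a non-negative combination of the rows of R?
in_cone <- function(y, R, tol = 1e-8) {
  if (nrow(R) == 0) return(max(abs(y)) < tol)
  fit <- pracma::lsqnonneg(t(R), as.numeric(y))
  sqrt(sum((as.numeric(y) - t(R) %*% fit$x)^2)) < tol * (1 + sqrt(sum(y^2)))
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

solved_pair <- function(net, seed = 1) {
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  list(net = net, basis = basis, x0 = x0,
       eq = solve_equilibrium(net, basis, x0, seed = seed))
}
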