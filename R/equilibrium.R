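#' Choose which kinetic equations to replace by conservation laws
#'
#' At an equilibrium on the compatibility class of `x0` the stacked system
#' \eqn{F(x) = 0} combines the kinetic conditions `S v(x) = 0` with the
#' class constraints `N x = N x0`.  Since the p conservation rows make p of
#' the n kinetic equations redundant, those are deleted to obtain a square
#' n x n system.  The deleted rows are the elemental-species rows: each is
#' a combination (through its conservation row) of the other kinetic
#' equations of its moiety.
#'
#' @param net A `crn_network`.
#' @param basis A weakly elemented `crn_conservation` (or p = 0).
#' @return Sorted integer vector of p species row indices to delete
#'   (`integer(0)` when p = 0).
#' @export
row_reduction_choice <- function(net, basis) {
  p <- nrow(basis$N)
  if (p == 0L) return(integer(0))
  if (!isTRUE(basis$weakly_elemented))
    stop("conservation basis must be weakly elemented", call. = FALSE)
  sort(basis$elemental_index)
}

#' Equilibrium by constrained root finding
#'
#' Computes the equilibrium of the mass-action dynamics on the
#' stoichiometric compatibility class of `x0` directly, without time
#' integration, by solving \eqn{F(x) = 0} where F stacks the reduced
#' kinetic conditions (see [row_reduction_choice()]) and the class
#' constraints `N x = N x0`.  The scheme is a damped Newton iteration with
#' non-linear projection of every iterate onto the non-negative orthant;
#' when a projected Newton step fails to decrease \eqn{\tfrac12\|F\|^2}
#' sufficiently, a backtracking gradient-descent step on the same merit
#' function is taken instead.  On stagnation the solver restarts from a
#' seeded randomized point of the compatibility class, up to `restarts`
#' times.
#'
#' Mass-action networks of the kind modelled here are conjectured to hold a
#' unique globally asymptotically stable equilibrium per compatibility
#' class; the solver assumes (and the test-suite empirically checks, via
#' multi-start agreement and comparison with [simulate_to_equilibrium()])
#' uniqueness rather than proving it.
#'
#' @param net A `crn_network`.
#' @param basis A `crn_conservation` for `net`, weakly elemented or p = 0.
#' @param x0 Non-negative state fixing the compatibility class.
#' @param seed Integer seed for the randomized restarts.
#' @param tol Convergence tolerance on \eqn{\|F\|_2 / (1 + \|x\|_\infty)}
#'   (default 1e-10).
#' @param max_iter Iteration cap per start (default 200).
#' @param restarts Maximum number of randomized restarts (default 10).
#' @return A list of class `crn_equilibrium`: `x_e` (non-negative, named),
#'   `residual` (\eqn{\|F(x_e)\|_2}), `iterations`, `method` (`"nlpc"`),
#'   `converged`, `class_residual` (\eqn{\|N x_e - N x_0\|_\infty}).
#' @export
solve_equilibrium <- function(net, basis, x0, seed = 1L, tol = 1e-10,
                              max_iter = 200L, restarts = 10L) {
  x0 <- .check_state(net, x0)
  N <- basis$N
  p <- nrow(N)
  if (p > 0L && !isTRUE(basis$weakly_elemented))
    stop("conservation basis must be weakly elemented (or empty)", call. = FALSE)
  n <- length(x0)
  drop_rows <- row_reduction_choice(net, basis)
  keep <- setdiff(seq_len(n), drop_rows)
  b0 <- if (p > 0L) as.vector(N %*% x0) else numeric(0)

  Ffun <- function(x) c(as.vector(net$S %*% .fluxes_fast(net, x))[keep],
                        if (p > 0L) as.vector(N %*% x) - b0)
  Jfun <- function(x) rbind(crn_jacobian(net, x)[keep, , drop = FALSE],
                            if (p > 0L) N)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  best <- NULL
  total_iter <- 0L
  starts <- c(list(x0), lapply(seq_len(restarts), function(i)
    .random_class_point(x0, N, b0)))
  for (x_start in starts) {
    run <- .nlpc_run(x_start, Ffun, Jfun, tol, max_iter)
    total_iter <- total_iter + run$iterations
    if (is.null(best) || run$residual < best$residual) best <- run
    if (best$converged) break
  }
  x_e <- stats::setNames(best$x, species_names(net))
  if (best$converged && qr(Jfun(best$x))$rank < n)
    warning("reduced Jacobian is rank-deficient at the solution; ",
            "the equilibrium may not be isolated", call. = FALSE)
  if (!best$converged)
    warning("equilibrium solver did not converge; best residual ",
            signif(best$residual, 3), call. = FALSE)
  structure(list(x_e = x_e, residual = best$residual,
                 iterations = total_iter, method = "nlpc",
                 converged = best$converged,
                 class_residual = if (p > 0L)
                   max(abs(as.vector(N %*% x_e) - b0)) else 0),
            class = "crn_equilibrium")
}

# One damped projected-Newton run with gradient-descent fallback.
.nlpc_run <- function(x, Ffun, Jfun, tol, max_iter) {
  Fx <- Ffun(x)
  nf <- sqrt(sum(Fx^2))
  scale <- function(x) 1 + max(abs(x))
  for (it in seq_len(max_iter)) {
    if (nf <= tol * scale(x))
      return(list(x = x, residual = nf, iterations = it - 1L, converged = TRUE))
    J <- Jfun(x)
    dx <- tryCatch(solve(J, -Fx), error = function(e) .svd_solve(J, -Fx))
    moved <- FALSE
    t <- 1
    while (t >= 1e-10) {
      x_new <- pmax(x + t * dx, 0)
      F_new <- Ffun(x_new)
      nf_new <- sqrt(sum(F_new^2))
      if (nf_new <= (1 - 1e-4 * t) * nf) {
        x <- x_new; Fx <- F_new; nf <- nf_new; moved <- TRUE; break
      }
      t <- t / 2
    }
    if (!moved) {
      # gradient of 0.5||F||^2 with backtracking
      g <- as.vector(crossprod(J, Fx))
      gn2 <- sum(g^2)
      if (gn2 == 0) break
      s <- (0.5 * nf^2) / gn2
      repeat {
        x_new <- pmax(x - s * g, 0)
        F_new <- Ffun(x_new)
        nf_new <- sqrt(sum(F_new^2))
        if (nf_new < nf) { x <- x_new; Fx <- F_new; nf <- nf_new; moved <- TRUE; break }
        s <- s / 2
        if (s < 1e-14) break
      }
    }
    if (!moved) break  # stagnation: caller may restart
  }
  list(x = x, residual = nf, iterations = it,
       converged = nf <= tol * scale(x))
}

.svd_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  inv_d <- ifelse(sv$d > tol, 1 / sv$d, 0)
  as.vector(sv$v %*% (inv_d * crossprod(sv$u, b)))
}

# A random non-negative point on the compatibility class {x >= 0, Nx = b0}:
# draw a positive random state on the scale of x0, then alternate projection
# onto the affine class with clipping to the orthant.
.random_class_point <- function(x0, N, b0) {
  n <- length(x0)
  lvl <- mean(x0[x0 > 0])
  if (!is.finite(lvl) || lvl <= 0) lvl <- 1
  x <- stats::runif(n, 0, 2 * lvl)
  if (length(b0) == 0L) return(stats::setNames(x, names(x0)))
  NNt <- N %*% t(N)
  for (i in 1:100) {
    resid <- as.vector(N %*% x) - b0
    if (max(abs(resid)) <= 1e-12 * (1 + max(abs(b0)))) break
    x <- x - as.vector(t(N) %*% solve(NNt, resid))
    x <- pmax(x, 0)
  }
  stats::setNames(x, names(x0))
}
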