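#' Extract semi-positive conservation laws of a network
#'
#' A conservation law is a non-negative vector y with \eqn{S^T y = 0}: the
#' weighted total \eqn{y^T x(t)} is constant along every trajectory of the
#' mass-action dynamics.  For moiety-conserved signalling networks each law
#' corresponds to the total amount of one protein moiety across its free,
#' modified and complexed forms.  This function computes the extreme rays
#' of the polyhedral cone \eqn{\{y \ge 0 : S^T y = 0\}} by the
#' double-description method in exact integer arithmetic (incremental
#' insertion of the equality constraints with support-minimality pruning),
#' then returns a maximal linearly independent subset as the rows of N.
#'
#' If the network carries declared CONSERVATION rows (see
#' [load_network()]), those are verified (N S = 0 exactly, entries >= 0)
#' and used as-is instead of being re-derived.
#'
#' The basis is *weakly elemented* when one species per law can be singled
#' out that occurs in that law alone with unit weight, so that the
#' corresponding columns of N form a p x p identity.  The lowest admissible
#' species index is chosen per row, scanning rows in order.
#'
#' @param net A `crn_network`.
#' @return A list of class `crn_conservation` with fields `N` (p x n
#'   matrix, p may be 0), `elemental_index` (integer vector of length p, or
#'   `NA` entries where no elemental species exists), and
#'   `weakly_elemented` (logical).  A warning is raised when the left null
#'   space of S has dimension larger than p, i.e. contains directions with
#'   no semi-positive representative.
#' @export
find_conservation_laws <- function(net) {
  S <- net$S
  n <- nrow(S)
  decl <- attr(net, "declared_conservation")
  if (!is.null(decl)) {
    N <- matrix(0, length(decl), n, dimnames = list(names(decl), rownames(S)))
    for (i in seq_along(decl)) {
      row <- decl[[i]]
      unknown <- setdiff(names(row), rownames(S))
      if (length(unknown))
        stop("declared conservation '", names(decl)[i], "' names unknown species ",
             paste(unknown, collapse = ", "), call. = FALSE)
      N[i, names(row)] <- row
    }
    if (any(N < 0))
      stop("declared conservation rows must be semi-positive", call. = FALSE)
    if (max(abs(N %*% S)) != 0)
      stop("declared conservation rows do not annihilate S", call. = FALSE)
    if (qr(t(N))$rank < nrow(N))
      stop("declared conservation rows are linearly dependent", call. = FALSE)
    return(.finish_basis(N, S))
  }

  rays <- .semipositive_extreme_rays(S)
  p_max <- n - qr(S)$rank
  if (nrow(rays) == 0L) {
    N <- matrix(0, 0, n, dimnames = list(NULL, rownames(S)))
    if (p_max > 0L)
      warning("left null space has dimension ", p_max,
              " but no semi-positive direction", call. = FALSE)
    return(.finish_basis(N, S))
  }
  # deterministic order: small supports first, then lexicographic
  supp <- rowSums(rays != 0)
  ord <- order(supp, apply(rays, 1, function(r) paste(r, collapse = ",")))
  rays <- rays[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(rays))) {
    cand <- rays[c(keep, i), , drop = FALSE]
    if (qr(t(cand))$rank == length(keep) + 1L) keep <- c(keep, i)
  }
  N <- rays[keep, , drop = FALSE]
  colnames(N) <- rownames(S)
  rownames(N) <- NULL
  if (nrow(N) < p_max)
    warning("left null space has dimension ", p_max, " but only ", nrow(N),
            " independent semi-positive direction(s)", call. = FALSE)
  .finish_basis(N, S)
}

# Extreme rays of {y >= 0 : t(S) %*% y = 0} by incremental double
# description.  Integer arithmetic throughout (entries stay exact in
# doubles; every ray is reduced by its gcd).  For cones of this form the
# extreme rays are exactly the support-minimal elements, which justifies
# the superset pruning after each constraint.
.semipositive_extreme_rays <- function(S) {
  n <- nrow(S)
  rays <- diag(n)
  for (j in seq_len(ncol(S))) {
    a <- S[, j]
    d <- as.vector(rays %*% a)
    zero <- rays[d == 0, , drop = FALSE]
    pos <- which(d > 0); neg <- which(d < 0)
    combo <- list()
    for (ip in pos) for (im in neg) {
      r <- d[ip] * rays[im, ] - d[im] * rays[ip, ]
      g <- .vec_gcd(r)
      if (g > 0) r <- r / g
      combo <- c(combo, list(r))
    }
    cand <- rbind(zero, do.call(rbind, combo))
    if (is.null(cand) || nrow(cand) == 0L) {
      rays <- matrix(0, 0, n); break
    }
    cand <- unique(cand)
    supports <- lapply(seq_len(nrow(cand)), function(i) which(cand[i, ] != 0))
    sizes <- lengths(supports)
    ord <- order(sizes)
    keep <- logical(nrow(cand))
    kept_supports <- list()
    for (i in ord) {
      s <- supports[[i]]
      minimal <- !any(vapply(kept_supports, function(ks)
        all(ks %in% s) && length(ks) < length(s), logical(1)))
      if (minimal) { keep[i] <- TRUE; kept_supports <- c(kept_supports, list(s)) }
    }
    rays <- cand[keep, , drop = FALSE]
  }
  rays
}

.vec_gcd <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(0)
  g <- v[1]
  for (x in v[-1]) {
    a <- g; b <- x
    while (b > 0) { t <- a %% b; a <- b; b <- t }
    g <- a
    if (g == 1) break
  }
  g
}

# Attach the weakly-elemented flag and elemental indices to a verified N.
.finish_basis <- function(N, S) {
  p <- nrow(N)
  elemental <- rep(NA_integer_, p)
  if (p > 0L) {
    taken <- integer(0)
    for (i in seq_len(p)) {
      others <- if (p > 1L) colSums(N[-i, , drop = FALSE] != 0) else rep(0, ncol(N))
      ok <- which(N[i, ] == 1 & others == 0)
      ok <- setdiff(ok, taken)
      if (length(ok)) { elemental[i] <- ok[1]; taken <- c(taken, ok[1]) }
    }
  }
  structure(list(N = N, elemental_index = elemental,
                 weakly_elemented = p > 0L && !anyNA(elemental)),
            class = "crn_conservation")
}

#' @export
print.crn_conservation <- function(x, ...) {
  cat("Conservation basis: p =", nrow(x$N),
      if (isTRUE(x$weakly_elemented)) "(weakly elemented)" else "", "\n")
  invisible(x)
}

#' Residual of a state against a stoichiometric compatibility class
#'
#' The compatibility class of `x0` is the affine set
#' \eqn{\{x : N x = N x_0\}}; trajectories and equilibria of the
#' mass-action dynamics stay on the class of their initial state.
#'
#' @param basis A `crn_conservation`.
#' @param x,x0 Numeric state vectors of length n.
#' @return Numeric vector of length p: `N x - N x0` (zero iff `x` lies on
#'   the class of `x0`).
#' @export
compatibility_residual <- function(basis, x, x0) {
  N <- basis$N
  if (length(x) != ncol(N) || length(x0) != ncol(N))
    stop("state vector length does not match the conservation basis",
         call. = FALSE)
  as.vector(N %*% x - N %*% x0)
}
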