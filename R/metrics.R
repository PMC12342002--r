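#' Relative-difference effect profile
#'
#' Coordinate-wise relative difference of a comparison equilibrium against
#' the physiological one, \eqn{\delta_i = (\tilde x_i - x_i) / x_i} for a
#' mutated equilibrium or \eqn{d_i = (x^d_i - x_i) / x_i} for a drug-loaded
#' one.  Each entry shares the sign of the raw difference; a value of -1
#' means the species is completely absent in the comparison state (its
#' function is stopped).  The profile is only defined when every reference
#' concentration is strictly positive.
#'
#' @param x_comp Comparison equilibrium (mutated or drug-loaded), length n.
#' @param x_phys Physiological equilibrium, strictly positive, length n.
#' @param role `"mutation_delta"` or `"drug_difference"` (annotation only).
#' @return A list of class `crn_effect_profile` with fields `values` (named
#'   length-n vector) and `role`.
#' @export
delta_profile <- function(x_comp, x_phys, role = c("mutation_delta",
                                                   "drug_difference")) {
  role <- match.arg(role)
  if (length(x_comp) != length(x_phys))
    stop("profile vectors must have equal length", call. = FALSE)
  if (any(x_phys <= 0))
    stop("ZERO_REFERENCE: physiological equilibrium must be strictly ",
         "positive in every coordinate", call. = FALSE)
  values <- (x_comp - x_phys) / x_phys
  if (!is.null(names(x_phys))) names(values) <- names(x_phys)
  structure(list(values = values, role = role), class = "crn_effect_profile")
}

#' @export
print.crn_effect_profile <- function(x, ...) {
  cat("Effect profile (", x$role, "), n = ", length(x$values),
      ", range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Species most affected by a perturbation
#'
#' Ranks species by the absolute concentration difference between the
#' comparison and physiological equilibria (nM, descending; ties keep the
#' input species order) and reports the relative difference alongside.
#'
#' @inheritParams delta_profile
#' @param m Number of rows to return.
#' @return Data frame with columns `species`, `abs_diff_nM`, `delta`.
#' @export
top_variations <- function(x_comp, x_phys, m = 10L) {
  prof <- delta_profile(x_comp, x_phys)
  adiff <- abs(x_comp - x_phys)
  ord <- order(-adiff)   # stable: ties keep species order
  ord <- ord[seq_len(min(m, length(ord)))]
  nms <- if (!is.null(names(x_phys))) names(x_phys) else
    paste0("species_", seq_along(x_phys))
  data.frame(species = nms[ord], abs_diff_nM = unname(adiff[ord]),
             delta = unname(prof$values[ord]), stringsAsFactors = FALSE)
}

#' Modified geometric mean of an effect profile
#'
#' \eqn{G(d) = (\prod_{i=1}^n (|d_i| + 10^{-6}))^{1/n} - 10^{-6}},
#' evaluated in log space.  The \eqn{10^{-6}} offset admits zero entries;
#' absolute values make the geometric mean well defined for profiles of
#' mixed sign, and reflect G's role as a distance of the perturbed
#' equilibrium from the physiological one.  G = 0 iff every entry is zero,
#' and G is invariant to permutations of the profile.
#'
#' @param profile A `crn_effect_profile` or bare numeric vector.
#' @return Scalar G >= 0 (up to the offset floor).
#' @export
geometric_index <- function(profile) {
  d <- if (inherits(profile, "crn_effect_profile")) profile$values else profile
  if (length(d) == 0L) stop("empty profile", call. = FALSE)
  exp(mean(log(abs(d) + 1e-6))) - 1e-6
}

#' One-dimensional drug dose scan
#'
#' For each concentration on the grid: augment the mutated network with the
#' drug at that initial concentration, compute the drug-loaded equilibrium
#' from the mutated equilibrium, form the d-profile against the
#' physiological equilibrium restricted to the original (non-drug) species,
#' and summarise it by [geometric_index()].  The reported optimum is the
#' grid argmin, with ties broken toward the smallest dose.  Solver failures
#' at individual doses are recorded and the scan continues.
#'
#' @param net_mut Mutated `crn_network`.
#' @param x_tilde_e Mutated equilibrium of `net_mut`.
#' @param x_phys_e Physiological equilibrium (strictly positive) on the
#'   same species.
#' @param drug A [drug_spec()]; its `c0` is overridden by the grid.
#' @param grid Non-empty vector of concentrations, nM, >= 0.
#' @param method,seed Passed to [drug_loaded_equilibrium()].
#' @return A list of class `crn_dose_scan`: `grid1`, `G_values`, `argmin`
#'   (dose), `G_min`, `profiles_at` (list of d-vectors per dose), and
#'   `failures` (character).
#' @export
dose_scan_1d <- function(net_mut, x_tilde_e, x_phys_e, drug, grid,
                         method = "nlpc", seed = 1L) {
  stopifnot(length(grid) >= 1L, all(grid >= 0))
  grid <- as.numeric(grid)
  orig <- species_names(net_mut)
  G <- rep(NA_real_, length(grid))
  profiles <- vector("list", length(grid))
  failures <- character(0)
  for (i in seq_along(grid)) {
    res <- tryCatch({
      spec <- drug; spec$c0 <- grid[i]; spec$schedule_time <- 0
      eq <- drug_loaded_equilibrium(net_mut, x_tilde_e, spec,
                                    method = method, seed = seed)
      prof <- delta_profile(eq$x_e[orig], x_phys_e, role = "drug_difference")
      list(G = geometric_index(prof), prof = prof$values)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("c=", grid[i], ": ", conditionMessage(res)))
    } else {
      G[i] <- res$G
      profiles[[i]] <- res$prof
    }
  }
  ok <- which(!is.na(G))
  if (!length(ok)) stop("dose scan failed at every grid point", call. = FALSE)
  best <- ok[order(G[ok], grid[ok])][1]
  structure(list(grid1 = grid, grid2 = NULL, G_values = G,
                 argmin = grid[best], G_min = G[best],
                 profiles_at = stats::setNames(profiles, grid),
                 failures = failures),
            class = "crn_dose_scan")
}

#' Two-dimensional dose scan for a drug combination
#'
#' As [dose_scan_1d()], but both drugs are added to one augmented network
#' and G is evaluated over the product grid.  The argmin uses lexicographic
#' smallest-dose tie-breaking (first axis, then second).
#'
#' @inheritParams dose_scan_1d
#' @param drugA,drugB [drug_spec()]s; `c0` overridden by the grids.
#' @param gridA,gridB Concentration grids (nM) for drugA (rows) and drugB
#'   (columns).
#' @return A `crn_dose_scan` with `grid1 = gridA`, `grid2 = gridB`,
#'   matrix `G_values`, and `argmin = c(cA, cB)`.
#' @export
dose_scan_2d <- function(net_mut, x_tilde_e, x_phys_e, drugA, drugB,
                         gridA, gridB, method = "nlpc", seed = 1L) {
  stopifnot(length(gridA) >= 1L, length(gridB) >= 1L,
            all(gridA >= 0), all(gridB >= 0))
  orig <- species_names(net_mut)
  G <- matrix(NA_real_, length(gridA), length(gridB),
              dimnames = list(gridA, gridB))
  failures <- character(0)
  for (i in seq_along(gridA)) for (j in seq_along(gridB)) {
    res <- tryCatch({
      sa <- drugA; sa$c0 <- gridA[i]; sa$schedule_time <- 0
      sb <- drugB; sb$c0 <- gridB[j]; sb$schedule_time <- 0
      eq <- drug_loaded_equilibrium(net_mut, x_tilde_e, list(sa, sb),
                                    method = method, seed = seed)
      prof <- delta_profile(eq$x_e[orig], x_phys_e, role = "drug_difference")
      geometric_index(prof)
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures <- c(failures, paste0("(", gridA[i], ",", gridB[j], "): ",
                                     conditionMessage(res)))
    else G[i, j] <- res
  }
  ok <- which(!is.na(G), arr.ind = TRUE)
  if (!nrow(ok)) stop("dose scan failed at every grid point", call. = FALSE)
  vals <- G[ok]
  best <- ok[order(vals, gridA[ok[, 1]], gridB[ok[, 2]]), , drop = FALSE][1, ]
  structure(list(grid1 = gridA, grid2 = gridB, G_values = G,
                 argmin = c(gridA[best[1]], gridB[best[2]]),
                 G_min = G[best[1], best[2]],
                 profiles_at = NULL, failures = failures),
            class = "crn_dose_scan")
}

#' @export
print.crn_dose_scan <- function(x, ...) {
  cat("Dose scan: argmin =", paste(x$argmin, collapse = ", "),
      "nM, G_min =", signif(x$G_min, 5), "\n")
  invisible(x)
}

#' Activated fraction of an elemental conserved variable
#'
#' For a moiety whose conservation row defines a constant total (e.g. total
#' ERK across free, phosphorylated and complexed forms), the activated
#' fraction at time t is the concentration of the chosen active species
#' divided by the moiety total of the trajectory's initial state.  Values
#' lie in \[0, 1\] up to solver tolerance.
#'
#' @param traj A `crn_trajectory`.
#' @param active_species Name of the active form (e.g. the doubly
#'   phosphorylated species).
#' @param basis A `crn_conservation` for the simulated network.
#' @param moiety Name of the elemental species identifying the moiety.
#' @return Numeric vector along `traj$times`.
#' @export
activated_fraction <- function(traj, active_species, basis, moiety) {
  sp <- colnames(traj$states)
  if (!active_species %in% sp)
    stop("unknown active species '", active_species, "'", call. = FALSE)
  idx <- match(moiety, sp)
  row <- which(basis$elemental_index == idx)
  if (!length(row))
    stop("'", moiety, "' is not an elemental conserved variable", call. = FALSE)
  total <- sum(basis$N[row, ] * traj$states[1, ])
  if (total <= 0) stop("zero moiety total", call. = FALSE)
  unname(traj$states[, active_species] / total)
}
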