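#' @keywords internal
"_PACKAGE"

#' Create a chemical species
#'
#' A species is identified by a unique name, carries an initial (reference)
#' concentration in nM, and may be annotated with the multiset of base
#' proteins it contains.  The composition annotation is what makes
#' loss-of-function projection possible: zeroing a protein must also zero
#' every complex that contains it.
#'
#' @param name Unique identifier string.
#' @param x0 Initial concentration, nM, non-negative.
#' @param composition Optional character vector of base-protein names
#'   (repeats allowed for homodimers); `NULL` when unknown.
#' @param phospho_state Optional free-form annotation (e.g. `"pp"`).
#' @return A list of class `crn_species`.
#' @export
crn_species <- function(name, x0, composition = NULL, phospho_state = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  x0 <- as.numeric(x0)
  if (!is.finite(x0) || x0 < 0)
    stop("species '", name, "': x0 must be finite and >= 0", call. = FALSE)
  if (!is.null(composition)) {
    composition <- as.character(composition)
    if (length(composition) == 0L)
      stop("species '", name, "': composition, when given, must be non-empty",
           call. = FALSE)
  }
  structure(list(name = name, x0 = x0, composition = composition,
                 phospho_state = phospho_state),
            class = "crn_species")
}

#' Create a mass-action reaction
#'
#' Reactants and products are named integer vectors mapping species name to
#' a positive stoichiometric coefficient.  An empty side (`character(0)`
#' names, written `0` in the interchange format) encodes a zeroth-order
#' source or a degradation sink.  The rate constant `k` has units
#' nM^(1-order) s^-1 where order is the sum of reactant coefficients.
#'
#' @param id Unique identifier string.
#' @param reactants,products Named numeric vectors of positive integer
#'   coefficients; names are species names.  May be empty, not both.
#' @param k Rate constant, strictly positive.
#' @param tags Character vector of tags; the recognised dialect is
#'   `"deactivation:<GENE>"`, `"drug:<NAME>"`, `"degradation"`.
#' @return A list of class `crn_reaction`.
#' @export
crn_reaction <- function(id, reactants, products, k, tags = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  chk_side <- function(side, what) {
    if (length(side) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(side)) || any(!nzchar(names(side))))
      stop("reaction '", id, "': ", what, " must be a named vector", call. = FALSE)
    side <- stats::setNames(as.numeric(side), names(side))
    if (any(side <= 0 | side != round(side)))
      stop("reaction '", id, "': ", what,
           " coefficients must be positive integers", call. = FALSE)
    side
  }
  reactants <- chk_side(reactants, "reactant")
  products  <- chk_side(products, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "': reactants and products cannot both be empty",
         call. = FALSE)
  k <- as.numeric(k)
  if (!is.finite(k) || k <= 0)
    stop("reaction '", id, "': rate constant must be > 0", call. = FALSE)
  structure(list(id = id, reactants = reactants, products = products,
                 k = k, tags = as.character(tags)),
            class = "crn_reaction")
}

#' Assemble a reaction network
#'
#' Builds the n x r stoichiometric matrix S, with
#' `S[i, j] = (product coefficient of species i in reaction j) -
#' (reactant coefficient)`, and checks referential integrity.  Under
#' mass-action kinetics the network induces the autonomous ODE system
#' `dx/dt = S v(x, k)`.
#'
#' @param species List of [crn_species()] objects (order is preserved and
#'   significant: it fixes the row order of S and of all state vectors).
#' @param reactions List of [crn_reaction()] objects (column order of S).
#' @return A list of class `crn_network` with elements `species`,
#'   `reactions`, and `S`.
#' @export
crn_network <- function(species, reactions) {
  stopifnot(length(species) >= 1L, length(reactions) >= 1L)
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species name(s): ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "),
         call. = FALSE)
  rx_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rx_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", "),
         call. = FALSE)
  n <- length(species); r <- length(reactions)
  S <- matrix(0, n, r, dimnames = list(sp_names, rx_ids))
  for (j in seq_len(r)) {
    rx <- reactions[[j]]
    for (side in c("reactants", "products")) {
      v <- rx[[side]]
      unknown <- setdiff(names(v), sp_names)
      if (length(unknown))
        stop("reaction '", rx$id, "': unknown species ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
  }
  structure(list(species = species, reactions = reactions, S = S),
            class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  cat("Mass-action reaction network:",
      length(x$species), "species,", length(x$reactions), "reactions\n")
  invisible(x)
}

#' Species names of a network
#' @param net A `crn_network`.
#' @return Character vector of length n, in state-vector order.
#' @export
species_names <- function(net) {
  vapply(net$species, `[[`, character(1), "name")
}

#' Initial concentrations of a network
#' @param net A `crn_network`.
#' @return Named numeric vector x0 (nM), in state-vector order.
#' @export
initial_state <- function(net) {
  stats::setNames(vapply(net$species, `[[`, numeric(1), "x0"),
                  species_names(net))
}

#' Rate constants of a network
#' @param net A `crn_network`.
#' @return Named numeric vector k, in reaction order.
#' @export
rate_constants <- function(net) {
  stats::setNames(vapply(net$reactions, `[[`, numeric(1), "k"),
                  vapply(net$reactions, `[[`, character(1), "id"))
}

#' Validate a network and report findings
#'
#' Structural checks beyond what the constructors enforce: dangling species
#' (appearing in no reaction), species with zero initial concentration that
#' are consumed but never produced, and malformed tags.  Errors mark a
#' network unusable for simulation; warnings are informative.
#'
#' @param net A `crn_network`.
#' @return A list of class `crn_validation` with data-frame fields
#'   `errors` and `warnings`, each with columns `code` and `message`.
#' @export
validate_network <- function(net) {
  errs <- list(); warns <- list()
  add <- function(lst, code, msg) c(lst, list(list(code = code, message = msg)))
  sp_names <- species_names(net)

  if (anyDuplicated(sp_names))
    errs <- add(errs, "DUPLICATE_SPECIES", "duplicate species names present")
  x0 <- initial_state(net)
  if (any(x0 < 0))
    errs <- add(errs, "NEGATIVE_X0",
                paste("negative x0:", paste(sp_names[x0 < 0], collapse = ", ")))

  touched <- character(0)
  for (rx in net$reactions) {
    touched <- c(touched, names(rx$reactants), names(rx$products))
    unknown <- setdiff(c(names(rx$reactants), names(rx$products)), sp_names)
    if (length(unknown))
      errs <- add(errs, "UNKNOWN_SPECIES",
                  paste0("reaction '", rx$id, "' references ",
                         paste(unknown, collapse = ", ")))
    if (rx$k <= 0)
      errs <- add(errs, "NONPOSITIVE_RATE",
                  paste0("reaction '", rx$id, "' has k <= 0"))
    bad_tags <- rx$tags[!grepl("^(deactivation:[^[:space:]]+|drug:[^[:space:]]+|degradation)$",
                               rx$tags)]
    if (length(bad_tags))
      warns <- add(warns, "UNRECOGNISED_TAG",
                   paste0("reaction '", rx$id, "': tag(s) ",
                          paste(bad_tags, collapse = ", "),
                          " outside the deactivation/drug/degradation dialect"))
  }
  dangling <- setdiff(sp_names, unique(touched))
  for (d in dangling)
    warns <- add(warns, "DANGLING_SPECIES",
                 paste0("species '", d, "' appears in no reaction"))

  produced <- unique(unlist(lapply(net$reactions, function(rx) names(rx$products))))
  for (i in seq_along(sp_names)) {
    nm <- sp_names[i]
    consumed <- any(vapply(net$reactions,
                           function(rx) nm %in% names(rx$reactants), logical(1)))
    if (x0[i] == 0 && consumed && !(nm %in% produced))
      warns <- add(warns, "UNREACHABLE_SPECIES",
                   paste0("species '", nm,
                          "' starts at 0, is consumed, and is never produced"))
  }

  as_df <- function(lst) {
    if (!length(lst)) return(data.frame(code = character(0), message = character(0),
                                        stringsAsFactors = FALSE))
    data.frame(code = vapply(lst, `[[`, character(1), "code"),
               message = vapply(lst, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  }
  structure(list(errors = as_df(errs), warnings = as_df(warns)),
            class = "crn_validation")
}

#' @export
print.crn_validation <- function(x, ...) {
  cat("Network validation:", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) print(x$errors)
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}

#' Tabulate species or reactions
#'
#' Flat data-frame views suitable for CSV export: one row per species
#' (name, x0, composition) or one row per reaction (id, equation, k, tags).
#'
#' @param net A `crn_network`.
#' @return A data frame.
#' @export
species_table <- function(net) {
  data.frame(
    name = species_names(net),
    x0 = unname(initial_state(net)),
    composition = vapply(net$species, function(s)
      if (is.null(s$composition)) "" else paste(s$composition, collapse = "+"),
      character(1)),
    stringsAsFactors = FALSE)
}

#' @rdname species_table
#' @export
reaction_table <- function(net) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("0")
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  data.frame(
    id = vapply(net$reactions, `[[`, character(1), "id"),
    equation = vapply(net$reactions, function(rx)
      paste(fmt_side(rx$reactants), "->", fmt_side(rx$products)), character(1)),
    k = vapply(net$reactions, `[[`, numeric(1), "k"),
    tags = vapply(net$reactions, function(rx)
      paste(rx$tags, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
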