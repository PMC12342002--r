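#' Specify a mutation
#'
#' Two mutation operators are supported.  A loss of function (LoF) projects
#' the initial state: the mutated protein and every compound containing it
#' are zeroed, shrinking the corresponding moiety totals (possibly to
#' zero).  A gain of function (GoF) edits the kinetics: every reaction
#' tagged `deactivation:<protein>` has its rate constant scaled by the
#' level \eqn{\lambda \in [0, 1]} — the fraction of the physiological
#' de-activation rate retained, so \eqn{\lambda = 0} is the complete
#' mutation (the tagged reactions are removed from the network) and
#' \eqn{\lambda = 1} is no mutation at all.
#'
#' @param protein Base-protein (gene) name.
#' @param kind `"LoF"` or `"GoF"`.
#' @param level GoF level \eqn{\lambda} in \[0, 1\]; ignored for LoF
#'   (always complete).
#' @return A list of class `crn_mutation`.
#' @export
mutation_spec <- function(protein, kind = c("GoF", "LoF"), level = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(protein), length(protein) == 1L)
  level <- as.numeric(level)
  if (level < 0 || level > 1) stop("level must be in [0, 1]", call. = FALSE)
  structure(list(protein = protein, kind = kind,
                 level = if (kind == "GoF") level else 0),
            class = "crn_mutation")
}

#' Apply a gain-of-function mutation
#'
#' Scales the rate constant of every reaction tagged
#' `deactivation:<protein>` by the mutation level; at level 0 the tagged
#' reactions are removed outright (the equivalent stoichiometric-matrix
#' modification).  The initial state is untouched.
#'
#' @param net A `crn_network` with at least one tagged de-activation
#'   reaction for the protein.
#' @param spec A GoF [mutation_spec()].
#' @return The mutated `crn_network`.
#' @export
apply_gof <- function(net, spec) {
  stopifnot(inherits(spec, "crn_mutation"))
  if (spec$kind != "GoF") stop("apply_gof needs a GoF spec", call. = FALSE)
  tag <- paste0("deactivation:", spec$protein)
  hit <- vapply(net$reactions, function(rx) tag %in% rx$tags, logical(1))
  if (!any(hit))
    stop("MISSING_DEACTIVATION_TAGS: no reaction tagged '", tag, "'",
         call. = FALSE)
  if (spec$level == 1) return(net)
  reactions <- net$reactions
  if (spec$level == 0) {
    reactions <- reactions[!hit]
  } else {
    for (j in which(hit)) reactions[[j]]$k <- reactions[[j]]$k * spec$level
  }
  out <- crn_network(net$species, reactions)
  attr(out, "declared_conservation") <- attr(net, "declared_conservation")
  out
}

#' Apply a loss-of-function mutation
#'
#' Projects the initial state: every species whose composition contains the
#' mutated protein is set to zero.  The network itself is unchanged;
#' subsequent equilibria live on the reduced compatibility class, on which
#' the zeroed species can never be produced again.
#'
#' @param net A `crn_network` whose species carry composition metadata.
#' @param x0 State vector to project.
#' @param spec A LoF [mutation_spec()].
#' @return The projected state vector.
#' @export
apply_lof <- function(net, x0, spec) {
  stopifnot(inherits(spec, "crn_mutation"))
  if (spec$kind != "LoF") stop("apply_lof needs a LoF spec", call. = FALSE)
  x0 <- .check_state(net, x0)
  hit <- vapply(net$species, function(s)
    !is.null(s$composition) && spec$protein %in% s$composition, logical(1))
  if (!any(hit))
    stop("UNKNOWN_PROTEIN: '", spec$protein,
         "' occurs in no species composition", call. = FALSE)
  x0[hit] <- 0
  x0
}

#' Apply several mutations at once
#'
#' All GoF rate scalings are applied to the network and all LoF zeroings to
#' the state; the edits commute, so the result is independent of the order
#' of the list, matching the modelling assumption that concurrent mutations
#' act simultaneously rather than sequentially.
#'
#' @param net A `crn_network`.
#' @param x0 Initial state.
#' @param specs List of [mutation_spec()] objects, at most one per protein.
#' @return List with fields `net` (mutated network) and `x0` (projected
#'   state).
#' @export
compose_mutations <- function(net, x0, specs) {
  if (inherits(specs, "crn_mutation")) specs <- list(specs)
  prot <- vapply(specs, `[[`, character(1), "protein")
  if (anyDuplicated(prot))
    stop("conflicting duplicate mutation specs for: ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "), call. = FALSE)
  x <- .check_state(net, x0)
  for (spec in specs)
    if (spec$kind == "GoF") net <- apply_gof(net, spec)
  for (spec in specs)
    if (spec$kind == "LoF") x <- apply_lof(net, x, spec)
  list(net = net, x0 = x)
}

#' Specify an inhibitor drug
#'
#' Drugs are modelled structurally: the network is enlarged with a free
#' drug species and reversible binding reactions to the listed targets, and
#' the bound complexes take part in no other reaction, so binding
#' sequesters the target.  For a *competitive* inhibitor the targets are
#' the catalytically active forms of the protein (the drug competes for the
#' catalytic site); for an *allosteric* inhibitor the targets are all
#' phosphoforms, locking them out of both activation and catalysis.  In
#' either case the caller lists the target species explicitly, keeping the
#' biology in the data layer.
#'
#' @param name Drug name (e.g. `"DBF"` for Dabrafenib, `"TMT"` for
#'   Trametinib).
#' @param mechanism `"competitive"` or `"allosteric"` (documentation of
#'   intent; the binding reactions added are the same).
#' @param targets Character vector of target species names.
#' @param k_on Binding rate, nM^-1 s^-1 (default 1e-3).
#' @param k_off Unbinding rate, s^-1 (default 1e-2).
#' @param c0 Initial (total) drug concentration, nM.
#' @param degradation_rate First-order decay of the free drug, s^-1; 0
#'   disables it.  The default when enabled elsewhere is
#'   [dbf_degradation_rate].
#' @param schedule_time Administration time, seconds; 0 means the drug is
#'   present from the start, otherwise it enters as a timed bolus.
#' @return A list of class `crn_drug`.
#' @export
drug_spec <- function(name, mechanism = c("competitive", "allosteric"),
                      targets, k_on = 1e-3, k_off = 1e-2, c0 = 0,
                      degradation_rate = 0, schedule_time = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.character(name), length(name) == 1L,
            is.character(targets), length(targets) >= 1L)
  if (k_on <= 0 || k_off <= 0) stop("k_on and k_off must be > 0", call. = FALSE)
  if (c0 < 0 || degradation_rate < 0 || schedule_time < 0)
    stop("c0, degradation_rate and schedule_time must be >= 0", call. = FALSE)
  structure(list(name = name, mechanism = mechanism, targets = targets,
                 k_on = k_on, k_off = k_off, c0 = c0,
                 degradation_rate = degradation_rate,
                 schedule_time = schedule_time),
            class = "crn_drug")
}

#' First-order degradation rate used for Dabrafenib
#'
#' Literature value 5.79e-6 s^-1 for the decay of the free drug.
#' @export
dbf_degradation_rate <- 5.79e-6

#' Augment a network with an inhibitor drug
#'
#' Adds the free drug species (initial concentration `c0` if the drug is
#' given at time 0, else 0), one bound complex per target, the reversible
#' binding reactions `drug + T -> drug_T` (`k_on`) and back (`k_off`), all
#' tagged `drug:<name>`, and, when `degradation_rate > 0`, the decay
#' reaction `drug -> 0` tagged `degradation`.  Bound complexes inherit the
#' target's composition plus the drug, and appear in no other reaction:
#' the inhibition is purely structural sequestration.
#'
#' @param net A `crn_network`.
#' @param spec A [drug_spec()] whose targets exist in `net`.
#' @return The augmented `crn_network`.  Any declared conservation rows are
#'   dropped (the basis must be re-derived for the enlarged species set).
#' @export
add_drug <- function(net, spec) {
  stopifnot(inherits(spec, "crn_drug"))
  sp_names <- species_names(net)
  missing <- setdiff(spec$targets, sp_names)
  if (length(missing))
    stop("drug target(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  complex_names <- paste0(spec$name, "_", spec$targets)
  clash <- intersect(c(spec$name, complex_names), sp_names)
  if (length(clash))
    stop("drug species name collision: ", paste(clash, collapse = ", "),
         call. = FALSE)
  drug_tag <- paste0("drug:", spec$name)
  species <- c(net$species, list(
    crn_species(spec$name, if (spec$schedule_time == 0) spec$c0 else 0,
                composition = spec$name)))
  reactions <- net$reactions
  for (i in seq_along(spec$targets)) {
    tgt <- spec$targets[i]
    tgt_comp <- net$species[[match(tgt, sp_names)]]$composition
    species <- c(species, list(
      crn_species(complex_names[i], 0,
                  composition = c(spec$name, if (is.null(tgt_comp)) tgt else tgt_comp))))
    reactions <- c(reactions, list(
      crn_reaction(paste0("bind_", spec$name, "_", tgt),
                   stats::setNames(c(1, 1), c(spec$name, tgt)),
                   stats::setNames(1, complex_names[i]),
                   spec$k_on, tags = drug_tag),
      crn_reaction(paste0("unbind_", spec$name, "_", tgt),
                   stats::setNames(1, complex_names[i]),
                   stats::setNames(c(1, 1), c(spec$name, tgt)),
                   spec$k_off, tags = drug_tag)))
  }
  if (spec$degradation_rate > 0)
    reactions <- c(reactions, list(
      crn_reaction(paste0("degrade_", spec$name),
                   stats::setNames(1, spec$name),
                   stats::setNames(numeric(0), character(0)),
                   spec$degradation_rate,
                   tags = c(drug_tag, "degradation"))))
  crn_network(species, reactions)
}

#' Extend a state vector onto a drug-augmented network
#'
#' Original species keep their values; the free drug gets `c0` (or 0 when
#' administration is scheduled later) and all bound complexes start at 0.
#'
#' @param net_aug Network returned by [add_drug()] (possibly repeatedly).
#' @param x State on the pre-augmentation species.
#' @param specs List of the [drug_spec()]s used for augmentation.
#' @return State on `net_aug`'s species.
#' @export
extend_state <- function(net_aug, x, specs) {
  if (inherits(specs, "crn_drug")) specs <- list(specs)
  sp <- species_names(net_aug)
  out <- stats::setNames(numeric(length(sp)), sp)
  out[names(x)] <- x
  for (spec in specs)
    out[spec$name] <- if (spec$schedule_time == 0) spec$c0 else 0
  out
}

#' Equilibrium of a drug-loaded network
#'
#' Implements the three-model pipeline step: starting from the mutated
#' equilibrium, the network is enlarged with the drug's binding reactions,
#' the free drug is set to its initial concentration `c0`, all complexes to
#' zero, and the equilibrium of the augmented system is computed on the
#' resulting compatibility class.
#'
#' @param net_mut The mutated `crn_network`.
#' @param x_tilde_e Mutated equilibrium state of `net_mut`.
#' @param spec One [drug_spec()] or a list of them (a drug combination).
#' @param method `"nlpc"` (default) or `"ode"`.
#' @param seed Seed for the root-finder restarts.
#' @param ... Passed on to [solve_equilibrium()] or
#'   [simulate_to_equilibrium()].
#' @return A `crn_equilibrium` on the augmented species set, with the
#'   augmented network attached as attribute `network`.
#' @export
drug_loaded_equilibrium <- function(net_mut, x_tilde_e, spec,
                                    method = c("nlpc", "ode"), seed = 1L, ...) {
  method <- match.arg(method)
  if (inherits(spec, "crn_drug")) spec <- list(spec)
  # a drug at zero dose is inert: leave the network untouched so that e.g.
  # 2-D scan marginals at zero dose coincide exactly with 1-D scans
  spec <- Filter(function(s) s$c0 > 0, spec)
  net_aug <- net_mut
  for (s in spec) net_aug <- add_drug(net_aug, s)
  # the equilibrium does not depend on the administration time, only the
  # transient does: load the full dose regardless of schedule_time
  specs_now <- lapply(spec, function(s) { s$schedule_time <- 0; s })
  x_init <- extend_state(net_aug, .check_state(net_mut, x_tilde_e), specs_now)
  eq <- if (method == "nlpc") {
    basis <- find_conservation_laws(net_aug)
    solve_equilibrium(net_aug, basis, x_init, seed = seed, ...)
  } else {
    simulate_to_equilibrium(net_aug, x_init, ...)
  }
  attr(eq, "network") <- net_aug
  eq
}
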