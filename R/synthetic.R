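#' A reversible two-species network with closed-form equilibrium
#'
#' `A <-> B` with forward rate `k_f` and backward rate `k_r`; starting from
#' total mass `total` in A, the equilibrium is
#' `(total k_r / (k_f + k_r), total k_f / (k_f + k_r))`.  Used as an exact
#' oracle for the solvers.
#'
#' @param k_f,k_r Positive rate constants, s^-1.
#' @param total Total mass, nM (placed on A initially).
#' @return A `crn_network`.
#' @export
build_reversible_pair <- function(k_f = 2, k_r = 1, total = 3) {
  crn_network(
    list(crn_species("A", total, composition = "M"),
         crn_species("B", 0, composition = "M")),
    list(crn_reaction("fwd", c(A = 1), c(B = 1), k_f),
         crn_reaction("rev", c(B = 1), c(A = 1), k_r)))
}

#' Toy MAPK-like activation cascade
#'
#' Generates a small mass-action network with the structural features of a
#' colorectal-cancer signalling network at desk scale: a GTPase cycle
#' (GDP/GTP-bound Ras-analog, activated by a GEF and deactivated by a GAP,
#' the GAP reactions tagged `deactivation:KRAS` so gain-of-function
#' mutations are exercisable), a cascade of kinase tiers activated by
#' enzymatic (complex-forming) phosphorylation with a phosphatase per tier
#' (double phosphorylation on the MEK/ERK-like tiers), and a PTEN-analog
#' side branch that binds the terminal phosphatase weakly, so that a PTEN
#' loss of function is exercisable yet barely perturbs the cascade.  All
#' species carry composition metadata; every protein moiety is conserved,
#' the conservation basis is weakly elemented, and the physiological
#' equilibrium is strictly positive.
#'
#' Default totals and rates place the physiological equilibrium in a
#' low-activity regime (small doubly-phosphorylated fractions) that is
#' strongly activated when the GAP deactivation reactions are removed.
#'
#' @param n_tiers Number of kinase tiers (default 3: Raf/MEK/ERK analogs).
#' @param double_phospho Logical vector per tier; defaults to single
#'   phosphorylation on tier 1 and double on later tiers.
#' @param totals Named moiety totals, nM; defaults documented in the
#'   methods vignette.
#' @param rate_scale Global multiplier on all rate constants.
#' @param seed Optional integer; when given, all rate constants are
#'   jittered log-uniformly by up to +/-10% (reproducibly).
#' @return A `crn_network`.
#' @export
build_mapk_toy <- function(n_tiers = 3,
                           double_phospho = c(FALSE, rep(TRUE, max(0, n_tiers - 1))),
                           totals = NULL, rate_scale = 1, seed = NULL) {
  stopifnot(n_tiers >= 1, length(double_phospho) == n_tiers)
  tier_names <- if (n_tiers == 3) c("Raf", "MEK", "ERK") else
    paste0("K", seq_len(n_tiers))
  def_totals <- c(KRAS = 100, GEF = 10, GAP = 30, PTEN = 50,
                  stats::setNames(c(100, 300, 400, rep(200, max(0, n_tiers - 3)))[seq_len(n_tiers)],
                                  tier_names),
                  stats::setNames(c(50, 100, 100, rep(100, max(0, n_tiers - 3)))[seq_len(n_tiers)],
                                  paste0("Pase", seq_len(n_tiers))))
  if (!is.null(totals)) def_totals[names(totals)] <- unlist(totals)
  totals <- def_totals
  if (any(totals <= 0)) stop("totals must be > 0", call. = FALSE)

  species <- list(); reactions <- list()
  add_sp <- function(name, x0, comp)
    species[[length(species) + 1]] <<- crn_species(name, x0, composition = comp)
  add_rx <- function(id, from, to, k, tags = character())
    reactions[[length(reactions) + 1]] <<- crn_reaction(id, from, to, k, tags)

  # enzymatic cycle helper: E + S <-> E_S -> E + P
  enz <- function(E, S, P, kon, koff, kcat, comp, tags = character()) {
    cx <- paste0(E, "_", S)
    add_sp(cx, 0, comp)
    add_rx(paste0("bind_", cx), stats::setNames(c(1, 1), c(E, S)),
           stats::setNames(1, cx), kon, tags)
    add_rx(paste0("unbind_", cx), stats::setNames(1, cx),
           stats::setNames(c(1, 1), c(E, S)), koff, tags)
    add_rx(paste0("cat_", cx), stats::setNames(1, cx),
           stats::setNames(c(1, 1), c(E, P)), kcat, tags)
  }

  # GTPase cycle
  add_sp("RasGDP", totals[["KRAS"]], "KRAS")
  add_sp("RasGTP", 0, "KRAS")
  add_sp("GEF", totals[["GEF"]], "GEF")
  add_sp("GAP", totals[["GAP"]], "GAP")
  enz("GEF", "RasGDP", "RasGTP", 1e-3, 1e-2, 0.05, c("GEF", "KRAS"))
  enz("GAP", "RasGTP", "RasGDP", 1e-3, 1e-2, 1.0, c("GAP", "KRAS"),
      tags = "deactivation:KRAS")

  kinase_above <- "RasGTP"
  kinase_comp <- "KRAS"
  for (t in seq_len(n_tiers)) {
    tn <- tier_names[t]
    pase <- paste0("Pase", t)
    steps <- if (double_phospho[t]) 2 else 1
    forms <- c(tn, paste0(strrep("p", seq_len(steps)), "-", tn))
    add_sp(forms[1], totals[[tn]], tn)
    for (s in seq_len(steps)) add_sp(forms[s + 1], 0, tn)
    add_sp(pase, totals[[pase]], pase)
    for (s in seq_len(steps)) {
      enz(kinase_above, forms[s], forms[s + 1], 1e-3, 1e-2, 0.5,
          c(kinase_comp, tn))
      enz(pase, forms[s + 1], forms[s], 1e-3, 1e-2, 0.15, c(pase, tn))
    }
    kinase_above <- forms[steps + 1]
    kinase_comp <- tn
  }

  # PTEN-analog branch: weak sequestration of the terminal phosphatase
  last_pase <- paste0("Pase", n_tiers)
  add_sp("PTEN", totals[["PTEN"]], "PTEN")
  cx <- "PTEN_Pase"
  add_sp(cx, 0, c("PTEN", last_pase))
  add_rx("bind_PTEN", stats::setNames(c(1, 1), c("PTEN", last_pase)),
         stats::setNames(1, cx), 1e-6)
  add_rx("unbind_PTEN", stats::setNames(1, cx),
         stats::setNames(c(1, 1), c("PTEN", last_pase)), 1e-2)

  if (rate_scale != 1 || !is.null(seed)) {
    jitter <- rep(1, length(reactions))
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      jitter <- exp(stats::runif(length(reactions), -log(1.1), log(1.1)))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
    for (j in seq_along(reactions))
      reactions[[j]]$k <- reactions[[j]]$k * rate_scale * jitter[j]
  }
  crn_network(species, reactions)
}

#' Seeded random moiety-conserving mass-action network
#'
#' Generates closed networks for property-based testing: a set of protein
#' moieties, each with one free form and possibly further forms connected
#' by reversible first-order conversions, plus heteromeric complexes with
#' reversible binding/unbinding.  Every reaction conserves the moiety
#' labelling, so one semi-positive conservation law per moiety holds by
#' construction, and all conversions being reversible keeps equilibria
#' strictly positive on every moiety that starts with mass.
#'
#' @param n_species Target species count (>= 1; met exactly).
#' @param n_reactions Target reaction count; reactions come in reversible
#'   pairs, so the realised count is `n_reactions` rounded up to even, and
#'   never below the pairs needed to connect all species.
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return A `crn_network` whose species carry moiety compositions.
#' @export
random_mass_action_network <- function(n_species, n_reactions, seed) {
  stopifnot(n_species >= 1, n_reactions >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  m <- max(1L, round(n_species / 3))
  moiety <- paste0("M", seq_len(m))
  # species bookkeeping: name -> composition; forms per moiety
  species <- list()
  forms <- stats::setNames(vector("list", m), moiety)
  for (i in seq_len(m)) {
    nm <- paste0(moiety[i], "a")
    species[[nm]] <- moiety[i]
    forms[[moiety[i]]] <- nm
  }
  reactions <- list()
  k_uni <- function() 10^stats::runif(1, -3, -1)
  k_bi <- function() 10^stats::runif(1, -4, -2)
  add_pair <- function(id, from, to, k1, k2) {
    reactions[[length(reactions) + 1]] <<- crn_reaction(paste0(id, "_f"), from, to, k1)
    reactions[[length(reactions) + 1]] <<- crn_reaction(paste0(id, "_r"), to, from, k2)
  }
  cplx_count <- 0L
  while (length(species) < n_species) {
    if (stats::runif(1) < 0.5 || m < 2L) {
      mo <- sample(moiety, 1)
      nm <- paste0(mo, letters[length(forms[[mo]]) + 1L])
      src <- sample(forms[[mo]], 1)
      species[[nm]] <- species[[src]]
      forms[[mo]] <- c(forms[[mo]], nm)
      add_pair(paste0("conv", length(reactions)),
               stats::setNames(1, src), stats::setNames(1, nm),
               k_uni(), k_uni())
    } else {
      pair <- sample(moiety, 2)
      a <- sample(forms[[pair[1]]], 1); b <- sample(forms[[pair[2]]], 1)
      cplx_count <- cplx_count + 1L
      nm <- paste0("C", cplx_count)
      species[[nm]] <- c(species[[a]], species[[b]])
      add_pair(paste0("bind", cplx_count),
               stats::setNames(c(1, 1), c(a, b)), stats::setNames(1, nm),
               k_bi(), k_uni())
    }
  }
  while (length(reactions) < n_reactions) {
    eligible <- moiety[lengths(forms) >= 2L]
    if (!length(eligible)) break
    mo <- sample(eligible, 1)
    fr <- sample(forms[[mo]], 2)
    add_pair(paste0("extra", length(reactions)),
             stats::setNames(1, fr[1]), stats::setNames(1, fr[2]),
             k_uni(), k_uni())
  }
  if (!length(reactions) && m >= 2L) {
    # single-form moieties only: connect two free forms through a complex
    cplx_count <- cplx_count + 1L
    nm <- paste0("C", cplx_count)
    a <- forms[[moiety[1]]][1]; b <- forms[[moiety[2]]][1]
    species[[nm]] <- c(species[[a]], species[[b]])
    add_pair("bind0", stats::setNames(c(1, 1), c(a, b)),
             stats::setNames(1, nm), k_bi(), k_uni())
  } else if (!length(reactions)) {
    a <- forms[[moiety[1]]][1]
    add_pair("iso0", stats::setNames(1, a), stats::setNames(1, a),
             k_uni(), k_uni())
  }
  sp <- lapply(names(species), function(nm) {
    free <- grepl("a$", nm) && !grepl("^C", nm)
    crn_species(nm, if (free) stats::runif(1, 10, 100) else 0,
                composition = species[[nm]])
  })
  crn_network(sp, reactions)
}

#' Load a full-scale colorectal-cancer reaction network
#'
#' Loader contract for the deposited 419-species / 850-reaction network
#' once converted to the interchange format (see the conversion notes in
#' the methods vignette).  Expects `<directory>/crc_crn.txt`; checks the
#' species/reaction counts (warning on mismatch, since variant conversions
#' exist) and the presence of `deactivation:KRAS` tags.
#'
#' @param directory Directory holding `crc_crn.txt`.
#' @return A `crn_network`.
#' @export
load_crcrn <- function(directory) {
  path <- file.path(directory, "crc_crn.txt")
  if (!file.exists(path))
    stop("expected network file not found: ", path, call. = FALSE)
  net <- load_network(path)
  n <- length(net$species); r <- length(net$reactions)
  if (n != 419L || r != 850L)
    warning("expected 419 species and 850 reactions, found ", n, " and ", r,
            call. = FALSE)
  has_kras <- any(vapply(net$reactions, function(rx)
    "deactivation:KRAS" %in% rx$tags, logical(1)))
  if (!has_kras)
    warning("no reaction tagged deactivation:KRAS; KRAS gain-of-function ",
            "mutations will not be applicable", call. = FALSE)
  net
}
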