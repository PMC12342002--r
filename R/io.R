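#' Read a reaction network from the plain-text interchange format
#'
#' The format is line-oriented UTF-8 text with `#` comments:
#' \preformatted{
#' SPECIES <name> <x0_nM> [composition=P1+P2+...]
#' REACTION <id> <c1> <sp1> + ... -> <c2> <sp2> + ... ; k=<float> [; tags=t1,t2]
#' CONSERVATION <name> <coeff> <species> [+ <coeff> <species> ...]
#' }
#' Stoichiometric coefficients default to 1 when omitted; an empty reaction
#' side is written `0` (so `A -> 0` is first-order degradation and
#' `0 -> A` a zeroth-order source).  There is no reversible-reaction
#' shorthand: a reversible pair is two REACTION lines.  Optional
#' CONSERVATION lines declare known semi-positive conservation rows; they
#' are attached to the network (attribute `declared_conservation`) and
#' verified, not re-derived, by [find_conservation_laws()].
#'
#' @param path Path to a network file.
#' @return A `crn_network`, species order as in the file.
#' @seealso [save_network()], [crn_network()]
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  species <- list(); reactions <- list(); conservation <- list()
  perr <- function(i, msg) stop("parse error at line ", i, " of '", path,
                                "': ", msg, call. = FALSE)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    kw <- sub("[[:space:]].*$", "", line)
    body <- trimws(sub("^[^[:space:]]+", "", line))
    if (kw == "SPECIES") {
      toks <- strsplit(body, "[[:space:]]+")[[1]]
      if (length(toks) < 2L) perr(i, "SPECIES needs <name> <x0>")
      x0 <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(x0)) perr(i, paste0("bad x0 '", toks[2], "'"))
      comp <- NULL
      for (extra in toks[-(1:2)]) {
        if (grepl("^composition=", extra)) {
          comp <- strsplit(sub("^composition=", "", extra), "+", fixed = TRUE)[[1]]
        } else perr(i, paste0("unrecognised token '", extra, "'"))
      }
      species <- c(species, list(tryCatch(
        crn_species(toks[1], x0, composition = comp),
        error = function(e) perr(i, conditionMessage(e)))))
    } else if (kw == "REACTION") {
      parts <- strsplit(body, ";", fixed = TRUE)[[1]]
      if (length(parts) < 2L) perr(i, "REACTION needs '; k=<float>'")
      head_toks <- trimws(parts[1])
      id <- sub("[[:space:]].*$", "", head_toks)
      eqn <- trimws(sub("^[^[:space:]]+", "", head_toks))
      sides <- strsplit(eqn, "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L) perr(i, "reaction needs exactly one '->'")
      k <- NA_real_; tags <- character()
      for (opt in trimws(parts[-1])) {
        if (grepl("^k=", opt)) {
          k <- suppressWarnings(as.numeric(sub("^k=", "", opt)))
          if (is.na(k)) perr(i, "bad rate constant")
        } else if (grepl("^tags=", opt)) {
          tags <- strsplit(sub("^tags=", "", opt), ",", fixed = TRUE)[[1]]
        } else perr(i, paste0("unrecognised option '", opt, "'"))
      }
      if (is.na(k)) perr(i, "missing k=")
      reactions <- c(reactions, list(tryCatch(
        crn_reaction(id, .parse_side(sides[1], function(m) perr(i, m)),
                     .parse_side(sides[2], function(m) perr(i, m)), k, tags),
        error = function(e) perr(i, conditionMessage(e)))))
    } else if (kw == "CONSERVATION") {
      toks <- strsplit(body, "[[:space:]]+")[[1]]
      nm <- toks[1]
      terms <- toks[-1][toks[-1] != "+"]
      if (length(terms) == 0L || length(terms) %% 2L != 0L)
        perr(i, "CONSERVATION needs <name> then <coeff> <species> pairs")
      coefs <- suppressWarnings(as.numeric(terms[c(TRUE, FALSE)]))
      if (anyNA(coefs) || any(coefs < 0)) perr(i, "bad conservation coefficient")
      row <- stats::setNames(coefs, terms[c(FALSE, TRUE)])
      conservation[[nm]] <- row
    } else perr(i, paste0("unknown keyword '", kw, "'"))
  }
  net <- crn_network(species, reactions)
  if (length(conservation)) attr(net, "declared_conservation") <- conservation
  net
}

# Parse one side of a reaction equation into a named coefficient vector.
.parse_side <- function(txt, fail) {
  txt <- trimws(txt)
  if (txt == "0") return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    toks <- strsplit(tm, "[[:space:]]+")[[1]]
    if (length(toks) == 1L) { coef <- 1; sp <- toks[1] }
    else if (length(toks) == 2L) {
      coef <- suppressWarnings(as.numeric(toks[1]))
      if (is.na(coef)) fail(paste0("bad coefficient '", toks[1], "'"))
      sp <- toks[2]
    } else fail(paste0("malformed term '", tm, "'"))
    if (sp %in% names(out)) out[sp] <- out[sp] + coef else out[sp] <- coef
  }
  out
}

#' Write a reaction network in the interchange format
#'
#' Serialization is canonical (stable ordering, `%.17g` numbers), so
#' `save -> load -> save` is byte-identical and `load(save(net))`
#' reconstructs an identical network.
#'
#' @param net A `crn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  num <- function(x) sprintf("%.17g", x)
  fmt_side <- function(v) {
    if (length(v) == 0L) return("0")
    paste(vapply(seq_along(v), function(i)
      if (v[i] == 1) names(v)[i] else paste(v[i], names(v)[i]), character(1)),
      collapse = " + ")
  }
  out <- character(0)
  for (s in net$species) {
    ln <- paste("SPECIES", s$name, num(s$x0))
    if (!is.null(s$composition))
      ln <- paste0(ln, " composition=", paste(s$composition, collapse = "+"))
    out <- c(out, ln)
  }
  for (rx in net$reactions) {
    ln <- paste0("REACTION ", rx$id, " ", fmt_side(rx$reactants), " -> ",
                 fmt_side(rx$products), " ; k=", num(rx$k))
    if (length(rx$tags)) ln <- paste0(ln, " ; tags=", paste(rx$tags, collapse = ","))
    out <- c(out, ln)
  }
  decl <- attr(net, "declared_conservation")
  for (nm in names(decl)) {
    row <- decl[[nm]]
    out <- c(out, paste("CONSERVATION", nm,
                        paste(num(row), names(row), collapse = " + ")))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
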