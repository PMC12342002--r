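#' Run the full equilibrium-comparison pipeline
#'
#' Orchestrates the three-model analysis: physiological equilibrium of the
#' input network, mutated equilibrium after applying the configured
#' mutations, optional drug-loaded equilibria, relative-difference
#' profiles, and optional 1-D/2-D dose scans.  All outputs are plain CSV /
#' JSON, each carrying provenance (seed and config hash) in comment
#' headers, and the run is deterministic given the seed.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' keys: `network` (path to an interchange-format file, or the string
#' `"mapk_toy"` for the built-in cascade), `seed`, `solver`
#' (`method`: `"nlpc"`/`"ode"`, `tol`), `mutations` (list of
#' `{protein, kind, level}`), `drugs` (list of `{name, mechanism, targets,
#' k_on, k_off, c0, degradation_rate, schedule_time_min}`), `scan`
#' (`{drug, grid}`), `scan2` (`{drugA, drugB, gridA, gridB}`), and
#' `out_dir`.
#'
#' @param config Path to a YAML file or a list.
#' @return Invisibly, a list bundle with the computed objects (`network`,
#'   `basis`, equilibria, profiles, scans) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  method <- config$solver$method %||% "nlpc"
  tol <- config$solver$tol %||% 1e-10
  cfg_hash <- .fnv1a(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                                      auto_unbox = TRUE))
  prov <- c(sprintf("# seed=%d", seed), sprintf("# config=%s", cfg_hash))
  stages <- character(0)
  write_prov_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(prov, con)
    utils::write.csv(df, con, row.names = FALSE)
  }

  net <- if (identical(config$network, "mapk_toy")) build_mapk_toy()
         else load_network(config$network)
  basis <- find_conservation_laws(net)
  x0 <- initial_state(net)
  eq_fun <- function(network, bas, x) {
    if (method == "nlpc") solve_equilibrium(network, bas, x, seed = seed, tol = tol)
    else simulate_to_equilibrium(network, x)
  }

  eq_phys <- eq_fun(net, basis, x0)
  write_prov_csv(data.frame(species = names(eq_phys$x_e),
                            x_e = unname(eq_phys$x_e)),
                 "physiological_equilibrium.csv")
  stages <- c(stages, "physiological")
  bundle <- list(network = net, basis = basis, eq_phys = eq_phys)
  residuals <- list(physiological = eq_phys$residual)

  if (length(config$mutations)) {
    specs <- lapply(config$mutations, function(mu)
      mutation_spec(mu$protein, mu$kind, mu$level %||% 0))
    mut <- compose_mutations(net, x0, specs)
    basis_mut <- find_conservation_laws(mut$net)
    eq_mut <- eq_fun(mut$net, basis_mut, mut$x0)
    prof <- delta_profile(eq_mut$x_e, eq_phys$x_e)
    write_prov_csv(data.frame(species = names(eq_mut$x_e),
                              x_e = unname(eq_mut$x_e),
                              delta = unname(prof$values)),
                   "mutated_equilibrium.csv")
    stages <- c(stages, "mutation")
    bundle$net_mut <- mut$net; bundle$eq_mut <- eq_mut; bundle$delta <- prof
    residuals$mutated <- eq_mut$residual
  }

  drug_specs <- lapply(config$drugs %||% list(), function(d)
    drug_spec(d$name, d$mechanism %||% "competitive", unlist(d$targets),
              k_on = d$k_on %||% 1e-3, k_off = d$k_off %||% 1e-2,
              c0 = d$c0 %||% 0,
              degradation_rate = d$degradation_rate %||% 0,
              schedule_time = 60 * (d$schedule_time_min %||% 0)))
  names(drug_specs) <- vapply(drug_specs, `[[`, character(1), "name")

  if (length(drug_specs) && !is.null(bundle$eq_mut)) {
    eq_drug <- drug_loaded_equilibrium(bundle$net_mut, bundle$eq_mut$x_e,
                                       drug_specs, method = method, seed = seed)
    orig <- species_names(bundle$net_mut)
    dprof <- delta_profile(eq_drug$x_e[orig], eq_phys$x_e,
                           role = "drug_difference")
    write_prov_csv(data.frame(species = names(eq_drug$x_e),
                              x_e = unname(eq_drug$x_e)),
                   "drug_equilibrium.csv")
    write_prov_csv(data.frame(species = orig, d = unname(dprof$values),
                              G = geometric_index(dprof)),
                   "d_profile.csv")
    stages <- c(stages, "drug")
    bundle$eq_drug <- eq_drug; bundle$d_profile <- dprof
    residuals$drug <- eq_drug$residual
  }

  if (!is.null(config$scan) && !is.null(bundle$eq_mut)) {
    sp <- drug_specs[[config$scan$drug]]
    if (is.null(sp)) stop("scan names unknown drug '", config$scan$drug, "'",
                          call. = FALSE)
    grid <- .parse_grid(config$scan$grid)
    scan <- dose_scan_1d(bundle$net_mut, bundle$eq_mut$x_e, eq_phys$x_e,
                         sp, grid, method = method, seed = seed)
    write_prov_csv(data.frame(dose_nM = scan$grid1, G = scan$G_values),
                   "dose_scan.csv")
    stages <- c(stages, "dose_scan")
    bundle$scan <- scan
  }

  if (!is.null(config$scan2) && !is.null(bundle$eq_mut)) {
    spA <- drug_specs[[config$scan2$drugA]]
    spB <- drug_specs[[config$scan2$drugB]]
    if (is.null(spA) || is.null(spB))
      stop("scan2 names an unknown drug", call. = FALSE)
    gridA <- .parse_grid(config$scan2$gridA)
    gridB <- .parse_grid(config$scan2$gridB)
    scan2 <- dose_scan_2d(bundle$net_mut, bundle$eq_mut$x_e, eq_phys$x_e,
                          spA, spB, gridA, gridB, method = method, seed = seed)
    df <- expand.grid(doseA_nM = gridA, doseB_nM = gridB)
    df$G <- as.vector(scan2$G_values)
    write_prov_csv(df, "dose_scan2.csv")
    stages <- c(stages, "dose_scan2")
    bundle$scan2 <- scan2
  }

  manifest <- list(config = config, seed = seed, config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("crneq")),
                   stages = stages, residuals = residuals)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_grid <- function(g) {
  if (is.numeric(g)) return(as.numeric(g))
  if (is.list(g)) return(seq(g$from, g$to, by = g$by))
  if (is.character(g) && grepl(":", g)) {
    parts <- as.numeric(strsplit(g, ":", fixed = TRUE)[[1]])
    return(seq(parts[1], parts[2], by = parts[3]))
  }
  stop("cannot parse dose grid", call. = FALSE)
}

# rolling polynomial hash of the UTF-8 bytes; provenance fingerprint only
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @importFrom ggplot2 .data
NULL

#' Plot an effect profile over species index
#'
#' One trace of the relative differences delta_i (or d_i) against species
#' index, the standard global view of a perturbation.
#'
#' @param profile A `crn_effect_profile`.
#' @return A ggplot object.
#' @export
plot_effect_profile <- function(profile) {
  df <- data.frame(index = seq_along(profile$values),
                   value = unname(profile$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "species index",
                  y = if (profile$role == "mutation_delta")
                    expression(delta[i]) else expression(d[i])) +
    ggplot2::theme_minimal()
}

#' Grouped equilibrium bar chart for selected species
#'
#' @param equilibria Named list of equilibrium state vectors (e.g.
#'   physiological, mutated, drug-loaded).
#' @param species Character vector of species to show.
#' @return A ggplot object (one panel per species, free y scale).
#' @export
plot_equilibrium_bars <- function(equilibria, species) {
  df <- do.call(rbind, lapply(names(equilibria), function(cond)
    data.frame(condition = cond, species = species,
               x_e = unname(equilibria[[cond]][species]))))
  df$condition <- factor(df$condition, levels = names(equilibria))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$x_e,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "equilibrium concentration (nM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot G against dose for a 1-D scan
#' @param scan A `crn_dose_scan` from [dose_scan_1d()].
#' @return A ggplot object.
#' @export
plot_dose_curve <- function(scan) {
  df <- data.frame(dose = scan$grid1, G = scan$G_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$G)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = scan$argmin, linetype = "dashed") +
    ggplot2::labs(x = "initial drug concentration (nM)", y = "G") +
    ggplot2::theme_minimal()
}

#' Heatmap of G over a 2-D dose scan
#' @param scan A `crn_dose_scan` from [dose_scan_2d()].
#' @return A ggplot object, axes labelled by the two dose grids.
#' @export
plot_dose_heatmap <- function(scan) {
  df <- expand.grid(doseA = scan$grid1, doseB = scan$grid2)
  df$G <- as.vector(scan$G_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$doseB, y = .data$doseA,
                                   fill = .data$G)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "drug B initial concentration (nM)",
                  y = "drug A initial concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Activated-fraction time course on a log time axis
#'
#' Time is reported in minutes on a log10 axis (the dynamics span seconds
#' to days); an optional horizontal reference marks the physiological
#' activated fraction.
#'
#' @param times Seconds.
#' @param fractions Values from [activated_fraction()], or a named list of
#'   such vectors for several doses.
#' @param reference Optional physiological reference level.
#' @return A ggplot object.
#' @export
plot_activated_fraction <- function(times, fractions, reference = NULL) {
  if (!is.list(fractions)) fractions <- list(trace = fractions)
  df <- do.call(rbind, lapply(names(fractions), function(nm)
    data.frame(time_min = times / 60, fraction = fractions[[nm]], dose = nm)))
  df <- df[df$time_min > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$fraction,
                                        colour = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (min)", y = "activated fraction") +
    ggplot2::theme_minimal()
  if (!is.null(reference))
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dashed")
  p
}
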