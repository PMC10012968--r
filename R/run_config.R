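#' Default run configuration
#'
#' Clinical units at this boundary (cardiac output in L/min); SI everywhere
#' inside. All parameters carry the package defaults and can be overridden by
#' a (possibly nested) list or YAML file with the same keys.
#'
#' @return Nested list of configuration defaults.
#' @export
default_run_config <- function() {
  list(
    posture = "supine",
    cardiac_output_L_min = 4.8,
    mode = "coupled",               # oneD | macro | coupled
    seed = 1L,
    geometry = list(
      n_acini = 10000L,
      total_volume = 4.0e-3,
      right_fraction = 0.525,
      strahler_ratio_art = 1.52,
      strahler_ratio_ven = 1.56,
      diameter_cv = 0.15
    ),
    capillary = list(
      H0 = 3.5e-6, Hmax = 7.7e-6, alpha_c = 1.3e-9,
      mu_c = 0.0019, f = 21.6, l_c = 1186e-6, SA_total = 65.4
    ),
    fluid = list(mu = 0.0035, rho_b = 1050),
    compliance = list(alpha = 1.49e-4),
    boundary = list(outlet_pressure = 666, alveolar_pressure = 0,
                    recoil_ref = -500, recoil_slope = -981),
    coupling = list(lambda = 0.2, epsilon = 0.1, max_iterations = 120),
    macro = list(lpa_target = 52.85, dP_target = 300),
    out_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (!k %in% names(base)) stop("unknown configuration key: '", k, "'")
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown top-level or nested keys raise a schema error naming the key.
#'
#' @param path YAML file path.
#' @return Full configuration (defaults overridden by the file).
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' Execute a configured run end to end
#'
#' Builds (or reuses) the geometry, solves the requested mode — uncoupled 1D
#' network (`"oneD"`), macro surrogate alone (`"macro"`), or the coupled
#' model (`"coupled"`) — and derives the perfusion metrics. Deterministic
#' given the seed. When `out_dir` is set, writes the network tables, the
#' per-element/per-acinus state, the coupling iteration log, and a metrics
#' JSON stamped with the seed and a configuration hash.
#'
#' @param config A configuration list (see [default_run_config()]), a YAML
#'   path, or `NULL` for defaults.
#' @param network Optional prebuilt `vessel_network` (geometry step skipped);
#'   used to share one geometry across postures.
#' @param macro Optional precalibrated macro model.
#' @return List with `config`, `network`, `state` (or `coupled` run),
#'   `summary` ([perfusion_summary()]), `metrics` (named list) and file paths
#'   when written.
#' @export
run_from_config <- function(config = NULL, network = NULL, macro = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config %||% list())
  if (cfg$cardiac_output_L_min <= 0) stop("cardiac output must be positive")
  pos <- posture(cfg$posture)
  Q <- cfg$cardiac_output_L_min / 6e4
  fluid <- fluid_properties(cfg$fluid$mu, cfg$fluid$rho_b)
  law <- compliance_law(cfg$compliance$alpha)
  cap <- do.call(capillary_sheet_params, cfg$capillary)
  if (is.null(network)) {
    g <- cfg$geometry
    network <- build_pulmonary_network(
      n_acini = g$n_acini, total_volume = g$total_volume,
      right_fraction = g$right_fraction, cap = cap, fluid = fluid,
      strahler_ratio_art = g$strahler_ratio_art,
      strahler_ratio_ven = g$strahler_ratio_ven,
      diameter_cv = g$diameter_cv,
      seed = cfg$seed, alveolar_pressure = cfg$boundary$alveolar_pressure)
  }
  bcs <- boundary_conditions(Q,
                             outlet_pressure = cfg$boundary$outlet_pressure,
                             alveolar_pressure = cfg$boundary$alveolar_pressure,
                             recoil_ref = cfg$boundary$recoil_ref,
                             recoil_slope = cfg$boundary$recoil_slope)
  res <- list(config = cfg, network = network)
  if (cfg$mode == "macro") {
    if (is.null(macro)) macro <- calibrate_macro(Q_ref = Q,
                                                 lpa_target = cfg$macro$lpa_target,
                                                 dP_target = cfg$macro$dP_target)
    res$macro <- macro
    res$macro_result <- macro_solve(macro, Q, c(LPA = bcs$outlet_pressure,
                                                RPA = bcs$outlet_pressure))
    res$metrics <- list(mode = "macro", posture = cfg$posture,
                        CO_L_min = cfg$cardiac_output_L_min,
                        inlet_pressure_Pa = res$macro_result$P_in,
                        LPA_fraction_pct = 100 * res$macro_result$Q_out[["LPA"]] / Q)
  } else if (cfg$mode == "oneD") {
    res$state <- solve_network(network, bcs, pos, fluid, law)
    res$summary <- perfusion_summary(res$state)
  } else if (cfg$mode == "coupled") {
    if (is.null(macro)) macro <- calibrate_macro(Q_ref = Q,
                                                 lpa_target = cfg$macro$lpa_target,
                                                 dP_target = cfg$macro$dP_target)
    res$macro <- macro
    cc <- coupling_config(lambda = cfg$coupling$lambda,
                          epsilon = cfg$coupling$epsilon,
                          max_iterations = cfg$coupling$max_iterations)
    res$coupled <- run_coupled(macro, network, Q, pos, cc, bcs, fluid, law)
    res$state <- res$coupled$state
    res$summary <- perfusion_summary(res$coupled)
  } else stop("unknown mode: '", cfg$mode, "'")

  if (!is.null(res$summary)) {
    gl <- glance(res$summary)
    res$metrics <- list(mode = cfg$mode, posture = cfg$posture,
                        CO_L_min = cfg$cardiac_output_L_min,
                        G = gl$G_pct_per_cm, COV = gl$COV_pct,
                        right_fraction = gl$right_fraction_pct)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_network_csv(network, cfg$out_dir)
    if (!is.null(res$state)) {
      utils::write.csv(res$state$elements[, c("id", "from", "to", "type", "flow",
                                              "diameter", "dP")],
                       file.path(cfg$out_dir, "state_elements.csv"),
                       row.names = FALSE)
      if (!is.null(res$state$acini))
        utils::write.csv(res$state$acini[, c("id", "lung", "flow", "height")],
                         file.path(cfg$out_dir, "state_acini.csv"),
                         row.names = FALSE)
      export_vtk(network, file.path(cfg$out_dir, "network.vtk"), res$state)
    }
    if (!is.null(res$coupled))
      utils::write.csv(res$coupled$log, file.path(cfg$out_dir, "iterations.csv"),
                       row.names = FALSE)
    cfg_hashable <- cfg
    cfg_hashable$out_dir <- NULL  # the hash identifies the run, not its location
    stamp <- c(res$metrics, list(seed = cfg$seed,
                                 config_hash = rlang::hash(cfg_hashable)))
    jsonlite::write_json(stamp, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$files <- list.files(cfg$out_dir, full.names = TRUE)
  }
  res
}
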