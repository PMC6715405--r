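# Calibrated baseline kinetics for the activator-substrate core on the unit
# lattice, chosen once via the dispersion relation: at D_H = 0.05 the Turing
# band opens for D_B/D_H ratios above ~260 (so ratio 10 is deeply stable and
# ratio 1000 strongly unstable), the dominant wavelength is ~6 voxels, and
# the homogeneous steady state is H* = 40, B* = 10 molecules/voxel -- counts
# high enough that noise exceedances of the spot threshold are rare, yet low
# enough that runs pattern at desk scale.
hb_base_params <- function() {
  list(k1 = 0.0015, k2 = 29, k3 = 0.5, k4 = 16, k5 = 1,
       D_H = 0.05, D_B = 50)
}

hbp_extra_params <- function() list(k6 = 0.05, k7 = 1, alpha = 1)

hbpm_extra_params <- function() list(k9 = 400, k10 = 0.05, k11 = 0.05,
                                     D_M = 7.5)

hbpma_extra_params <- function() {
  list(k13 = 50, k14 = 0.1, k_AH = 0.5, k_HA = 0.05, D_A = 1)
}

preset_table <- function() {
  base <- hb_base_params()
  hbp <- c(base, hbp_extra_params())
  hbpm <- c(hbp, hbpm_extra_params())
  hbpma <- c(hbpm, hbpma_extra_params())
  list(
    "hb-2d" = list(model = "HB", dim = 2, radius_ratio = 1, params = base,
                   note = "2D activator-substrate core; regular spots"),
    "hb-3d" = list(model = "HB", dim = 3, radius_ratio = 1, params = base,
                   note = "3D core; disconnected blobs, no longitudinal order"),
    "hbp-3d" = list(model = "HBP", dim = 3, radius_ratio = 1, params = hbp,
                    note = "carrier P canalizes spots into longitudinal vessels"),
    "hbpm-wide" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                       params = hbpm,
                       note = "wide stem: central SVBs inside an SVB-free annulus"),
    "hbpm-medium" = list(model = "HBPM", dim = 3, radius_ratio = 0.75,
                         params = hbpm, note = "75% diameter: few scattered SVBs"),
    "hbpm-small" = list(model = "HBPM", dim = 3, radius_ratio = 0.37,
                        params = hbpm,
                        note = "37% diameter: inhibitor reaches the center, no SVBs"),
    "hbpm-mhi-dhi" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                          params = utils::modifyList(hbpm, list(k9 = 800, D_M = 15)),
                          note = "high M production, high M diffusion"),
    "hbpm-mhi-dlo" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                          params = utils::modifyList(hbpm, list(k9 = 800, D_M = 3)),
                          note = "high M production, low M diffusion"),
    "hbpm-mlo-dhi" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                          params = utils::modifyList(hbpm, list(k9 = 200, D_M = 15)),
                          note = "low M production, high M diffusion"),
    "hbpm-mlo-dlo" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                          params = utils::modifyList(hbpm, list(k9 = 200, D_M = 3)),
                          note = "low M production, low M diffusion"),
    "eustele" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                     params = utils::modifyList(hbpm, list(k3 = 0.25)),
                     note = "low background B degradation: peripheral bundle ring"),
    "eustele-svb" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                         params = utils::modifyList(hbpm, list(k3 = 0.1, k9 = 200)),
                         note = "lower k3 and reduced M: ring plus central SVBs"),
    "siphonostele-svb" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                              params = utils::modifyList(hbpm, list(k3 = 0)),
                              note = "no background B degradation: continuous cylinder"),
    "atactostele" = list(model = "HBPM", dim = 3, radius_ratio = 1,
                         params = utils::modifyList(hbpm, list(k11 = 0.01)),
                         note = "weak M suppression: scattered bundles throughout"),
    "haplostele" = list(model = "HBPM", dim = 3, radius_ratio = 0.5,
                        params = hbpm,
                        note = "narrow stem: single central vascular rod"),
    "hbpma" = list(model = "HBPMA", dim = 3, radius_ratio = 1,
                   params = hbpma,
                   note = "apical hormone A transported basipetally by P"),
    "hbpma-no-dh" = list(model = "HBPMA", dim = 3, radius_ratio = 1,
                         params = utils::modifyList(hbpma, list(D_H = 0)),
                         note = "source-sink variant with no passive H diffusion")
  )
}

#' List the built-in simulation presets
#'
#' @return A tibble with `name`, `model`, `dim`, `radius_ratio`, `note`.
#' @export
preset_names <- function() {
  tb <- preset_table()
  tibble::tibble(
    name = names(tb),
    model = vapply(tb, `[[`, "", "model"),
    dim = vapply(tb, function(x) as.integer(x$dim), 0L),
    radius_ratio = vapply(tb, `[[`, 0, "radius_ratio"),
    note = vapply(tb, `[[`, "", "note")
  )
}

#' Build a run configuration from a named preset
#'
#' Stem-size presets express their radius as a ratio of `base_radius` (the
#' diameter percentages 100/75/50/37 of the stem-size experiment); the base
#' radius itself is a required user choice, as is the cylinder height for 3D
#' presets. All defaults are written out so a saved config is self-contained.
#' Preset rate constants are calibrated-to-regime defaults (see the package
#' vignette), not values transcribed from any specific experiment.
#'
#' @param name Preset name (see [preset_names()]).
#' @param base_radius Base stem radius in voxels.
#' @param height Cylinder height in voxels (3D presets; default
#'   `2 * base_radius`).
#' @param seed Run seed.
#' @param max_events,max_time Stop condition (at least one finite).
#' @param snapshot_dt Snapshot cadence in simulation time.
#' @param overrides Named list of parameter overrides.
#' @return A `vp_config` list.
#' @export
preset_config <- function(name, base_radius, height = NULL, seed = 1,
                          max_events = Inf, max_time = 40,
                          snapshot_dt = NULL, overrides = list()) {
  tb <- preset_table()
  if (!name %in% names(tb)) {
    stop(sprintf("unknown preset '%s'; see preset_names().", name),
         call. = FALSE)
  }
  check_radius(base_radius)
  p <- tb[[name]]
  radius <- max(1L, as.integer(round(p$radius_ratio * base_radius)))
  if (p$dim == 3 && is.null(height)) height <- 2L * as.integer(base_radius)
  params <- utils::modifyList(p$params, as.list(overrides))
  config <- list(
    preset = name,
    model = p$model,
    feedback = "repression",
    geometry = list(dim = p$dim, radius = radius,
                    height = if (p$dim == 3) as.integer(height) else 1L,
                    shell_fraction = 0.04),
    params = params,
    stop = list(max_events = max_events, max_time = max_time),
    seed = as.integer(seed),
    snapshot = list(every_events = NULL,
                    dt = snapshot_dt %||%
                      (if (is.finite(max_time)) max_time / 8 else NULL)),
    analysis = list(threshold = NULL, threshold_fraction = 0.5,
                    connectivity = "face", min_size = 1)
  )
  structure(config, class = "vp_config")
}

#' Validate a run configuration
#'
#' Checks field presence, geometry sanity, and that the model factory accepts
#' the parameter map (a missing rate constant is reported by name).
#'
#' @param config A `vp_config` (or plain list with the same fields).
#' @return The config, invisibly, on success.
#' @export
validate_config <- function(config) {
  needed <- c("model", "geometry", "stop", "seed")
  if (!identical(config$model, "custom")) needed <- c(needed, "params")
  absent <- setdiff(needed, names(config))
  if (length(absent)) {
    stop(sprintf("config is missing field(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (identical(config$model, "custom") && is.null(config$network)) {
    stop("config with model 'custom' needs an inline `network` block.",
         call. = FALSE)
  }
  g <- config$geometry
  if (!g$dim %in% c(2, 3)) stop("geometry$dim must be 2 or 3.", call. = FALSE)
  check_radius(g$radius)
  check_shell_fraction(g$shell_fraction %||% 0.04)
  me <- config$stop$max_events %||% Inf
  mt <- config$stop$max_time %||% Inf
  if (me < 0 || mt < 0 || (!is.finite(me) && !is.finite(mt))) {
    stop("config$stop must set a finite, non-negative max_events or max_time.",
         call. = FALSE)
  }
  if (identical(config$model, "custom")) {
    network_from_config(config$network)
  } else {
    make_model(config$model, config$params,
               feedback = config$feedback %||% "repression")
  }
  invisible(config)
}

#' Build a reaction network from its configuration description
#'
#' Arbitrary stochastic reaction-diffusion systems beyond the named model
#' families can be declared directly in a run config: a `species` list
#' (`name`, `D`), a `reactions` list (`label`, `reactants`/`products` as
#' name-count maps, `k`, optional `restriction`), and an optional `transport`
#' list (`carrier`, `cargo`, `alpha`, optional `directionality`).
#'
#' @param spec A list as found in `config$network`.
#' @return A `vp_network`.
#' @export
network_from_config <- function(spec) {
  species <- tibble::tibble(
    name = vapply(spec$species, `[[`, "", "name"),
    D = vapply(spec$species, function(s) as.numeric(s$D), 0)
  )
  rx <- lapply(spec$reactions, function(r) {
    reaction(r$label,
             reactants = unlist(r$reactants),
             products = unlist(r$products),
             k = r$k,
             restriction = r$restriction %||% "all")
  })
  tr <- lapply(spec$transport %||% list(), function(t) {
    transport_rule(t$carrier, t$cargo, t$alpha,
                   directionality = t$directionality %||%
                     "symmetric_longitudinal")
  })
  reaction_network(species, rx, tr, model = spec$name %||% "custom")
}

#' Build lattice and network from a configuration
#'
#' @param config A validated `vp_config`.
#' @return A list with elements `lattice` and `network`.
#' @export
config_objects <- function(config) {
  g <- config$geometry
  lat <- if (g$dim == 2) {
    lattice_disc(g$radius, g$shell_fraction %||% 0.04)
  } else {
    lattice_cylinder(g$radius, g$height, g$shell_fraction %||% 0.04)
  }
  net <- if (identical(config$model, "custom")) {
    network_from_config(config$network)
  } else {
    make_model(config$model, config$params,
               feedback = config$feedback %||% "repression")
  }
  list(lattice = lat, network = net)
}

#' Execute a run configuration
#'
#' @param config A `vp_config`.
#' @param log_events Record the event log.
#' @return A `vp_trajectory`.
#' @export
run_config <- function(config, log_events = FALSE) {
  validate_config(config)
  ob <- config_objects(config)
  simulate_ssa(ob$network, ob$lattice, seed = config$seed,
               max_events = config$stop$max_events %||% Inf,
               max_time = config$stop$max_time %||% Inf,
               snapshot_every = config$snapshot$every_events,
               snapshot_dt = config$snapshot$dt,
               log_events = log_events)
}

# recursively sort names so the hash is stable under key reordering
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Stable hash of a run configuration
#'
#' Invariant under cosmetic key reordering; sensitive to every semantic
#' field.
#'
#' @param config A `vp_config` or plain list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(canonicalize(unclass(config)))
}

#' Read / write a run configuration as YAML
#'
#' Configs round-trip losslessly (`Inf` stop conditions are encoded as the
#' string `"Inf"`).
#'
#' @param config A `vp_config`.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `vp_config`.
#' @export
write_run_config <- function(config, path) {
  enc <- unclass(config)
  enc$stop <- lapply(enc$stop, function(v)
    if (is.numeric(v) && !is.finite(v)) "Inf" else v)
  yaml::write_yaml(enc, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$stop <- lapply(x$stop, function(v) if (identical(v, "Inf")) Inf else v)
  structure(x, class = "vp_config")
}
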