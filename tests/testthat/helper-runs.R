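# Shared, lazily computed simulation products for the heavier checks.
# Cached in an environment so several test blocks can reuse one run.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# 2D HB diffusion sweep on an R = 30 disc: D_H = 0.05, ratios 10 and 1000,
# three replicates, absolute spot threshold 3 H* = 120 molecules/voxel.
acceptance_sweep <- function() {
  cached("sweep", sweep_diffusion(
    radius = 30, D_H_values = 0.05, ratio_values = c(10, 1000),
    params = base_hb(), replicates = 3, max_time = 40, snapshot_dt = 10,
    threshold = spot_threshold(base_hb()), seed = 101
  ))
}

# HBPM stem-size experiment: identical kinetics, radius ratio 1.0 vs 0.37
# (base radius 14), three seeds, analyzed as 2D cross-sections.
acceptance_stem_sizes <- function() {
  cached("stems", {
    p <- c(base_hb(), list(D_H = 0.05, D_B = 50,
                           k6 = 0.05, k7 = 1, alpha = 1,
                           k9 = 400, k10 = 0.05, k11 = 0.05, D_M = 7.5))
    thr <- spot_threshold(p)
    net <- make_model("HBPM", p)
    out <- list()
    for (R in c(14, 5)) {
      lat <- lattice_disc(R)
      interior <- !shell_mask(lat)
      for (seed in 1:3) {
        traj <- simulate_ssa(net, lat, seed = seed, max_time = 40,
                             snapshot_dt = 10)
        ps <- persistent_spots(traj, "H", threshold = thr, n_last = 3)
        n_int <- if (nrow(ps)) {
          sum(vapply(ps$voxels, function(v) all(interior[v]), TRUE))
        } else 0L
        out[[length(out) + 1L]] <- tibble::tibble(
          radius = R, seed = seed, interior_spots = n_int)
      }
    }
    dplyr::bind_rows(out)
  })
}

# facilitated-transport hop experiment at fixed carrier counts
eq3_hop_fractions <- function(n_P_values = c(0, 3, 12, 60),
                              max_events = 6e4) {
  cached(paste0("eq3-", paste(n_P_values, collapse = "_")), {
    lat <- lattice_cylinder(4, 9)
    interior6 <- rowSums(lat$nbr != 0) == 6
    purrr::map_dfr(n_P_values, function(nP) {
      net <- reaction_network(
        tibble::tibble(name = c("Hc", "P"), D = c(1, 0)),
        transport = list(transport_rule("P", "Hc", alpha = 1)))
      counts <- matrix(0L, n_voxels(lat), 2,
                       dimnames = list(NULL, c("Hc", "P")))
      counts[, "Hc"] <- 20L
      counts[, "P"] <- as.integer(nP)
      st <- init_state(lat, net, counts)
      traj <- simulate_ssa(net, lat, seed = 1000 + nP,
                           max_events = max_events, init = st,
                           log_events = TRUE)
      lg <- traj$event_log
      hops <- lg[interior6[lg$voxel], ]
      tibble::tibble(n_P = nP, n_hops = nrow(hops),
                     frac_long = mean(hops$dir %in% c("+z", "-z")))
    })
  })
}
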