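#' Detect supra-threshold spots (simulated vascular bundles)
#'
#' Connected components of the voxel set `{count > threshold}` on a 2D disc
#' (or one z-slice of a cylinder). Spots are maximal connected components
#' under the chosen connectivity; each is summarized by its voxel count, its
#' centroid, its equivalent diameter `2 * sqrt(area / pi)` (the diameter of
#' the circle with the same area, since "diameter" is otherwise undefined for
#' irregular regions), and its maximum count.
#'
#' @param field Numeric vector of per-voxel counts (length `n_voxels`), e.g.
#'   from [species_field()].
#' @param lattice The `vp_lattice` the field lives on.
#' @param threshold Spots are voxels with `count > threshold` (strict).
#' @param connectivity `"face"` (4-neighbor, matching the diffusion topology;
#'   default) or `"face_and_diagonal"` (8-neighbor).
#' @param z For a 3D lattice, the z-slice to analyze (0-based); required in
#'   3D, ignored in 2D.
#' @return A `vp_spots` tibble, one row per spot: `spot_id`, `n_voxels`,
#'   `centroid_x`, `centroid_y`, `diameter`, `max_count`, plus a `voxels`
#'   list-column of member voxel indices. Attributes: `threshold`,
#'   `connectivity`, `n_spots`, `mean_diameter`, `median_diameter`.
#' @examples
#' d <- lattice_disc(10)
#' f <- rep(0, n_voxels(d))
#' detect_spots(f, d, threshold = 1)   # zero rows
#' @export
detect_spots <- function(field, lattice, threshold,
                         connectivity = c("face", "face_and_diagonal"),
                         z = NULL) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(lattice, "vp_lattice"), length(field) == n_voxels(lattice))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a positive scalar.", call. = FALSE)
  }
  if (lattice$dim == 3L && is.null(z)) {
    stop("3D field: select a z-slice with `z =` (0-based layer index).",
         call. = FALSE)
  }
  in_slice <- if (lattice$dim == 3L) lattice$voxels$z == z else
    rep(TRUE, n_voxels(lattice))
  hot <- which(in_slice & field > threshold)
  empty <- tibble::tibble(spot_id = integer(), n_voxels = integer(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          diameter = numeric(), max_count = numeric(),
                          voxels = list())
  if (length(hot) == 0L) {
    return(spot_summary(empty, threshold, connectivity))
  }
  pos <- match(seq_len(n_voxels(lattice)), hot) # voxel -> position in hot
  edges <- NULL
  # in-plane face neighbors (+x, -x, +y, -y columns)
  for (d in 1:4) {
    nb <- lattice$nbr[hot, d]
    ok <- nb != 0L & !is.na(pos[pmax(nb, 1L)]) & nb > 0L
    ok[ok] <- !is.na(pos[nb[ok]])
    if (any(ok)) {
      edges <- rbind(edges, cbind(seq_along(hot)[ok], pos[nb[ok]]))
    }
  }
  if (connectivity == "face_and_diagonal") {
    vx <- lattice$voxels
    keymap <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(hot)) {
      assign(paste(vx$x[hot[i]], vx$y[hot[i]], sep = ","), i, envir = keymap)
    }
    for (off in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      keys <- paste(vx$x[hot] + off[1], vx$y[hot] + off[2], sep = ",")
      j <- vapply(keys, function(kk)
        if (exists(kk, envir = keymap, inherits = FALSE))
          get(kk, envir = keymap) else NA_integer_, 0L, USE.NAMES = FALSE)
      ok <- !is.na(j)
      if (any(ok)) edges <- rbind(edges, cbind(seq_along(hot)[ok], j[ok]))
    }
  }
  g <- igraph::make_empty_graph(n = length(hot), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  vx <- lattice$voxels
  spots <- tibble::tibble(member = memb, voxel = hot,
                          x = vx$x[hot], y = vx$y[hot], count = field[hot])
  out <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(spots, .data$member),
    n_voxels = dplyr::n(),
    centroid_x = mean(.data$x),
    centroid_y = mean(.data$y),
    diameter = 2 * sqrt(dplyr::n() / pi),
    max_count = max(.data$count),
    voxels = list(.data$voxel),
    .groups = "drop"
  ), dplyr::desc(.data$n_voxels))
  out$spot_id <- seq_len(nrow(out))
  out <- out[, c("spot_id", "n_voxels", "centroid_x", "centroid_y",
                 "diameter", "max_count", "voxels")]
  spot_summary(out, threshold, connectivity)
}

spot_summary <- function(tbl, threshold, connectivity) {
  structure(tbl, threshold = threshold, connectivity = connectivity,
            n_spots = nrow(tbl),
            mean_diameter = if (nrow(tbl)) mean(tbl$diameter) else NA_real_,
            median_diameter = if (nrow(tbl)) stats::median(tbl$diameter)
            else NA_real_,
            class = c("vp_spots", class(tbl)))
}

#' @export
glance.vp_spots <- function(x, ...) {
  tibble::tibble(n_spots = attr(x, "n_spots"),
                 mean_diameter = attr(x, "mean_diameter"),
                 median_diameter = attr(x, "median_diameter"),
                 threshold = attr(x, "threshold"),
                 connectivity = attr(x, "connectivity"))
}

#' Spot threshold anchored at the homogeneous steady state
#'
#' An absolute molecules-per-voxel spot criterion stated as a multiple of the
#' deterministic homogeneous activator level `H*` of the kinetics. An
#' unpatterned stochastic field fluctuates around `H*`, so a threshold a few
#' multiples above it is crossed persistently only where the Turing
#' instability has concentrated the activator.
#'
#' @param params Kinetic constants `k1..k5`.
#' @param multiple Multiple of `H*` (default 3).
#' @return Positive scalar threshold.
#' @export
spot_threshold <- function(params, multiple = 3) {
  ss <- homogeneous_steady_state(params)
  multiple * max(ss$H)
}

#' Threshold as a fraction of the field maximum
#'
#' The absolute spot criterion (counts above a fixed number of molecules per
#' voxel) is scale-dependent; when runs are scaled down the threshold is
#' restated as a fraction of the realized field maximum.
#'
#' @param field Numeric per-voxel counts.
#' @param fraction Fraction of `max(field)` (default 0.5).
#' @return Positive scalar threshold.
#' @export
threshold_from_field <- function(field, fraction = 0.5) {
  m <- max(field)
  if (m <= 0) return(Inf)
  fraction * m
}

#' Spots that persist across the last snapshots of a trajectory
#'
#' Transient noise excursions can exceed a relative threshold in an
#' unpatterned field; a vascular bundle, by contrast, occupies the same
#' voxels over time. This intersects the supra-threshold masks of the last
#' `n_last` snapshots and keeps connected components with at least `min_size`
#' voxels.
#'
#' @param trajectory A `vp_trajectory` with at least `n_last` snapshots.
#' @param species Species to analyze (default `"H"`).
#' @param threshold Absolute threshold; default `NULL` means
#'   `threshold_fraction` of the final-snapshot maximum.
#' @param threshold_fraction Used when `threshold` is `NULL` (default 0.5).
#' @param min_size Minimum persistent-component size in voxels (default 1:
#'   at desk scale spots can be near lattice-scale, and persistence across
#'   snapshots is the primary noise filter).
#' @param n_last Number of trailing snapshots to intersect (default 2).
#' @param z z-slice for 3D lattices.
#' @return A `vp_spots` summary of the persistent components.
#' @export
persistent_spots <- function(trajectory, species = "H", threshold = NULL,
                             threshold_fraction = 0.5, min_size = 1,
                             n_last = 2, z = NULL) {
  stopifnot(inherits(trajectory, "vp_trajectory"))
  snaps <- trajectory$snapshots
  if (length(snaps) < n_last) {
    stop(sprintf("need at least %d snapshots; have %d.", n_last,
                 length(snaps)), call. = FALSE)
  }
  fields <- lapply(utils::tail(snaps, n_last), species_field,
                   species = species)
  if (is.null(threshold)) {
    threshold <- threshold_from_field(fields[[length(fields)]],
                                      threshold_fraction)
  }
  inter <- Reduce(pmin, fields) # voxelwise min across snapshots
  spots <- detect_spots(inter, trajectory$lattice, threshold, z = z)
  keep <- spots$n_voxels >= min_size
  spot_summary(spots[keep, ], attr(spots, "threshold"),
               attr(spots, "connectivity"))
}

#' Radial zonation profile and SVB-free annulus width
#'
#' Bins the field by radial distance and locates the zones seen in stems with
#' supplemental vascular bundles: zone A (the cortical shell, radial width
#' `shell_fraction * R`), zone B (the annulus immediately inside the shell
#' that contains no spot voxels), and zone C (the central region containing
#' spots). Zone B's width is `r_shell - max(r)` over supra-threshold voxels
#' interior to the shell boundary `r_shell = (1 - shell_fraction) * R`
#' (equal to `r_shell` when the interior has no spots at all).
#'
#' @param field Numeric per-voxel counts.
#' @param lattice A `vp_lattice`.
#' @param threshold Spot threshold (strict `>`).
#' @param bin_width Radial bin width in voxels (default 1).
#' @param z z-slice for 3D lattices.
#' @return A `vp_zonation`: tibble of radial bins (`r_mid`, `mean_count`,
#'   `n_voxels`, `any_spot`) with attributes `zone_a_width`, `zone_b_width`,
#'   `zone_c_radius`, `r_shell`, `threshold`.
#' @export
zonation <- function(field, lattice, threshold, bin_width = 1, z = NULL) {
  stopifnot(inherits(lattice, "vp_lattice"))
  in_slice <- if (lattice$dim == 3L) {
    if (is.null(z)) stop("3D field: select a z-slice with `z =`.",
                         call. = FALSE)
    lattice$voxels$z == z
  } else rep(TRUE, n_voxels(lattice))
  r <- lattice$voxels$r[in_slice]
  f <- field[in_slice]
  R <- lattice$radius
  breaks <- seq(0, R + bin_width, by = bin_width)
  bin <- cut(r, breaks = breaks, include.lowest = TRUE, right = FALSE)
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, r = r, f = f), .data$bin),
    r_mid = mean(.data$r), mean_count = mean(.data$f),
    n_voxels = dplyr::n(), any_spot = any(.data$f > threshold),
    .groups = "drop")
  r_shell <- (1 - lattice$shell_fraction) * R
  interior_spot_r <- r[f > threshold & r < r_shell]
  zone_b <- if (length(interior_spot_r)) max(0, r_shell - max(interior_spot_r))
  else r_shell
  zone_c <- if (length(interior_spot_r)) max(interior_spot_r) else 0
  structure(prof, zone_a_width = R - r_shell, zone_b_width = zone_b,
            zone_c_radius = zone_c, r_shell = r_shell, threshold = threshold,
            class = c("vp_zonation", class(prof)))
}

#' @export
glance.vp_zonation <- function(x, ...) {
  tibble::tibble(zone_a_width = attr(x, "zone_a_width"),
                 zone_b_width = attr(x, "zone_b_width"),
                 zone_c_radius = attr(x, "zone_c_radius"),
                 r_shell = attr(x, "r_shell"),
                 threshold = attr(x, "threshold"))
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Assess pattern stationarity over a snapshot window
#'
#' Operationalizes "the pattern did not change substantially": over the last
#' `window` snapshots, the spot count must be constant and the Jaccard
#' similarity of consecutive supra-threshold masks at least `jaccard_min`.
#'
#' @param trajectory A `vp_trajectory` with at least 2 snapshots in the
#'   window.
#' @param species Species to analyze (default `"H"`).
#' @param threshold Spot threshold.
#' @param window Number of trailing snapshots to assess (default 3, floored
#'   at 2).
#' @param jaccard_min Minimum consecutive-mask Jaccard similarity (default
#'   0.9).
#' @param z z-slice for 3D lattices.
#' @return A list: `stationary` (logical) and `diagnostics`, a tibble with
#'   one row per snapshot in the window (`time`, `n_spots`,
#'   `jaccard_to_prev`).
#' @export
stationarity <- function(trajectory, species = "H", threshold, window = 3,
                         jaccard_min = 0.9, z = NULL) {
  stopifnot(inherits(trajectory, "vp_trajectory"))
  n <- length(trajectory$snapshots)
  window <- max(2L, min(window, n))
  if (n < 2L) stop("need at least 2 snapshots to assess stationarity.",
                   call. = FALSE)
  idx <- seq.int(n - window + 1L, n)
  fields <- lapply(trajectory$snapshots[idx], species_field, species = species)
  masks <- lapply(fields, function(f) f > threshold)
  nspots <- vapply(fields, function(f)
    attr(detect_spots(f, trajectory$lattice, threshold, z = z), "n_spots"),
    0L)
  jc <- c(NA_real_, vapply(seq_along(masks)[-1], function(i)
    jaccard(masks[[i - 1L]], masks[[i]]), 0))
  diag <- tibble::tibble(time = trajectory$snap_times[idx], n_spots = nspots,
                         jaccard_to_prev = jc)
  list(stationary = length(unique(nspots)) == 1L &&
         all(jc[-1] >= jaccard_min),
       diagnostics = diag)
}

#' Diffusion-rate sweep of the 2D activator-substrate model
#'
#' Runs the HB model on a disc for every combination of `D_H` and
#' `D_B / D_H` ratio, with `replicates` independent seeded runs per cell,
#' and summarizes persistent spot statistics per run -- the in-silico
#' experiment relating diffusion rates to bundle size and density.
#'
#' @param radius Disc radius in voxels.
#' @param D_H_values Activator diffusion rates (positive).
#' @param ratio_values `D_B / D_H` ratios (positive).
#' @param params Kinetic constants `k1..k5` shared by every cell.
#' @param replicates Runs per cell (default 3).
#' @param max_time,max_events Stop condition per run.
#' @param seed Base seed; replicate seeds are derived deterministically and
#'   recorded in the output.
#' @param snapshot_dt Snapshot cadence used for persistence checking.
#' @param threshold Absolute spot threshold (molecules/voxel) applied to every
#'   run; default `NULL` falls back to `threshold_fraction` of each run's
#'   final field maximum. See [spot_threshold()] for the steady-state-anchored
#'   choice.
#' @param threshold_fraction Spot threshold as a fraction of each run's final
#'   field maximum (used when `threshold` is `NULL`).
#' @param min_size Minimum persistent-spot size in voxels.
#' @return A tibble with one row per (D_H, ratio, replicate): the recorded
#'   `seed`, `n_spots`, `mean_diameter`, `median_diameter`, `max_count`,
#'   `events`, `time`.
#' @export
sweep_diffusion <- function(radius, D_H_values, ratio_values, params,
                            replicates = 3, max_time = Inf, max_events = Inf,
                            seed = 1, snapshot_dt = NULL, threshold = NULL,
                            threshold_fraction = 0.5, min_size = 1) {
  if (any(D_H_values <= 0) || any(ratio_values <= 0)) {
    stop("diffusion rates and ratios must be positive.", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1.", call. = FALSE)
  grid <- tidyr::expand_grid(D_H = sort(D_H_values),
                             ratio = sort(ratio_values),
                             replicate = seq_len(replicates))
  grid$seed <- as.integer(seed) + seq_len(nrow(grid)) - 1L
  lat <- lattice_disc(radius)
  if (is.null(snapshot_dt) && is.finite(max_time)) {
    snapshot_dt <- max_time / 10
  }
  purrr::pmap_dfr(grid, function(D_H, ratio, replicate, seed) {
    net <- make_model("HB", c(params, list(D_H = D_H, D_B = ratio * D_H)))
    traj <- simulate_ssa(net, lat, seed = seed, max_time = max_time,
                         max_events = max_events, snapshot_dt = snapshot_dt)
    sp <- persistent_spots(traj, "H", threshold = threshold,
                           threshold_fraction = threshold_fraction,
                           min_size = min_size)
    tibble::tibble(D_H = D_H, ratio = ratio, D_B = ratio * D_H,
                   replicate = replicate, seed = seed,
                   n_spots = attr(sp, "n_spots"),
                   mean_diameter = attr(sp, "mean_diameter"),
                   median_diameter = attr(sp, "median_diameter"),
                   max_count = if (nrow(sp)) max(sp$max_count) else NA_real_,
                   events = traj$state$events, time = traj$state$time)
  })
}
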