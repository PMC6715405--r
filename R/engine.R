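#' @useDynLib vascpat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# encode a vp_network into the flat arrays the C++ core consumes
encode_network <- function(network) {
  sp <- network$species$name
  n_sp <- length(sp)
  n_rx <- length(network$reactions)
  stoich_r <- matrix(0L, n_rx, n_sp, dimnames = list(NULL, sp))
  stoich_p <- matrix(0L, n_rx, n_sp, dimnames = list(NULL, sp))
  k <- numeric(n_rx)
  restr <- integer(n_rx)
  codes <- c(all = 0L, cortical_shell = 1L, apex_layer = 2L)
  for (i in seq_len(n_rx)) {
    r <- network$reactions[[i]]
    stoich_r[i, names(r$reactants)] <- r$reactants
    stoich_p[i, names(r$products)] <- r$products
    k[i] <- r$k
    restr[i] <- codes[[r$restriction]]
  }
  n_tr <- length(network$transport)
  tr_carrier <- tr_cargo <- tr_dir <- integer(n_tr)
  tr_alpha <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    tr <- network$transport[[i]]
    tr_carrier[i] <- match(tr$carrier, sp)
    tr_cargo[i] <- match(tr$cargo, sp)
    tr_alpha[i] <- tr$alpha
    tr_dir[i] <- if (tr$directionality == "basipetal_only") 1L else 0L
  }
  list(species = sp, D = network$species$D,
       stoich_r = stoich_r, stoich_p = stoich_p, k = k, restr = restr,
       tr_carrier = tr_carrier, tr_cargo = tr_cargo, tr_alpha = tr_alpha,
       tr_dir = tr_dir)
}

#' Initial state of a stochastic simulation
#'
#' All counts start at zero (the source channels bootstrap the system) unless
#' `counts` supplies a full matrix.
#'
#' @param lattice A `vp_lattice`.
#' @param network A `vp_network`.
#' @param counts Optional integer matrix, `n_voxels x n_species` (columns in
#'   `network$species$name` order).
#' @return A `vp_state`: counts matrix plus `time` and `events` scalars.
#' @export
init_state <- function(lattice, network, counts = NULL) {
  sp <- network$species$name
  if (is.null(counts)) {
    counts <- matrix(0L, n_voxels(lattice), length(sp),
                     dimnames = list(NULL, sp))
  } else {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == n_voxels(lattice), ncol(counts) == length(sp))
    if (any(counts < 0)) stop("initial counts must be >= 0.", call. = FALSE)
    storage.mode(counts) <- "integer"
    colnames(counts) <- sp
  }
  structure(list(counts = counts, time = 0, events = 0),
            class = "vp_state")
}

#' @method print vp_state
#' @export
print.vp_state <- function(x, ...) {
  cat(sprintf("<vp_state> t = %.6g, %s events, totals: %s\n",
              x$time, format(x$events, big.mark = ","),
              paste(sprintf("%s=%g", colnames(x$counts), colSums(x$counts)),
                    collapse = ", ")))
  invisible(x)
}

ssa_config_hash <- function(network, lattice, init_counts) {
  canon <- list(
    species = as.list(network$species[order(network$species$name), ]),
    reactions = lapply(network$reactions, function(r)
      r[c("label", "reactants", "products", "k", "restriction")]),
    transport = lapply(network$transport, unclass),
    dim = lattice$dim, radius = lattice$radius, height = lattice$height,
    shell_fraction = lattice$shell_fraction,
    init = as.integer(init_counts)
  )
  rlang::hash(canon)
}

#' Run an exact stochastic simulation
#'
#' Generates one realization of the reaction-diffusion master equation on the
#' lattice: per-voxel mass-action reactions, nearest-neighbor diffusion hops
#' at per-direction rate `D * n`, and carrier-facilitated longitudinal
#' transport. Event selection is the direct Gillespie method over a per-voxel
#' aggregated propensity tree, so the sampler is exact. The run stops at
#' whichever of `max_events` / `max_time` is reached first, or cleanly when
#' the system reaches an absorbing state (total propensity zero).
#'
#' @param network A `vp_network`.
#' @param lattice A `vp_lattice`.
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it. Required for a fresh run.
#' @param max_events Stop after this many events (may be `Inf`).
#' @param max_time Stop at this simulation time (may be `Inf`).
#' @param snapshot_every Record a full state snapshot every this many events
#'   (`NULL` to disable).
#' @param snapshot_dt Record a snapshot at fixed simulation-time cadence
#'   (`NULL` to disable). Time-cadence snapshots sample the jump process
#'   correctly (the state holds between events).
#' @param init Optional `vp_state` to start from (default: all-zero counts).
#' @param log_events Record an event log (time, voxel, channel) for audit;
#'   off by default. Capped at `max_log` rows.
#' @param max_log Event-log row cap.
#' @return A `vp_trajectory`: final `state`, `snapshots` (list of count
#'   matrices) with `snap_times`/`snap_events`, the `event_log` tibble (if
#'   requested), the seed, the post-run RNG state (for [resume_ssa()]), a
#'   config hash, and the stop `reason`.
#' @examples
#' hb <- make_model("HB", list(k1 = 0.0125, k2 = 30, k3 = 1.25, k4 = 10,
#'                             k5 = 2.5, D_H = 0.05, D_B = 50))
#' traj <- simulate_ssa(hb, lattice_disc(8), seed = 1, max_events = 2e4)
#' traj$state
#' @export
simulate_ssa <- function(network, lattice, seed = NULL, max_events = Inf,
                         max_time = Inf, snapshot_every = NULL,
                         snapshot_dt = NULL, init = NULL, log_events = FALSE,
                         max_log = 2e6) {
  stopifnot(inherits(network, "vp_network"), inherits(lattice, "vp_lattice"))
  if (!is.finite(max_events) && !is.finite(max_time)) {
    stop("supply a finite `max_events` or `max_time` stop condition.",
         call. = FALSE)
  }
  if (max_events < 0 || max_time < 0) {
    stop("stop conditions must be non-negative.", call. = FALSE)
  }
  bad <- unlist(lapply(network$reactions, function(r) {
    if (r$restriction == "apex_layer" && lattice$dim != 3L) r$label else NULL
  }))
  if (length(bad)) {
    stop(sprintf("reaction(s) %s are apex-restricted but the lattice is 2D.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(init)) init <- init_state(lattice, network)
  if (is.null(seed)) stop("`seed` is required for a fresh run.", call. = FALSE)
  set.seed(as.integer(seed))
  run_ssa_internal(network, lattice, init, max_events, max_time,
                   snapshot_every, snapshot_dt, log_events, max_log,
                   seed = as.integer(seed))
}

run_ssa_internal <- function(network, lattice, init, max_events, max_time,
                             snapshot_every, snapshot_dt, log_events, max_log,
                             seed, prior = NULL) {
  enc <- encode_network(network)
  res <- .ssa_run_cpp(
    counts = init$counts, nbr = lattice$nbr, region = region_codes(lattice),
    apex = lattice$voxels$apex, D = enc$D, stoich_r = enc$stoich_r,
    stoich_p = enc$stoich_p, k = enc$k, restr = enc$restr,
    tr_carrier = enc$tr_carrier, tr_cargo = enc$tr_cargo,
    tr_alpha = enc$tr_alpha, tr_dir = enc$tr_dir,
    start_time = init$time, start_events = init$events,
    max_events = max_events, max_time = max_time,
    snapshot_every = if (is.null(snapshot_every)) 0 else snapshot_every,
    snapshot_dt = if (is.null(snapshot_dt)) 0 else snapshot_dt,
    log_events = log_events, max_log = max_log
  )
  state <- structure(list(
    counts = structure(res$counts, dimnames = list(NULL, enc$species)),
    time = res$time, events = res$events
  ), class = "vp_state")
  log <- NULL
  if (log_events) {
    log <- tibble::tibble(
      time = res$event_log$time,
      voxel = res$event_log$voxel,
      type = c("reaction", "diffusion", "transport")[res$event_log$type + 1L],
      channel = dplyr::case_when(
        res$event_log$type == 0L ~ vapply(network$reactions, `[[`, "",
                                          "label")[res$event_log$index],
        res$event_log$type == 1L ~ enc$species[res$event_log$index],
        TRUE ~ paste0("transport:",
                      vapply(network$transport, `[[`, "",
                             "cargo")[res$event_log$index])
      ),
      dir = c("+x", "-x", "+y", "-y", "+z", "-z", NA)[
        ifelse(res$event_log$dir == 0L, 7L, res$event_log$dir)]
    )
    if (res$log_truncated) {
      attr(log, "truncated") <- TRUE
      warning("event log truncated at `max_log` rows.", call. = FALSE)
    }
  }
  snaps <- lapply(res$snapshots, function(m) {
    colnames(m) <- enc$species
    m
  })
  if (!is.null(prior)) {
    snaps <- c(prior$snapshots, snaps)
    res$snap_times <- c(prior$snap_times, res$snap_times)
    res$snap_events <- c(prior$snap_events, res$snap_events)
  }
  structure(list(
    state = state, snapshots = snaps, snap_times = res$snap_times,
    snap_events = res$snap_events, event_log = log, reason = res$reason,
    seed = seed, rng_state = .Random.seed,
    config_hash = ssa_config_hash(network, lattice,
                                  if (is.null(prior)) init$counts
                                  else prior$init_counts),
    init_counts = if (is.null(prior)) init$counts else prior$init_counts,
    network = network, lattice = lattice,
    settings = list(snapshot_every = snapshot_every, snapshot_dt = snapshot_dt,
                    log_events = log_events, max_log = max_log)
  ), class = "vp_trajectory")
}

#' @method print vp_trajectory
#' @export
print.vp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<vp_trajectory> model %s, seed %d: t = %.6g, %s events (%s), %d snapshot(s)\n",
    x$network$model, x$seed, x$state$time,
    format(x$state$events, big.mark = ","), x$reason, length(x$snapshots)))
  invisible(x)
}

#' Continue a stochastic simulation from its stored RNG state
#'
#' The continuation is event-for-event identical to an uninterrupted run with
#' the same seed, because the trajectory carries the generator state and the
#' engine consumes random numbers in a fixed order.
#'
#' @param trajectory A `vp_trajectory` (possibly read back from a checkpoint
#'   file, see [read_checkpoint()]).
#' @param max_events Additional events to simulate (may be `Inf` if
#'   `max_time` is finite).
#' @param max_time Absolute simulation time to stop at.
#' @param network,lattice Optional; must hash-match the checkpointed
#'   configuration if supplied (a mismatch is an error, not a silent restart).
#' @return A `vp_trajectory` continuing the input.
#' @export
resume_ssa <- function(trajectory, max_events = Inf, max_time = Inf,
                       network = NULL, lattice = NULL) {
  stopifnot(inherits(trajectory, "vp_trajectory"))
  if (!is.finite(max_events) && !is.finite(max_time)) {
    stop("supply a finite `max_events` or `max_time` stop condition.",
         call. = FALSE)
  }
  network <- network %||% trajectory$network
  lattice <- lattice %||% trajectory$lattice
  hash <- ssa_config_hash(network, lattice, trajectory$init_counts)
  if (!identical(hash, trajectory$config_hash)) {
    stop("configuration hash mismatch: cannot resume with an altered model.",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", trajectory$rng_state, envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  out <- run_ssa_internal(
    network, lattice, trajectory$state, max_events, max_time,
    trajectory$settings$snapshot_every, trajectory$settings$snapshot_dt,
    trajectory$settings$log_events, trajectory$settings$max_log,
    seed = trajectory$seed,
    prior = list(snapshots = trajectory$snapshots,
                 snap_times = trajectory$snap_times,
                 snap_events = trajectory$snap_events,
                 init_counts = trajectory$init_counts)
  )
  on.exit()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory checkpoint
#'
#' The checkpoint is a single self-describing file holding the counts array,
#' simulation time, event counter, random-generator state, and the config
#' hash, so a resumed process reproduces the original trajectory
#' event-for-event.
#'
#' @param trajectory A `vp_trajectory`.
#' @param path File path.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   returns the `vp_trajectory`.
#' @export
write_checkpoint <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "vp_trajectory"))
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "vp_trajectory")) {
    stop("file does not contain a vascpat checkpoint.", call. = FALSE)
  }
  x
}

#' Probability that a carried molecule leaving its voxel moves longitudinally
#'
#' For a cargo molecule in an interior voxel with `carrier_count` carrier
#' molecules, the probability that a movement event is longitudinal is
#' \deqn{(2 D + \alpha P) / (6 D + \alpha P),}
#' i.e. the passive baseline 1/3 plus a Michaelis-Menten excess with
#' Vmax = 2/3 and half-saturation at `6 D / alpha` carrier molecules.
#'
#' @param carrier_count Non-negative carrier count(s) `P` in the voxel.
#' @param D_cargo Passive per-direction diffusion rate of the cargo (> 0).
#' @param alpha Carrier affinity (>= 0).
#' @return Probability in `[1/3, 1)` (vectorized over `carrier_count`).
#' @export
longitudinal_move_probability <- function(carrier_count, D_cargo = 1,
                                          alpha = 1) {
  if (!is.numeric(D_cargo) || length(D_cargo) != 1L || D_cargo <= 0) {
    stop("`D_cargo` must be a positive scalar.", call. = FALSE)
  }
  if (alpha < 0) stop("`alpha` must be >= 0.", call. = FALSE)
  if (any(carrier_count < 0)) stop("`carrier_count` must be >= 0.",
                                   call. = FALSE)
  (2 * D_cargo + alpha * carrier_count) / (6 * D_cargo + alpha * carrier_count)
}

#' Per-direction movement propensities of one species in one voxel
#'
#' Passive diffusion contributes rate `D * n` toward each in-domain face
#' neighbor. For a transported cargo, the facilitated propensity
#' `alpha * n_carrier * n_cargo` is added on the longitudinal axis: split
#' equally between up and down for symmetric transport, entirely downward for
#' basipetal transport. Directions whose neighbor lies outside the domain are
#' absent (zero-flux boundary by omission).
#'
#' @param state A `vp_state`.
#' @param network A `vp_network`.
#' @param lattice A `vp_lattice`.
#' @param species Species name.
#' @param voxel Voxel index (row of `lattice$voxels`).
#' @return A tibble with columns `direction`, `kind` (`"diffusion"` or
#'   `"transport"`), and `rate`.
#' @export
movement_propensities <- function(state, network, lattice, species, voxel) {
  sp <- match(species, network$species$name)
  if (is.na(sp)) stop(sprintf("species %s is not in the network.", species),
                      call. = FALSE)
  n <- state$counts[voxel, sp]
  D <- network$species$D[sp]
  present <- lattice$nbr[voxel, ] != 0L
  dirs <- colnames(lattice$nbr)
  out <- tibble::tibble(direction = dirs[present], kind = "diffusion",
                        rate = unname(D * n))
  for (tr in network$transport) {
    if (tr$cargo != species) next
    nP <- state$counts[voxel, match(tr$carrier, network$species$name)]
    fac <- unname(tr$alpha * nP * n)
    if (tr$directionality == "symmetric_longitudinal") {
      for (d in c("+z", "-z")) {
        if (present[match(d, dirs)]) {
          out <- dplyr::bind_rows(out, tibble::tibble(
            direction = d, kind = "transport", rate = fac / 2))
        }
      }
    } else if (present[match("-z", dirs)]) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        direction = "-z", kind = "transport", rate = fac))
    }
  }
  out[out$rate > 0 | out$kind == "diffusion", ]
}

#' Tidy a simulation state into a long voxel table
#'
#' @param x A `vp_state` or `vp_trajectory` (the latter tidies its final
#'   state).
#' @param lattice The `vp_lattice` the state lives on (taken from the
#'   trajectory when tidying one).
#' @param ... Unused.
#' @return A tibble with `voxel`, `x`, `y`, `z`, `r`, `region`, `species`,
#'   `count`.
#' @export
tidy.vp_state <- function(x, lattice, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(lattice$voxels,
                     tibble::as_tibble(as.data.frame(x$counts))),
    cols = dplyr::all_of(colnames(x$counts)),
    names_to = "species", values_to = "count")
  long
}

#' @rdname tidy.vp_state
#' @export
tidy.vp_trajectory <- function(x, ...) tidy.vp_state(x$state, x$lattice, ...)

#' One-row summary of a trajectory
#'
#' @param x A `vp_trajectory`.
#' @param ... Unused.
#' @return A tibble with model, seed, final time, event count, voxel count,
#'   stop reason, and per-species molecule totals.
#' @export
glance.vp_trajectory <- function(x, ...) {
  totals <- colSums(x$state$counts)
  dplyr::bind_cols(
    tibble::tibble(model = x$network$model, seed = x$seed,
                   time = x$state$time, events = x$state$events,
                   n_voxels = nrow(x$state$counts), reason = x$reason,
                   n_snapshots = length(x$snapshots)),
    tibble::as_tibble(as.list(totals))
  )
}

#' Extract one species' field from a state or snapshot
#'
#' @param state A `vp_state` or a bare counts matrix (a snapshot).
#' @param species Species name.
#' @return Numeric vector of per-voxel counts.
#' @export
species_field <- function(state, species) {
  m <- if (inherits(state, "vp_state")) state$counts else state
  if (!species %in% colnames(m)) {
    stop(sprintf("species %s not present.", species), call. = FALSE)
  }
  as.numeric(m[, species])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
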