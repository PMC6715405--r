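#' Declare a mass-action reaction
#'
#' Reactions are at most trimolecular in total order (the activator
#' autocatalysis channel `2H + B -> 3H` being the largest used by the built-in
#' models) and may be restricted to a named region of the lattice.
#'
#' @param label Channel label (e.g. `"X1"`).
#' @param reactants Named integer vector of reactant stoichiometries
#'   (e.g. `c(H = 2, B = 1)`); use `NULL` or an empty vector for a source.
#' @param products Named integer vector of product stoichiometries.
#' @param k Rate constant, finite and `>= 0`.
#' @param restriction One of `"all"`, `"cortical_shell"`, `"apex_layer"`:
#'   where on the lattice the channel is allowed to fire.
#' @return A `vp_reaction` (a named list).
#' @export
reaction <- function(label, reactants = NULL, products = NULL, k,
                     restriction = c("all", "cortical_shell", "apex_layer")) {
  restriction <- match.arg(restriction)
  reactants <- normalize_stoich(reactants, "reactants")
  products <- normalize_stoich(products, "products")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || !is.finite(k) || k < 0) {
    stop(sprintf("rate constant for %s must be finite and >= 0.", label),
         call. = FALSE)
  }
  if (sum(reactants) > 3L) {
    stop(sprintf("reaction %s has total order %d; at most 3 is supported.",
                 label, sum(reactants)), call. = FALSE)
  }
  structure(list(label = label, reactants = reactants, products = products,
                 k = k, restriction = restriction),
            class = "vp_reaction")
}

normalize_stoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("`%s` must be a named vector (species -> count).", what),
         call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop(sprintf("`%s` stoichiometries must be non-negative integers.", what),
         call. = FALSE)
  }
  v <- as.integer(x)
  names(v) <- names(x)
  tapply(v, names(v), sum)[unique(names(v))]
}

#' Declare a carrier-facilitated longitudinal transport rule
#'
#' Models the efflux-carrier channel `P` (up/down arrows) `Y`: in a voxel
#' holding `n_P` carrier molecules, each cargo molecule acquires an additional
#' longitudinal movement propensity `alpha * n_P` on top of its passive
#' diffusion. Symmetric transport splits that propensity equally between the
#' up (+z) and down (-z) neighbors; basipetal transport directs all of it
#' downward (toward the stem base).
#'
#' @param carrier Carrier species name (the built-in models use `"P"`).
#' @param cargo Cargo species name (`"H"` in HBP/HBPM, `"A"` in HBPMA).
#' @param alpha Affinity of the cargo for the carrier, `>= 0`.
#' @param directionality `"symmetric_longitudinal"` or `"basipetal_only"`.
#' @return A `vp_transport` (a named list).
#' @export
transport_rule <- function(carrier, cargo, alpha,
                           directionality = c("symmetric_longitudinal",
                                              "basipetal_only")) {
  directionality <- match.arg(directionality)
  if (identical(carrier, cargo)) {
    stop("carrier and cargo must be different species.", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a scalar >= 0.", call. = FALSE)
  }
  structure(list(carrier = carrier, cargo = cargo, alpha = alpha,
                 directionality = directionality),
            class = "vp_transport")
}

#' Assemble a reaction network
#'
#' Low-level constructor for arbitrary stochastic reaction-diffusion systems;
#' the named model families are available through [make_model()].
#'
#' @param species Tibble or data frame with columns `name` and `D`
#'   (per-direction hop rate on the unit lattice, `>= 0`).
#' @param reactions List of [reaction()] objects.
#' @param transport List of [transport_rule()] objects (at most one per cargo).
#' @param model Optional model name recorded for provenance.
#' @return A `vp_network`.
#' @export
reaction_network <- function(species, reactions = list(), transport = list(),
                             model = "custom") {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "D") %in% names(species)))
  if (anyDuplicated(species$name)) {
    stop("species names must be unique.", call. = FALSE)
  }
  if (any(species$D < 0)) stop("diffusion coefficients must be >= 0.",
                               call. = FALSE)
  if (inherits(reactions, "vp_reaction")) reactions <- list(reactions)
  if (inherits(transport, "vp_transport")) transport <- list(transport)
  used <- unique(c(
    unlist(lapply(reactions, function(r) c(names(r$reactants), names(r$products)))),
    unlist(lapply(transport, function(tr) c(tr$carrier, tr$cargo)))
  ))
  missing <- setdiff(used, species$name)
  if (length(missing)) {
    stop(sprintf("species referenced but not declared: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cargos <- vapply(transport, `[[`, "", "cargo")
  if (anyDuplicated(cargos)) {
    stop("at most one transport rule per cargo species.", call. = FALSE)
  }
  structure(list(species = species, reactions = reactions,
                 transport = transport, model = model),
            class = "vp_network")
}

#' @method print vp_network
#' @export
print.vp_network <- function(x, ...) {
  cat(sprintf("<vp_network> model %s: %d species, %d reactions, %d transport rule(s)\n",
              x$model, nrow(x$species), length(x$reactions), length(x$transport)))
  cat(" species:", paste(sprintf("%s (D=%g)", x$species$name, x$species$D),
                         collapse = ", "), "\n")
  for (r in x$reactions) {
    lhs <- stoich_str(r$reactants)
    rhs <- stoich_str(r$products)
    restr <- if (r$restriction == "all") "" else sprintf(" [%s]", r$restriction)
    cat(sprintf("  %-4s %s -> %s  k=%g%s\n", r$label, lhs, rhs, r$k, restr))
  }
  for (tr in x$transport) {
    cat(sprintf("  %s transports %s (alpha=%g, %s)\n",
                tr$carrier, tr$cargo, tr$alpha, tr$directionality))
  }
  invisible(x)
}

stoich_str <- function(s) {
  if (length(s) == 0L) return("0")
  paste(ifelse(s > 1L, paste0(s, names(s)), names(s)), collapse = " + ")
}

#' Tidy the reaction list of a network
#'
#' @param x A `vp_network`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: `label`, `formula`, `k`,
#'   `restriction`.
#' @export
tidy.vp_network <- function(x, ...) {
  tibble::tibble(
    label = vapply(x$reactions, `[[`, "", "label"),
    formula = vapply(x$reactions, function(r)
      paste(stoich_str(r$reactants), "->", stoich_str(r$products)), ""),
    k = vapply(x$reactions, `[[`, 0, "k"),
    restriction = vapply(x$reactions, `[[`, "", "restriction")
  )
}

require_params <- function(params, needed, model) {
  absent <- setdiff(needed, names(params))
  if (length(absent)) {
    stop(sprintf("model %s requires parameter(s): %s",
                 model, paste(absent, collapse = ", ")), call. = FALSE)
  }
}

#' Build one of the named vascular-patterning models
#'
#' Factory for the model family studied in the package:
#' \describe{
#'   \item{HB}{The two-species activator-substrate (Gray-Scott-Schnakenberg)
#'     core: autocatalysis `2H + B -> 3H` (X1, rate `k1`), substrate
#'     production/decay `0 -> B` / `B -> 0` (X2 `k2`, X3 `k3`), activator
#'     production/decay `0 -> H` / `H -> 0` (X4 `k4`, X5 `k5`).
#'     Needs `k1..k5`, `D_H`, `D_B`.}
#'   \item{HBP}{Adds the efflux carrier `P` (diffusion 0): `H -> H + P`
#'     (X6 `k6`), `P -> 0` (X7 `k7`), and symmetric facilitated longitudinal
#'     transport of `H` by `P` (X8, affinity `alpha`). Needs additionally
#'     `k6`, `k7`, `alpha`.}
#'   \item{HBPM}{Adds the peripheral inhibitor `M`: `0 -> M` restricted to the
#'     cortical shell (X9 `k9`), `M -> 0` (X10 `k10`), mutual annihilation
#'     `M + H -> 0` (X11 `k11`) and optionally `M + B -> 0` (X12 `k12`,
#'     included only when `k12` is supplied and positive). Needs additionally
#'     `k9`, `k10`, `k11`, `D_M`.}
#'   \item{HBPMA}{Source-sink variant: an apically produced hormone `A`
#'     (`0 -> A` restricted to the apex layer, rate `k13`; decay `A -> 0`,
#'     `k14`; diffusion `D_A`) is the transported cargo instead of `H`, moved
#'     by `P` basipetally only. `A` and `H` regulate each other through a
#'     feedback pair: `A -> A + H` (rate `k_AH`) plus either `H + A -> H`
#'     (`feedback = "repression"`, rate `k_HA`, default) or `H -> H + A`
#'     (`feedback = "activation"`, rate `k_HA`).}
#' }
#'
#' @param name One of `"HB"`, `"HBP"`, `"HBPM"`, `"HBPMA"`.
#' @param params Named list/vector of rate constants and diffusion
#'   coefficients (see Details). A missing constant is a configuration error
#'   naming the absent constant.
#' @param feedback HBPMA only: `"repression"` or `"activation"` form of the
#'   H-side of the H/A feedback loop.
#' @return A `vp_network`.
#' @examples
#' hb <- make_model("HB", list(k1 = 0.0125, k2 = 30, k3 = 1.25, k4 = 10,
#'                             k5 = 2.5, D_H = 0.05, D_B = 50))
#' tidy(hb)
#' @export
make_model <- function(name = c("HB", "HBP", "HBPM", "HBPMA"), params,
                       feedback = c("repression", "activation")) {
  name <- match.arg(name)
  feedback <- match.arg(feedback)
  params <- as.list(params)

  require_params(params, c("k1", "k2", "k3", "k4", "k5", "D_H", "D_B"), name)
  p <- params
  species <- tibble::tibble(name = c("H", "B"), D = c(p$D_H, p$D_B))
  rx <- list(
    reaction("X1", c(H = 2, B = 1), c(H = 3), p$k1),
    reaction("X2", NULL, c(B = 1), p$k2),
    reaction("X3", c(B = 1), NULL, p$k3),
    reaction("X4", NULL, c(H = 1), p$k4),
    reaction("X5", c(H = 1), NULL, p$k5)
  )
  transport <- list()

  if (name %in% c("HBP", "HBPM", "HBPMA")) {
    require_params(params, c("k6", "k7", "alpha"), name)
    species <- dplyr::bind_rows(species, tibble::tibble(name = "P", D = 0))
    rx <- c(rx, list(
      reaction("X6", c(H = 1), c(H = 1, P = 1), p$k6),
      reaction("X7", c(P = 1), NULL, p$k7)
    ))
    if (name != "HBPMA") {
      transport <- list(transport_rule("P", "H", p$alpha,
                                       "symmetric_longitudinal"))
    }
  }

  if (name %in% c("HBPM", "HBPMA")) {
    require_params(params, c("k9", "k10", "k11", "D_M"), name)
    species <- dplyr::bind_rows(species, tibble::tibble(name = "M", D = p$D_M))
    rx <- c(rx, list(
      reaction("X9", NULL, c(M = 1), p$k9, restriction = "cortical_shell"),
      reaction("X10", c(M = 1), NULL, p$k10),
      reaction("X11", c(M = 1, H = 1), NULL, p$k11)
    ))
    if (!is.null(p$k12) && p$k12 > 0) {
      rx <- c(rx, list(reaction("X12", c(M = 1, B = 1), NULL, p$k12)))
    }
  }

  if (name == "HBPMA") {
    require_params(params, c("k13", "k14", "k_AH", "k_HA", "D_A"), name)
    species <- dplyr::bind_rows(species, tibble::tibble(name = "A", D = p$D_A))
    fb <- if (feedback == "repression") {
      reaction("XF2", c(H = 1, A = 1), c(H = 1), p$k_HA)
    } else {
      reaction("XF2", c(H = 1), c(H = 1, A = 1), p$k_HA)
    }
    rx <- c(rx, list(
      reaction("X13", NULL, c(A = 1), p$k13, restriction = "apex_layer"),
      reaction("X14", c(A = 1), NULL, p$k14),
      reaction("XF1", c(A = 1), c(A = 1, H = 1), p$k_AH),
      fb
    ))
    transport <- list(transport_rule("P", "A", p$alpha, "basipetal_only"))
  }

  reaction_network(species, rx, transport, model = name)
}

#' Mass-action propensity of one reaction channel in one voxel
#'
#' Standard Gillespie combinatorial form on molecule counts: a source channel
#' fires at `k`; first order in `S` at `k * n_S`; `S + T` at `k * n_S * n_T`;
#' the dimeric channel `2H + B` at `k * n_H * (n_H - 1) * n_B`. A channel
#' restricted to a region contributes 0 outside it.
#'
#' @param reaction A [reaction()].
#' @param counts Named non-negative integer vector of per-species counts in
#'   the voxel.
#' @param region The voxel's cross-sectional region, `"interior"` or
#'   `"cortical_shell"`.
#' @param apex Whether the voxel lies on the apex (top z) layer.
#' @return Non-negative propensity.
#' @export
propensity <- function(reaction, counts, region = "interior", apex = FALSE) {
  stopifnot(inherits(reaction, "vp_reaction"))
  if (any(counts < 0)) {
    stop("negative molecule counts: corrupted state.", call. = FALSE)
  }
  if (reaction$restriction == "cortical_shell" && region != "cortical_shell") {
    return(0)
  }
  if (reaction$restriction == "apex_layer" && !apex) return(0)
  a <- reaction$k
  s <- reaction$reactants
  for (i in seq_along(s)) {
    n <- counts[[names(s)[i]]]
    m <- s[[i]]
    # falling factorial n (n-1) ... (n-m+1)
    for (j in seq_len(m)) a <- a * max(n - j + 1, 0)
  }
  unname(a)
}
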