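#' Deterministic activator-substrate dynamics (mean-field reference)
#'
#' Forward-Euler finite-difference integrator for the two-species
#' Gray-Scott-Schnakenberg system on a lattice:
#' \deqn{\partial_t [H] = D_H \nabla^2 [H] + k_1 [H]^2 [B] + k_4 - k_5 [H]}
#' \deqn{\partial_t [B] = D_B \nabla^2 [B] - k_1 [H]^2 [B] + k_2 - k_3 [B]}
#' with the 5-point (2D) / 7-point (3D) Laplacian and zero-flux boundaries
#' realized by neighbor omission (the same topology the stochastic engine
#' uses), so mass changes only through the reaction terms.
#'
#' `dt` must satisfy the explicit-stability bound
#' `dt < 1 / (2 * d * max(D_H, D_B))` for lattice dimension `d`; violating it
#' is a configuration error. A negative or non-finite concentration aborts
#' with the step index: it signals an invalid `dt`/parameter regime rather
#' than being silently clipped.
#'
#' @param lattice A `vp_lattice`.
#' @param init Numeric matrix `n_voxels x 2` with columns `H`, `B` (or a
#'   `vp_field`).
#' @param params Named list with `k1..k5`, `D_H`, `D_B`.
#' @param dt Time step.
#' @param n_steps Number of Euler steps (positive integer).
#' @return A `vp_field`: the concentration matrix plus `time` and the lattice.
#' @export
pde_integrate <- function(lattice, init, params, dt, n_steps) {
  stopifnot(inherits(lattice, "vp_lattice"))
  p <- as.list(params)
  require_params(p, c("k1", "k2", "k3", "k4", "k5", "D_H", "D_B"), "HB (PDE)")
  d <- lattice$dim
  dmax <- max(p$D_H, p$D_B)
  if (dmax > 0 && dt >= 1 / (2 * d * dmax)) {
    stop(sprintf(
      "dt = %g violates the explicit stability bound dt < 1/(2*%d*%g) = %g.",
      dt, d, dmax, 1 / (2 * d * dmax)), call. = FALSE)
  }
  if (n_steps < 1 || abs(n_steps - round(n_steps)) > 1e-8) {
    stop("`n_steps` must be a positive integer.", call. = FALSE)
  }
  n_steps <- round(n_steps)
  f <- if (inherits(init, "vp_field")) init$conc else as.matrix(init)
  stopifnot(nrow(f) == n_voxels(lattice), ncol(f) == 2L)
  colnames(f) <- c("H", "B")
  t0 <- if (inherits(init, "vp_field")) init$time else 0

  L <- lattice_laplacian(lattice)
  H <- f[, 1L]
  B <- f[, 2L]
  for (step in seq_len(n_steps)) {
    rxn <- p$k1 * H * H * B
    dH <- p$D_H * as.numeric(L %*% H) + rxn + p$k4 - p$k5 * H
    dB <- p$D_B * as.numeric(L %*% B) - rxn + p$k2 - p$k3 * B
    H <- H + dt * dH
    B <- B + dt * dB
    if (any(!is.finite(H)) || any(!is.finite(B)) || any(H < 0) || any(B < 0)) {
      stop(sprintf(
        "integration failure at step %d: negative or non-finite concentration.",
        step), call. = FALSE)
    }
  }
  structure(list(conc = cbind(H = H, B = B), time = t0 + dt * n_steps,
                 lattice = lattice),
            class = "vp_field")
}

#' @method print vp_field
#' @export
print.vp_field <- function(x, ...) {
  cat(sprintf("<vp_field> t = %.6g, mean [H] = %.4g, mean [B] = %.4g\n",
              x$time, mean(x$conc[, "H"]), mean(x$conc[, "B"])))
  invisible(x)
}

# sparse zero-flux graph Laplacian (L f)_v = sum_w (f_w - f_v) over neighbors
lattice_laplacian <- function(lattice) {
  nb <- lattice$nbr
  from <- rep(seq_len(nrow(nb)), times = ncol(nb))
  to <- as.vector(nb)
  keep <- to != 0L
  from <- from[keep]
  to <- to[keep]
  n <- nrow(nb)
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  A - Matrix::Diagonal(n, deg)
}

#' Homogeneous steady states of the activator-substrate kinetics
#'
#' Solves the spatially uniform fixed-point equations
#' `k1 H^2 B + k4 - k5 H = 0` and `k2 - k3 B - k1 H^2 B = 0`.
#' Eliminating `B = k2 / (k3 + k1 H^2)` reduces the system to a cubic in `H`,
#' solved by polynomial root finding; all non-negative real roots are
#' returned with their `B` values and residuals.
#'
#' @param params Named list with `k1..k5` (`k5 > 0`).
#' @return A tibble with columns `H`, `B`, `residual_H`, `residual_B`, one row
#'   per non-negative steady state.
#' @export
homogeneous_steady_state <- function(params) {
  p <- as.list(params)
  require_params(p, c("k1", "k2", "k3", "k4", "k5"), "HB kinetics")
  if (p$k5 <= 0) stop("`k5` must be positive.", call. = FALSE)
  if (p$k1 == 0) {
    H <- p$k4 / p$k5
    B <- if (p$k3 > 0) p$k2 / p$k3 else NA_real_
    if (is.na(B)) {
      stop("no finite steady state: k1 = 0 and k3 = 0 leave B unbalanced.",
           call. = FALSE)
    }
    roots <- H
  } else {
    # -k5 k1 H^3 + k1 (k2 + k4) H^2 - k5 k3 H + k4 k3 = 0
    coefs <- c(p$k4 * p$k3, -p$k5 * p$k3, p$k1 * (p$k2 + p$k4), -p$k5 * p$k1)
    z <- polyroot(coefs)
    roots <- Re(z)[abs(Im(z)) < 1e-8 * (1 + abs(Re(z)))]
    roots <- sort(unique(roots[roots >= -1e-12]))
    roots <- pmax(roots, 0)
  }
  if (length(roots) == 0L) {
    stop("no non-negative homogeneous steady state for these parameters.",
         call. = FALSE)
  }
  H <- roots
  B <- if (p$k1 == 0) p$k2 / p$k3 else p$k2 / (p$k3 + p$k1 * H^2)
  out <- tibble::tibble(
    H = H, B = B,
    residual_H = p$k1 * H^2 * B + p$k4 - p$k5 * H,
    residual_B = p$k2 - p$k3 * B - p$k1 * H^2 * B
  )
  scale <- max(1, p$k2, p$k4)
  out <- out[is.finite(out$B) & abs(out$residual_H) < 1e-6 * scale &
               abs(out$residual_B) < 1e-6 * scale, ]
  if (nrow(out) == 0L) {
    stop("no non-negative homogeneous steady state for these parameters.",
         call. = FALSE)
  }
  out
}

#' Linear-stability dispersion relation of the activator-substrate system
#'
#' For each wavenumber `q`, computes the leading eigenvalue (largest real
#' part) of `J - q^2 diag(D_H, D_B)`, where `J` is the reaction Jacobian at
#' the homogeneous steady state. A band of `q` with positive growth rate is
#' the Turing (diffusion-driven) instability that seeds the vascular-bundle
#' spot pattern; its presence requires the substrate to diffuse sufficiently
#' faster than the activator.
#'
#' @param params Named list with `k1..k5`, `D_H`, `D_B`.
#' @param steady_state Optional one-row data frame / list with `H`, `B`; by
#'   default the largest-`H` root of [homogeneous_steady_state()] is used.
#' @param q Wavenumber grid (non-negative).
#' @return A tibble `q`, `growth_rate`, with attributes `unstable_band`
#'   (range of unstable `q`, or `NULL`) and `steady_state`.
#' @export
dispersion_relation <- function(params, steady_state = NULL,
                                q = seq(0, 3, length.out = 301)) {
  p <- as.list(params)
  require_params(p, c("k1", "k2", "k3", "k4", "k5", "D_H", "D_B"),
                 "HB kinetics")
  if (is.null(steady_state)) {
    ss <- homogeneous_steady_state(p)
    ss <- ss[which.max(ss$H), ]
  } else {
    ss <- as.list(steady_state)
  }
  H <- ss$H
  B <- ss$B
  J <- matrix(c(2 * p$k1 * H * B - p$k5, -2 * p$k1 * H * B,
                p$k1 * H^2, -p$k3 - p$k1 * H^2), 2, 2)
  growth <- vapply(q, function(qi) {
    M <- J - qi^2 * diag(c(p$D_H, p$D_B))
    max(Re(eigen(M, only.values = TRUE)$values))
  }, 0)
  out <- tibble::tibble(q = q, growth_rate = growth)
  unstable <- q[growth > 0 & q > 0]
  attr(out, "unstable_band") <- if (length(unstable)) range(unstable) else NULL
  attr(out, "steady_state") <- c(H = H, B = B)
  out
}

#' Steady state plus small random perturbation as a deterministic initial field
#'
#' The deterministic integrator has no intrinsic noise to break the symmetry
#' of a uniform state, so patterned runs start from the homogeneous steady
#' state with a small multiplicative perturbation.
#'
#' @param lattice A `vp_lattice`.
#' @param params Kinetic parameters (see [homogeneous_steady_state()]).
#' @param amplitude Relative perturbation amplitude (default 0.01).
#' @param seed Seed for the perturbation.
#' @return A `vp_field`.
#' @export
perturbed_steady_field <- function(lattice, params, amplitude = 0.01,
                                   seed = 1) {
  ss <- homogeneous_steady_state(params)
  ss <- ss[which.max(ss$H), ]
  set.seed(as.integer(seed))
  n <- n_voxels(lattice)
  conc <- cbind(
    H = ss$H * (1 + amplitude * stats::runif(n, -1, 1)),
    B = ss$B * (1 + amplitude * stats::runif(n, -1, 1))
  )
  structure(list(conc = conc, time = 0, lattice = lattice),
            class = "vp_field")
}

#' @export
tidy.vp_field <- function(x, ...) {
  dplyr::bind_cols(x$lattice$voxels,
                   tibble::as_tibble(as.data.frame(x$conc)))
}
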