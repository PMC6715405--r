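# Independent oracles used across the suite. These deliberately avoid the
# package's own data structures and algorithms where they check one.

# brute-force count of integer lattice points within distance R of the origin
oracle_disc_count <- function(R) {
  n <- 0L
  for (x in -R:R) for (y in -R:R) if (x^2 + y^2 <= R^2 + 1e-9) n <- n + 1L
  n
}

# brute-force voxel set of the outer annulus r >= (1 - fraction) * R
oracle_shell_set <- function(lattice, fraction) {
  vx <- lattice$voxels
  which(sqrt(vx$x^2 + vx$y^2) >= (1 - fraction) * lattice$radius)
}

# flood-fill connected components of a logical mask over lattice voxels,
# returned as a list of sorted voxel-index vectors (sorted by size desc)
oracle_flood_fill <- function(mask, lattice, diagonal = FALSE) {
  vx <- lattice$voxels
  hot <- which(mask)
  if (!length(hot)) return(list())
  key <- paste(vx$x, vx$y, vx$z, sep = ",")
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (v in hot) assign(key[v], v, envir = lookup)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (diagonal) offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  seen <- logical(nrow(vx))
  comps <- list()
  for (v in hot) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, cur)
      for (o in offs) {
        kk <- paste(vx$x[cur] + o[1], vx$y[cur] + o[2], vx$z[cur], sep = ",")
        if (exists(kk, envir = lookup, inherits = FALSE)) {
          w <- get(kk, envir = lookup)
          if (!seen[w]) {
            seen[w] <- TRUE
            queue <- c(queue, w)
          }
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(-vapply(comps, length, 0L))]
}

# fourth-order Runge-Kutta integration of the well-mixed two-species kinetics
oracle_rk4 <- function(y0, p, t_end, n_steps = 20000) {
  f <- function(y) {
    r <- p$k1 * y[1]^2 * y[2]
    c(r + p$k4 - p$k5 * y[1], p$k2 - p$k3 * y[2] - r)
  }
  h <- t_end / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# paint filled discs of a given radius/value onto a per-voxel field
paint_disc <- function(field, lattice, cx, cy, radius, value) {
  vx <- lattice$voxels
  hit <- (vx$x - cx)^2 + (vx$y - cy)^2 <= radius^2 + 1e-9
  field[hit] <- value
  field
}

# small two-species network: pure birth-death of H (X4/X5 only)
birth_death_net <- function(k4 = 50, k5 = 1) {
  reaction_network(
    tibble::tibble(name = "H", D = 0),
    list(reaction("X4", NULL, c(H = 1), k4),
         reaction("X5", c(H = 1), NULL, k5))
  )
}

# diffusion-only single-species network
diffusion_net <- function(D = 1) {
  reaction_network(tibble::tibble(name = "S", D = D))
}

base_hb <- function() {
  list(k1 = 0.0015, k2 = 29, k3 = 0.5, k4 = 16, k5 = 1)
}
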