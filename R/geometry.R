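#' Voxel lattice for a stem cross-section (2D disc)
#'
#' Builds the discretized spatial domain used by the stochastic and
#' deterministic solvers: the set of unit voxels whose centers lie within
#' Euclidean distance `radius` of the domain center, with face (4-neighbor)
#' adjacency. Boundaries are reflective (zero-flux): voxels outside the disc
#' are simply absent from every neighbor list, so no event can ever move a
#' molecule out of the domain.
#'
#' Each cross-section is partitioned into an `"interior"` region and a
#' `"cortical_shell"` region, the outer annulus of relative radial width
#' `shell_fraction` (voxels with `r >= (1 - shell_fraction) * radius`). The
#' shell is where peripherally produced species (the inhibitor M of the HBPM
#' model) are sourced.
#'
#' @param radius Disc radius in voxels (positive integer-valued scalar).
#' @param shell_fraction Relative width of the cortical shell annulus,
#'   in (0, 1). Default 0.04 (the outer 4 percent of the stem).
#' @return A `vp_lattice` object: a list with a `voxels` tibble
#'   (`voxel`, `x`, `y`, `z`, `r`, `region`, `apex`), an integer neighbor
#'   matrix `nbr` (one row per voxel, columns `+x,-x,+y,-y,+z,-z`, 0 where the
#'   neighbor is outside the domain), and scalar metadata (`dim`, `radius`,
#'   `height`, `shell_fraction`).
#' @examples
#' d <- lattice_disc(10)
#' nrow(as_tibble(d))       # voxel count
#' @seealso [lattice_cylinder()], [shell_mask()], [apex_mask()]
#' @export
lattice_disc <- function(radius, shell_fraction = 0.04) {
  check_radius(radius)
  build_lattice(radius, height = 1L, dim = 2L, shell_fraction = shell_fraction)
}

#' Voxel lattice for a plant stem (3D right circular cylinder)
#'
#' The 2D disc cross-section of [lattice_disc()] extruded over `height`
#' z-layers with 6-neighbor (face) adjacency. `z` is the longitudinal axis;
#' "basipetal" means decreasing `z`. The top z-layer is flagged as the apex
#' (`apex = TRUE`), the production site of apically sourced species.
#'
#' @inheritParams lattice_disc
#' @param height Cylinder height in voxels (positive integer-valued scalar).
#' @return A `vp_lattice`; see [lattice_disc()].
#' @export
lattice_cylinder <- function(radius, height, shell_fraction = 0.04) {
  check_radius(radius)
  if (!is.numeric(height) || length(height) != 1L || is.na(height) ||
      height < 1 || height != round(height)) {
    stop("`height` must be a positive integer-valued scalar.", call. = FALSE)
  }
  build_lattice(radius, height = as.integer(height), dim = 3L,
                shell_fraction = shell_fraction)
}

check_radius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 1 || radius != round(radius)) {
    stop("`radius` must be a positive integer-valued scalar.", call. = FALSE)
  }
  invisible(radius)
}

check_shell_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  invisible(fraction)
}

# Direction column order is part of the engine contract: +x,-x,+y,-y,+z,-z.
lattice_directions <- function() {
  matrix(c(1L, 0L, 0L,
           -1L, 0L, 0L,
           0L, 1L, 0L,
           0L, -1L, 0L,
           0L, 0L, 1L,
           0L, 0L, -1L),
         ncol = 3L, byrow = TRUE,
         dimnames = list(c("+x", "-x", "+y", "-y", "+z", "-z"), NULL))
}

build_lattice <- function(radius, height, dim, shell_fraction) {
  check_shell_fraction(shell_fraction)
  R <- as.integer(radius)
  # disc membership: voxel-center distance to the center voxel <= R
  g <- expand.grid(x = -R:R, y = -R:R)
  r <- sqrt(g$x^2 + g$y^2)
  keep <- r <= R + 1e-9
  disc <- g[keep, , drop = FALSE]
  rr <- r[keep]
  n_xy <- nrow(disc)
  z <- rep(seq_len(height) - 1L, each = n_xy)
  vox <- tibble::tibble(
    voxel = seq_len(n_xy * height),
    x = rep(disc$x, times = height),
    y = rep(disc$y, times = height),
    z = as.integer(z),
    r = rep(rr, times = height)
  )
  vox$region <- ifelse(vox$r >= (1 - shell_fraction) * R, "cortical_shell",
                       "interior")
  vox$apex <- if (dim == 3L) vox$z == height - 1L else FALSE

  # neighbor lookup through a dense (x, y, z) -> voxel index map
  key <- function(x, y, z) {
    (x + R) + (2L * R + 1L) * ((y + R) + (2L * R + 1L) * z)
  }
  idx <- integer((2L * R + 1L)^2 * height)
  idx[key(vox$x, vox$y, vox$z) + 1L] <- vox$voxel
  dirs <- lattice_directions()
  nbr <- matrix(0L, nrow = nrow(vox), ncol = 6L,
                dimnames = list(NULL, rownames(dirs)))
  for (d in seq_len(6L)) {
    nx <- vox$x + dirs[d, 1L]
    ny <- vox$y + dirs[d, 2L]
    nz <- vox$z + dirs[d, 3L]
    ok <- abs(nx) <= R & abs(ny) <= R & nz >= 0L & nz <= height - 1L
    cand <- integer(nrow(vox))
    cand[ok] <- idx[key(nx[ok], ny[ok], nz[ok]) + 1L]
    nbr[, d] <- cand
  }

  structure(
    list(voxels = vox, nbr = nbr, dim = dim, radius = R,
         height = as.integer(height), shell_fraction = shell_fraction),
    class = "vp_lattice"
  )
}

#' @method print vp_lattice
#' @export
print.vp_lattice <- function(x, ...) {
  kind <- if (x$dim == 2L) "disc" else "cylinder"
  cat(sprintf("<vp_lattice> %s: radius %d%s, %d voxels, shell fraction %.3g\n",
              kind, x$radius,
              if (x$dim == 3L) sprintf(" x height %d", x$height) else "",
              nrow(x$voxels), x$shell_fraction))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.vp_lattice <- function(x, ...) x$voxels

#' Number of voxels in a lattice
#' @param lattice A `vp_lattice`.
#' @return Integer voxel count.
#' @export
n_voxels <- function(lattice) {
  stopifnot(inherits(lattice, "vp_lattice"))
  nrow(lattice$voxels)
}

#' Cortical-shell voxel mask
#'
#' Logical mask of the voxels in the outer annulus of relative width
#' `fraction` (radial distance `r >= (1 - fraction) * radius`), applied per
#' z-layer in 3D. With the default fraction this is the production region of
#' the peripheral inhibitor in the HBPM model.
#'
#' @param lattice A `vp_lattice`.
#' @param fraction Relative annulus width in (0, 1); default 0.04.
#' @return Logical vector over voxels (in `voxels$voxel` order).
#' @export
shell_mask <- function(lattice, fraction = 0.04) {
  stopifnot(inherits(lattice, "vp_lattice"))
  check_shell_fraction(fraction)
  lattice$voxels$r >= (1 - fraction) * lattice$radius
}

#' Apex voxel mask (top z-layer of a cylinder)
#'
#' @param lattice A 3D `vp_lattice`.
#' @return Logical vector over voxels, `TRUE` exactly on the maximal z-layer.
#' @export
apex_mask <- function(lattice) {
  stopifnot(inherits(lattice, "vp_lattice"))
  if (lattice$dim != 3L) {
    stop("`apex_mask()` requires a 3D (cylinder) lattice.", call. = FALSE)
  }
  lattice$voxels$z == lattice$height - 1L
}

# integer region codes shared with the C++ engine: 1 interior, 2 shell
region_codes <- function(lattice) {
  ifelse(lattice$voxels$region == "cortical_shell", 2L, 1L)
}
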