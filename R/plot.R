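#' Heatmap of one species over a cross-section
#'
#' Renders a per-voxel field with the convention used throughout the package:
#' white outside the domain (absence of molecules) and intensity scaled from 0
#' to the field maximum.
#'
#' @param field Numeric per-voxel counts (or a `vp_state` plus `species`).
#' @param lattice A `vp_lattice`.
#' @param species Species name when `field` is a `vp_state`.
#' @param z z-slice for 3D lattices (default: the middle layer).
#' @return A ggplot object.
#' @export
plot_field <- function(field, lattice, species = NULL, z = NULL) {
  if (inherits(field, "vp_state")) {
    if (is.null(species)) stop("supply `species` for a vp_state.",
                               call. = FALSE)
    field <- species_field(field, species)
  }
  stopifnot(length(field) == n_voxels(lattice))
  vx <- lattice$voxels
  if (lattice$dim == 3L) {
    if (is.null(z)) z <- lattice$height %/% 2L
    keep <- vx$z == z
  } else {
    keep <- rep(TRUE, nrow(vx))
  }
  df <- tibble::tibble(x = vx$x[keep], y = vx$y[keep], count = field[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick4",
                                 limits = c(0, max(df$count, 1))) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = if (is.null(species)) "count" else
      sprintf("[%s]", species))
}

#' @export
autoplot.vp_field <- function(object, species = "H", ...) {
  plot_field(object$conc[, species], object$lattice, species = NULL, ...) +
    ggplot2::labs(fill = sprintf("[%s]", species))
}

#' @export
autoplot.vp_spots <- function(object, lattice, ...) {
  if (nrow(object) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no spots"))
  }
  vx <- lattice$voxels
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    v <- object$voxels[[i]]
    tibble::tibble(x = vx$x[v], y = vx$y[v],
                   spot = factor(object$spot_id[i]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$spot)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @export
autoplot.vp_zonation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid,
                                       y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "r_shell"),
                        linetype = "dashed") +
    ggplot2::labs(x = "radial distance (voxels)", y = "mean count per voxel")
}

#' Fig-style summary of a diffusion sweep
#'
#' Boxplots of persistent spot count and mean spot diameter against the
#' substrate/activator diffusion ratio, one panel set per activator diffusion
#' rate.
#'
#' @param sweep Output of [sweep_diffusion()].
#' @param what `"n_spots"` or `"mean_diameter"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, what = c("n_spots", "mean_diameter")) {
  what <- match.arg(what)
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$ratio),
                                      y = .data[[what]],
                                      color = factor(.data$D_H))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "D_B / D_H", color = "D_H", y = what)
}

#' Write a PNG frame of a field
#'
#' Grayscale raster with the cross-section embedded in a white background:
#' pixels outside the domain are white, intensity inside scales linearly from
#' white (0) to black (field maximum).
#'
#' @param field Numeric per-voxel counts.
#' @param lattice A `vp_lattice`.
#' @param path Output PNG path.
#' @param z z-slice for 3D lattices (default middle layer).
#' @return `path`, invisibly.
#' @export
write_field_png <- function(field, lattice, path, z = NULL) {
  stopifnot(length(field) == n_voxels(lattice))
  vx <- lattice$voxels
  if (lattice$dim == 3L) {
    if (is.null(z)) z <- lattice$height %/% 2L
    keep <- vx$z == z
  } else keep <- rep(TRUE, nrow(vx))
  R <- lattice$radius
  img <- matrix(1, nrow = 2L * R + 1L, ncol = 2L * R + 1L)
  m <- max(field[keep], 1)
  img[cbind(vx$y[keep] + R + 1L, vx$x[keep] + R + 1L)] <-
    1 - field[keep] / m
  png::writePNG(img[rev(seq_len(nrow(img))), , drop = FALSE], target = path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
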