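#' Toroidal layer geometry
#'
#' The neurons of a layer lie on a 2D square grid. The grid wraps around:
#' neurons on opposite edges are treated as adjacent, which removes edge
#' effects from the distance-dependent connectivity. Coordinates are
#' expressed in pyramidal-grid units; the pyramidal layer has `unit = 1`.
#'
#' @param rows,cols grid dimensions.
#' @param unit spacing between neighbouring neurons of this layer, in
#'   pyramidal-grid units.
#' @return an object of class `layer_geometry`.
#' @export
layer_geometry <- function(rows, cols, unit = 1) {
  stopifnot(rows >= 1, cols >= 1, unit > 0)
  g <- list(rows = as.integer(rows), cols = as.integer(cols), unit = unit,
            wrap = TRUE, n = as.integer(rows) * as.integer(cols),
            period = c(rows * unit, cols * unit))
  class(g) <- "layer_geometry"
  g
}

#' @export
print.layer_geometry <- function(x, ...) {
  cat(sprintf("<layer_geometry> %d x %d toroidal grid, unit = %g\n",
              x$rows, x$cols, x$unit))
  invisible(x)
}

#' Grid coordinates of all neurons in a layer
#'
#' Neurons are indexed row-major (index 1 is the top-left corner); neuron
#' `k` sits at `((k-1) %/% cols, (k-1) %% cols) * unit`.
#'
#' @param geom a [layer_geometry()].
#' @return an `n x 2` matrix of `(row, col)` coordinates in pyramidal-grid
#'   units.
#' @export
grid_coords <- function(geom) {
  k <- seq_len(geom$n) - 1L
  cbind(row = (k %/% geom$cols) * geom$unit,
        col = (k %% geom$cols) * geom$unit)
}

#' Wrap-around distance between two grid points
#'
#' Euclidean distance on the torus: along each axis the shorter of the
#' direct and the wrapped separation is taken, so opposite edges of the map
#' are adjacent.
#'
#' @param p,q length-2 coordinates `(row, col)` in pyramidal-grid units.
#' @param geom the [layer_geometry()] defining the wrap period.
#' @return the toroidal Euclidean distance.
#' @examples
#' g <- layer_geometry(40, 40)
#' torus_distance(c(0, 0), c(39, 39), g)  # sqrt(2): corners are neighbours
#' @export
torus_distance <- function(p, q, geom) {
  stopifnot(length(p) == 2, length(q) == 2)
  per <- geom$period
  if (any(p < 0) || any(q < 0) || any(p >= per) || any(q >= per)) {
    stop("coordinate outside the grid [0, period)", call. = FALSE)
  }
  d <- abs(p - q)
  d <- pmin(d, per - d)
  sqrt(sum(d^2))
}

#' Pairwise toroidal distances between two coordinate sets
#'
#' @param coords_post,coords_pre `n x 2` coordinate matrices (post-synaptic
#'   rows, pre-synaptic columns of the result).
#' @param period length-2 wrap period (extent of the pyramidal map).
#' @return an `n_post x n_pre` distance matrix.
#' @export
torus_distance_matrix <- function(coords_post, coords_pre, period) {
  dr <- abs(outer(coords_post[, 1], coords_pre[, 1], "-"))
  dr <- pmin(dr, period[1] - dr)
  dc <- abs(outer(coords_post[, 2], coords_pre[, 2], "-"))
  dc <- pmin(dc, period[2] - dc)
  sqrt(dr^2 + dc^2)
}

#' Embed the interneuron grid in the pyramidal map
#'
#' Interneurons are far fewer than pyramidal cells (169 vs 1600 by default,
#' the ~9:1 CA1 ratio) but share the same cortical sheet; their grid is
#' embedded uniformly in the pyramidal extent, anchored at the origin, with
#' spacing `pyr_extent / int_rows` pyramidal units. All cross-layer
#' distances use these embedded coordinates.
#'
#' @param geom_p pyramidal [layer_geometry()].
#' @param geom_i interneuron [layer_geometry()].
#' @return an `n_int x 2` coordinate matrix in pyramidal-grid units.
#' @export
place_interneurons <- function(geom_p, geom_i) {
  spacing <- c(geom_p$period[1] / geom_i$rows, geom_p$period[2] / geom_i$cols)
  k <- seq_len(geom_i$n) - 1L
  cbind(row = (k %/% geom_i$cols) * spacing[1],
        col = (k %% geom_i$cols) * spacing[2])
}
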