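#' Regular 3-D scalar grid
#'
#' The shared container for every scalar field in the package: ion
#' concentrations (M), electrostatic potentials (kT/e), distances to the
#' closest structure atom (Angstrom), probability densities (1/Angstrom^3)
#' and binary masks.  Values live on grid *nodes*; node \code{(i,j,k)}
#' (1-based) sits at \code{origin + (i-1, j-1, k-1) * spacing}.  Region
#' integrals treat each node as one voxel of volume
#' \code{prod(spacing)}.
#'
#' @param values Numeric 3-D array.
#' @param origin Numeric length-3, position of node (1,1,1) in Angstrom.
#' @param spacing Numeric length 1 or 3, node spacing per axis in Angstrom.
#' @param units One of \code{"M"}, \code{"kT/e"}, \code{"A"}, \code{"A^-3"},
#'   \code{"mask"}, \code{"1"}.
#' @return An object of class \code{grid_map}.
#' @export
grid_map <- function(values, origin, spacing, units = "1") {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(origin) == 3L, all(is.finite(origin)))
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0), all(dim(values) >= 2L))
  units <- match.arg(units, c("M", "kT/e", "A", "A^-3", "mask", "1"))
  if (units == "mask") {
    if (!all(values %in% c(0, 1))) stop("mask grid values must be 0 or 1")
  } else if (anyNA(values) || any(!is.finite(values))) {
    stop("grid values must be finite")
  }
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values), units = units),
            class = "grid_map")
}

#' Grid geometry specification
#'
#' Geometry-only description of a grid (no values), used to request maps.
#'
#' @param origin Position of the first node (Angstrom).
#' @param spacing Node spacing, length 1 or 3 (Angstrom).
#' @param dims Number of nodes per axis.
#' @return An object of class \code{grid_spec}.
#' @export
#' @examples
#' grid_spec_centered(center = c(0, 0, 0), extent = 64, spacing = 1)
grid_spec <- function(origin, spacing, dims) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- rep_len(as.integer(dims), 3L)
  stopifnot(all(spacing > 0), all(dims >= 2L), length(origin) == 3L)
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param center Grid center (Angstrom).
#' @param extent Edge length per axis (Angstrom), length 1 or 3.
#' @export
grid_spec_centered <- function(center, extent, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  extent <- rep_len(as.numeric(extent), 3L)
  dims <- as.integer(round(extent / spacing)) + 1L
  grid_spec(center - (dims - 1L) * spacing / 2, spacing, dims)
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "grid_map")) return(grid_spec(x$origin, x$spacing, x$dims))
  stop("cannot interpret object as a grid specification")
}

#' Node coordinates of a grid axis
#' @param g A \code{grid_map} or \code{grid_spec}.
#' @param axis Axis index 1..3.
#' @return Numeric vector of node positions along the axis (Angstrom).
#' @export
grid_axis <- function(g, axis) {
  g <- as_grid_spec(g)
  g$origin[axis] + (seq_len(g$dims[axis]) - 1) * g$spacing[axis]
}

# n x 3 matrix of all node coordinates, node index i fastest (R array order)
grid_coords <- function(g) {
  g <- as_grid_spec(g)
  as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                        z = grid_axis(g, 3), KEEP.OUT.ATTRS = FALSE))
}

#' Voxel volume of a grid
#' @param g A \code{grid_map} or \code{grid_spec}.
#' @return Volume in Angstrom^3 represented by each node.
#' @export
voxel_volume <- function(g) prod(as_grid_spec(g)$spacing)

same_geometry <- function(a, b, tol = 1e-9) {
  a <- as_grid_spec(a); b <- as_grid_spec(b)
  all(a$dims == b$dims) && all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

stop_if_incommensurate <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grids do not share the same geometry (origin/spacing/dims)")
  invisible(TRUE)
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> %d x %d x %d nodes, spacing (%g, %g, %g) A, units '%s'\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  cat(sprintf("  origin (%g, %g, %g) A; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Trilinear interpolation of a grid map
#'
#' @param g A \code{grid_map}.
#' @param xyz n x 3 matrix of query positions (Angstrom); must lie inside
#'   the grid.
#' @return Numeric vector of interpolated values.
#' @export
grid_interpolate <- function(g, xyz) {
  xyz <- to_coord_matrix(xyz)
  frac <- sweep(sweep(xyz, 2, g$origin), 2, g$spacing, "/")
  if (any(frac < -1e-9) || any(sweep(frac, 2, g$dims - 1L) > 1e-9))
    stop("query positions outside grid")
  frac <- pmin(pmax(frac, 0), matrix(rep(g$dims - 1L, each = nrow(frac)), ncol = 3))
  i0 <- pmin(floor(frac), matrix(rep(g$dims - 2L, each = nrow(frac)), ncol = 3))
  t <- frac - i0
  v <- g$values
  out <- numeric(nrow(xyz))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    out <- out + w * v[idx]
  }
  out
}

to_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c(1, 2, 3)])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  x
}
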