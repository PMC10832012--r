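#' Voxel-grid geometry
#'
#' Describes an axis-aligned voxel grid in physical patient coordinates.
#' `origin` is the physical position (cm) of the *center* of voxel
#' `(1,1,1)`; `spacing` is the voxel pitch per axis (cm); `dim` the voxel
#' counts. All dose grids and structure masks that enter a metric
#' computation must share one geometry — resampling belongs to ingest,
#' never to the metric engine.
#'
#' @param origin numeric(3), cm.
#' @param spacing numeric(3) or scalar (isotropic), cm, strictly positive.
#' @param dim integer(3), voxel counts per axis, all >= 1.
#' @return an object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(origin = c(0, 0, 0), spacing = 0.2, dim = c(64, 64, 64))
#' voxel_volume(g)  # 0.008 cc
#' @export
grid_geometry <- function(origin = c(0, 0, 0), spacing = 0.1, dim) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dim) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive and finite")
  if (any(dim < 1)) stop("grid dim must be >= 1 on every axis")
  structure(list(origin = origin, spacing = spacing, dim = dim),
            class = "grid_geometry")
}

#' @describeIn grid_geometry volume of one voxel in cc (spacings in cm).
#' @param geom a `grid_geometry`.
#' @export
voxel_volume <- function(geom) prod(geom$spacing)

#' Physical coordinates of voxel centers along each axis
#'
#' @param geom a `grid_geometry`.
#' @return list with numeric vectors `x`, `y`, `z` (cm).
#' @export
axis_coords <- function(geom) {
  list(x = geom$origin[1] + (seq_len(geom$dim[1]) - 1) * geom$spacing[1],
       y = geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2],
       z = geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3])
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d, spacing (%g, %g, %g) cm, origin (%g, %g, %g) cm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

stop_if_geometry_mismatch <- function(a, b, what = "objects") {
  if (!same_geometry(a, b))
    stop(sprintf("%s are not on the same voxel grid; resample at ingest first", what))
  invisible(TRUE)
}
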