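#' Structure volume
#'
#' Volume of a structure in cc: set-voxel count times voxel volume.
#'
#' @param mask a [structure_mask]; must be non-empty.
#' @return volume in cc.
#' @export
structure_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  stop_if_empty(mask)
  sum(mask$occupancy) * voxel_volume(mask$geometry)
}

#' Overlap volume of two structures
#'
#' Volume of the voxelwise intersection, in cc. Symmetric; bounded by the
#' smaller of the two structure volumes.
#'
#' @param a,b [structure_mask] objects on the same grid.
#' @return overlap volume in cc.
#' @export
overlap_volume <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  stop_if_geometry_mismatch(a$geometry, b$geometry,
                            sprintf("structures '%s' and '%s'", a$name, b$name))
  sum(a$occupancy & b$occupancy) * voxel_volume(a$geometry)
}

#' Overlap fraction of an OAR with a target volume
#'
#' The main geometric predictor of the KBP models: the volume an organ at
#' risk shares with a target, normalized to the OAR volume, in percent.
#'
#' @param oar OAR [structure_mask] (non-empty).
#' @param ptv target [structure_mask] on the same grid.
#' @return percent in `[0, 100]`.
#' @export
overlap_fraction <- function(oar, ptv) {
  100 * overlap_volume(oar, ptv) / structure_volume(oar)
}

#' Center of mass of a structure
#'
#' Unweighted mean of the set-voxel center coordinates, in physical cm.
#'
#' @param mask a non-empty [structure_mask].
#' @return numeric(3), cm.
#' @export
centroid <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  stop_if_empty(mask)
  idx <- which(mask$occupancy, arr.ind = TRUE)
  g <- mask$geometry
  colMeans(sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`))
}

#' Distance between two structure centroids
#'
#' 3D Euclidean distance between the centers of mass, in cm (e.g. the
#' peritoneal-cavity-to-PTV46 distance used as a dose predictor).
#'
#' @param a,b non-empty [structure_mask] objects on the same grid.
#' @return distance in cm.
#' @export
centroid_distance <- function(a, b) {
  stop_if_geometry_mismatch(a$geometry, b$geometry,
                            sprintf("structures '%s' and '%s'", a$name, b$name))
  sqrt(sum((centroid(a) - centroid(b))^2))
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: for each bin edge d (Gy), the structure
#' volume (cc) receiving at least d. Voxels count toward a bin when their
#' dose is >= the edge (inclusive threshold).
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid.
#' @param bin_width bin width in Gy, > 0. Default 0.05 Gy, finer than any
#'   clinically reported precision.
#' @return object of class `dvh`: list with `bin_edges` (Gy, ascending from
#'   0, last edge >= max structure dose), `cumulative_volume` (cc,
#'   non-increasing), `total_volume` (cc), `structure`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.05) {
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  d <- structure_doses(dose, mask)
  vv <- voxel_volume(mask$geometry)
  top <- bin_width * ceiling(max(d) / bin_width)
  edges <- seq(0, max(top, bin_width), by = bin_width)
  if (edges[length(edges)] < max(d)) edges <- c(edges, edges[length(edges)] + bin_width)
  ds <- sort(d)
  n <- length(ds)
  # voxels with dose >= edge, via binary search on the sorted doses
  cum <- (n - findInterval(edges - 1e-12, ds)) * vv
  cum[1] <- n * vv  # V(0 Gy) is the full structure volume by definition
  structure(list(bin_edges = edges, cumulative_volume = cum,
                 total_volume = n * vv, structure = mask$name),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("cumulative DVH of '%s': %.2f cc, %d bins up to %.2f Gy\n",
              x$structure, x$total_volume,
              length(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' VxGy: volume receiving at least a threshold dose
#'
#' Structure volume receiving >= `threshold` Gy, computed directly from the
#' voxels (never from a binned DVH), in cc or in percent of the structure
#' volume. E.g. `v_dose(d, cavity, 15, "cc")` is the cavity V15Gy(cc).
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid.
#' @param threshold dose threshold in Gy, >= 0.
#' @param unit `"cc"` or `"percent"`.
#' @return volume in the requested unit.
#' @export
v_dose <- function(dose, mask, threshold, unit = c("cc", "percent")) {
  unit <- match.arg(unit)
  if (!is.finite(threshold) || threshold < 0) stop("threshold must be >= 0")
  d <- structure_doses(dose, mask)
  n_above <- sum(d >= threshold)
  if (unit == "cc") n_above * voxel_volume(mask$geometry)
  else 100 * n_above / length(d)
}

#' Dq%: minimum dose to the hottest q% of a structure
#'
#' The dose received by at least q% of the structure volume. Convention:
#' structure voxel doses are sorted descending and the dose at rank
#' `ceiling(q/100 * N)` is returned — the discrete "hottest q%" reading,
#' with no interpolation. `d_at_volume_percent(dose, m, 100)` is the
#' structure minimum dose; the function is non-increasing in q.
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid.
#' @param q volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
d_at_volume_percent <- function(dose, mask, q) {
  if (!is.finite(q) || q <= 0 || q > 100) stop("q must be in (0, 100]")
  d <- sort(structure_doses(dose, mask), decreasing = TRUE)
  d[min(length(d), max(1L, as.integer(ceiling(q / 100 * length(d)))))]
}

#' Mean and maximum structure dose
#'
#' Arithmetic mean (`mean_dose`) and maximum (`max_dose`) of the dose over
#' the structure's voxels, in Gy. The maximum is the single hottest voxel
#' (no near-max volume variant).
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid.
#' @return dose in Gy.
#' @export
mean_dose <- function(dose, mask) mean(structure_doses(dose, mask))

#' @rdname mean_dose
#' @export
max_dose <- function(dose, mask) max(structure_doses(dose, mask))
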