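#' Dose grid
#'
#' A 3D scalar field of absorbed dose (Gy) on a voxel grid, together with
#' the prescription dose of the plan (the summed prescription when two
#' series are planned, e.g. 46 Gy pelvis + 30 Gy boost = 76 Gy).
#'
#' @param dose numeric 3D array of absorbed dose in Gy; all values finite
#'   and non-negative.
#' @param geom a [grid_geometry] consistent with `dim(dose)`.
#' @param prescription_dose prescription dose in Gy, > 0. Default 76.
#' @return an object of class `dose_grid`.
#' @examples
#' g <- grid_geometry(spacing = 0.5, dim = c(10, 10, 10))
#' dg <- dose_grid(array(50, c(10, 10, 10)), g, prescription_dose = 76)
#' @export
dose_grid <- function(dose, geom, prescription_dose = 76) {
  stopifnot(inherits(geom, "grid_geometry"))
  dose <- as.array(dose)
  if (length(dim(dose)) != 3 || !all(dim(dose) == geom$dim))
    stop("dose array extent does not match the grid geometry")
  if (any(!is.finite(dose))) stop("dose values must all be finite")
  if (any(dose < 0)) stop("dose values must be non-negative")
  if (!is.finite(prescription_dose) || prescription_dose <= 0)
    stop("prescription_dose must be positive")
  structure(list(dose = dose, geometry = geom,
                 prescription_dose = prescription_dose),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose grid: max %.2f Gy, prescription %.1f Gy\n",
              max(x$dose), x$prescription_dose))
  print(x$geometry)
  invisible(x)
}

#' Structure mask
#'
#' Binary occupancy of one anatomical structure (target volume or organ at
#' risk) on a voxel grid. Masks are strictly binary: no partial-voxel
#' weighting is applied anywhere in the metric engine.
#'
#' @param occupancy logical 3D array (or coercible) on the same grid.
#' @param geom a [grid_geometry].
#' @param name structure label, e.g. `"PTV46"`, `"Rectum"`,
#'   `"PeritonealCavity"`.
#' @param role `"target"` or `"oar"`. Defaults to `"target"` for names
#'   starting with PTV/CTV/GTV, `"oar"` otherwise.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, geom, name, role = NULL) {
  stopifnot(inherits(geom, "grid_geometry"), is.character(name), nzchar(name))
  occupancy <- array(as.logical(occupancy), dim = dim(as.array(occupancy)))
  if (length(dim(occupancy)) != 3 || !all(dim(occupancy) == geom$dim))
    stop(sprintf("occupancy array for '%s' does not match the grid geometry", name))
  if (any(is.na(occupancy))) stop("occupancy must not contain NA")
  if (is.null(role))
    role <- if (grepl("^(PTV|CTV|GTV)", name, ignore.case = TRUE)) "target" else "oar"
  role <- match.arg(role, c("target", "oar"))
  structure(list(occupancy = occupancy, geometry = geom,
                 name = name, role = role),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure '%s' (%s): %d voxels, %.2f cc\n",
              x$name, x$role, sum(x$occupancy),
              sum(x$occupancy) * voxel_volume(x$geometry)))
  invisible(x)
}

stop_if_empty <- function(mask) {
  if (!any(mask$occupancy))
    stop(sprintf("structure '%s' has no voxels set", mask$name))
  invisible(TRUE)
}

# doses of the voxels inside a mask, with geometry check
structure_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  stop_if_geometry_mismatch(dose$geometry, mask$geometry,
                            sprintf("dose grid and structure '%s'", mask$name))
  stop_if_empty(mask)
  dose$dose[mask$occupancy]
}
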