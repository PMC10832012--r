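# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Exact 3D Euclidean distance (cm) from every voxel center to the nearest
# voxel of `occ`. Per-slice 2D distance transforms (EBImage::distmap) are
# combined over the z offset: for a fixed slice k the nearest target point
# to (x, y, z) is at squared distance d2k(x,y)^2 + dz^2, so the 3D
# distance is the minimum over slices. Requires equal in-plane spacings.
target_distance_cm <- function(occ, spacing) {
  if (abs(spacing[1] - spacing[2]) > 1e-9)
    stop("distance transform requires equal x/y spacing")
  dims <- dim(occ)
  d2 <- EBImage::distmap(array(as.numeric(!occ), dims))  # per-slice 2D EDT
  best <- array(Inf, dims)
  zs <- seq_len(dims[3])
  for (k in zs) {
    a2 <- (d2[, , k] * spacing[1])^2
    if (!any(is.finite(a2))) next  # slice contains no target voxel
    dz2 <- ((zs - k) * spacing[3])^2
    best <- pmin(best, outer(a2, dz2, `+`))
  }
  if (any(!is.finite(best)))
    stop("distance transform undefined: target structure is empty")
  sqrt(best)
}

# boolean occupancy of an axis-aligned ellipsoid (centers/radii in cm)
ellipsoid_occupancy <- function(geom, center, radii) {
  ax <- axis_coords(geom)
  u2 <- ((ax$x - center[1]) / radii[1])^2
  v2 <- ((ax$y - center[2]) / radii[2])^2
  w2 <- ((ax$z - center[3]) / radii[3])^2
  outer(outer(u2, v2, `+`), w2, `+`) <= 1
}

# tube along z: circle of given radius in (x, y), |z - center| <= half_length
tube_occupancy <- function(geom, center, radius, half_length) {
  ax <- axis_coords(geom)
  r2 <- outer(((ax$x - center[1]) / radius)^2,
              ((ax$y - center[2]) / radius)^2, `+`) <= 1
  zin <- abs(ax$z - center[3]) <= half_length
  outer(r2, zin, `&`)
}

#' Synthetic pelvic phantom specification
#'
#' Parameters of the test phantom: a two-target geometry (PTV46 pelvic
#' volume containing the PTV76 boost), a posterior rectal tube, an
#' anterior-superior bladder sphere, and a large superior peritoneal
#' cavity from which the CTVs (targets shrunk by `ctv_margin_cm`), bladder
#' and rectum are carved out. OAR-target overlap is controllable either
#' directly (by placing centers) or by requesting an overlap fraction
#' ([make_phantom] then positions the OAR along the line to the target).
#'
#' The default grid is 64 x 64 x 64 at 0.2 cm isotropic spacing — a
#' desk-scale phantom whose structure volumes are smaller than real pelvic
#' anatomy but whose predictor ranges (overlap fraction, centroid
#' distance) cover the model domains.
#'
#' @param dim,spacing,origin grid geometry (see [grid_geometry]).
#' @param prescription_dose summed prescription in Gy (default 76).
#' @param ptv46_center,ptv46_radii,ptv76_center,ptv76_radii ellipsoid
#'   parameters in cm.
#' @param rectum_center,rectum_radius,rectum_half_length rectal tube.
#' @param bladder_center,bladder_radius bladder sphere.
#' @param cavity_center,cavity_radii,cavity_zmin cavity ellipsoid,
#'   restricted to `z >= cavity_zmin`.
#' @param ctv_margin_cm PTV-to-CTV margin subtracted from the target radii
#'   when carving the cavity (default 0.5 cm).
#' @param rectum_overlap_pct,bladder_overlap_pct optional requested
#'   overlap fraction (%) of the OAR with PTV76.
#' @param falloff_cm exponential dose falloff length scale (cm) outside
#'   the high-dose target; 0 gives a hard step.
#' @param noise_sd Gaussian dose noise SD in Gy (clipped at 0 Gy).
#' @param series data.frame with columns `target` and `dose` (Gy): the
#'   treatment series summed voxelwise into the plan dose. Default the
#'   two-series protocol, 46 Gy on PTV46 plus a 30 Gy boost on PTV76.
#' @param seed RNG seed for the dose noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 64), spacing = 0.2, origin = c(0, 0, 0),
                         prescription_dose = 76,
                         ptv46_center = c(6.3, 6.3, 6.3), ptv46_radii = c(3.0, 2.6, 2.6),
                         ptv76_center = c(6.3, 6.0, 6.0), ptv76_radii = c(1.8, 1.5, 1.5),
                         rectum_center = c(6.3, 3.9, 6.0), rectum_radius = 0.8,
                         rectum_half_length = 3.0,
                         bladder_center = c(6.3, 8.6, 7.5), bladder_radius = 1.5,
                         cavity_center = c(6.3, 6.3, 8.6), cavity_radii = c(5.5, 5.5, 4.6),
                         cavity_zmin = 6.9, ctv_margin_cm = 0.5,
                         rectum_overlap_pct = NULL, bladder_overlap_pct = NULL,
                         falloff_cm = 1.0, noise_sd = 0.2,
                         series = data.frame(target = c("PTV46", "PTV76"),
                                             dose = c(46, 30)),
                         seed = 1L) {
  if (!is.finite(falloff_cm) || falloff_cm < 0)
    stop("falloff_cm must be >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  spec <- as.list(environment())
  class(spec) <- "phantom_spec"
  spec
}

# place an OAR along the segment default-center -> target centroid so that
# its overlap fraction with the target approaches the request (bisection on
# the continuous shift; the discrete grid limits attainable precision)
solve_overlap_position <- function(build, base_center, target, requested_pct, geom) {
  tgt_c <- centroid(target)
  ov_at <- function(t) {
    m <- build(base_center + t * (tgt_c - base_center))
    if (!any(m$occupancy)) return(NA_real_)
    overlap_fraction(m, target)
  }
  hi <- ov_at(1)
  if (requested_pct > hi + 1e-9)
    stop(sprintf("requested overlap %.1f%% exceeds the %.1f%% achievable for this geometry",
                 requested_pct, hi))
  lo_t <- 0; hi_t <- 1
  if (ov_at(0) >= requested_pct) return(base_center + 0 * (tgt_c - base_center))
  for (i in 1:40) {
    mid <- (lo_t + hi_t) / 2
    if (ov_at(mid) < requested_pct) lo_t <- mid else hi_t <- mid
  }
  # pick the endpoint closer to the request
  t_best <- if (abs(ov_at(lo_t) - requested_pct) < abs(ov_at(hi_t) - requested_pct))
    lo_t else hi_t
  base_center + t_best * (tgt_c - base_center)
}

#' Build the synthetic phantom structure set
#'
#' Deterministic for a fixed spec. Primitives are rasterized onto the
#' grid; PTV76 is clipped to PTV46 and the cavity excludes the CTVs
#' (targets shrunk by the margin), bladder and rectum. When an overlap
#' fraction is requested for the rectum or bladder the OAR is positioned
#' by bisection along the line to the PTV76 centroid; the discrete grid
#' makes the achieved fraction step in voxel-sized lumps, so callers
#' should read the achieved value back with [overlap_fraction].
#'
#' @param spec a [phantom_spec].
#' @return list with `structures` (named list of [structure_mask]:
#'   PTV46, PTV76, Rectum, Bladder, PeritonealCavity) and `geometry`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- grid_geometry(spec$origin, spec$spacing, spec$dim)
  ptv46 <- ellipsoid_occupancy(g, spec$ptv46_center, spec$ptv46_radii)
  ptv76 <- ellipsoid_occupancy(g, spec$ptv76_center, spec$ptv76_radii) & ptv46
  if (!any(ptv46)) stop("PTV46 lies outside the grid")
  if (!any(ptv76)) stop("PTV76 lies outside the grid")
  m46 <- structure_mask(ptv46, g, "PTV46", "target")
  m76 <- structure_mask(ptv76, g, "PTV76", "target")

  rect_center <- spec$rectum_center
  build_rect <- function(center)
    structure_mask(tube_occupancy(g, center, spec$rectum_radius,
                                  spec$rectum_half_length), g, "Rectum", "oar")
  if (!is.null(spec$rectum_overlap_pct))
    rect_center <- solve_overlap_position(build_rect, spec$rectum_center, m76,
                                          spec$rectum_overlap_pct, g)
  rectum <- build_rect(rect_center)

  blad_center <- spec$bladder_center
  build_blad <- function(center)
    structure_mask(ellipsoid_occupancy(g, center, rep(spec$bladder_radius, 3)),
                   g, "Bladder", "oar")
  if (!is.null(spec$bladder_overlap_pct))
    blad_center <- solve_overlap_position(build_blad, spec$bladder_center, m76,
                                          spec$bladder_overlap_pct, g)
  bladder <- build_blad(blad_center)

  ax <- axis_coords(g)
  cav <- ellipsoid_occupancy(g, spec$cavity_center, spec$cavity_radii)
  cav <- cav & outer(array(TRUE, spec$dim[1:2]), ax$z >= spec$cavity_zmin, `&`)
  ctv46 <- ellipsoid_occupancy(g, spec$ptv46_center,
                               pmax(spec$ptv46_radii - spec$ctv_margin_cm, 0.1))
  ctv76 <- ellipsoid_occupancy(g, spec$ptv76_center,
                               pmax(spec$ptv76_radii - spec$ctv_margin_cm, 0.1))
  cav <- cav & !ctv46 & !ctv76 & !bladder$occupancy & !rectum$occupancy
  cavity <- structure_mask(cav, g, "PeritonealCavity", "oar")

  list(structures = list(PTV46 = m46, PTV76 = m76, Rectum = rectum,
                         Bladder = bladder, PeritonealCavity = cavity),
       geometry = g)
}

#' Generate a synthetic dose distribution for a phantom
#'
#' Each treatment series contributes its series dose as a plateau inside
#' its target plus an exponential falloff with the Euclidean distance to
#' the target outside (`dose * exp(-d / falloff_cm)`; a zero falloff
#' length gives 0 outside the target). Series are summed voxelwise — the
#' convention under which the OAR constraints are stated — and optional
#' Gaussian noise is added (clipped at 0 Gy). Distances are exact 3D
#' Euclidean distances to the nearest target voxel center (equal in-plane
#' spacings required; z spacing may differ).
#'
#' @param structures named structure list from [make_phantom].
#' @param spec the [phantom_spec] (series, falloff, noise, seed).
#' @return a [dose_grid].
#' @export
make_dose <- function(structures, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- NULL
  d <- NULL
  for (i in seq_len(nrow(spec$series))) {
    tgt <- structures[[spec$series$target[i]]]
    if (is.null(tgt)) stop(sprintf("target '%s' missing", spec$series$target[i]))
    g <- tgt$geometry
    occ <- tgt$occupancy
    lvl <- spec$series$dose[i]
    if (spec$falloff_cm == 0) {
      contrib <- array(ifelse(occ, lvl, 0), g$dim)
    } else {
      dist_cm <- target_distance_cm(occ, g$spacing)
      contrib <- array(lvl * exp(-dist_cm / spec$falloff_cm), g$dim)
      contrib[occ] <- lvl
    }
    d <- if (is.null(d)) contrib else d + contrib
  }
  if (spec$noise_sd > 0)
    d <- with_seed(spec$seed,
                   pmax(array(d + stats::rnorm(length(d), 0, spec$noise_sd),
                              g$dim), 0))
  dose_grid(d, g, spec$prescription_dose)
}

#' Synthetic training-cohort specification
#'
#' Feature-level cohort generator: for each KBP model, predictor values
#' are drawn uniformly over a plausible clinical range and responses as
#' `y = A x + B + eps`, `eps ~ N(0, sd)`. The default truth table places
#' the response metrics in the ranges a prostate VMAT cohort exhibits
#' (rectum/bladder V60Gy around 0-50%, cavity mean dose around 10-25 Gy,
#' cavity V15Gy several hundred cc).
#'
#' @param n number of plans, >= 3 (default 25, a typical training-cohort
#'   size for single-clinic KBP models).
#' @param truth data.frame with columns `model_id`, `A`, `B`, `sd`,
#'   `xmin`, `xmax`; default built in.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 25, truth = NULL, seed = 1L) {
  if (n < 3) stop("a cohort needs at least 3 plans")
  if (is.null(truth)) {
    truth <- data.frame(
      model_id = c("rectum_v60", "rectum_v70", "bladder_v60", "bladder_v70",
                   "cavity_davg", "cavity_v45", "cavity_v15"),
      A = c(1.6, 1.2, 1.4, 1.1, -1.5, 5.0, 0.009),
      B = c(2.0, 0.5, 1.0, 0.3, 30.0, 5.0, 100.0),
      sd = c(1.5, 1.2, 1.5, 1.2, 1.5, 8.0, 60.0),
      xmin = c(0, 0, 0, 0, 4, 0, 2e4),
      xmax = c(30, 30, 30, 30, 15, 10, 7e4),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("model_id", "A", "B", "sd", "xmin", "xmax") %in% names(truth)))
  if (any(truth$sd < 0)) stop("noise sd must be >= 0")
  if (any(truth$xmax < truth$xmin)) stop("predictor range reversed")
  structure(list(n = as.integer(n), truth = truth, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic feature-level training cohort
#'
#' Draws, per model and plan, a predictor value and a response on the true
#' line plus Gaussian scatter. Deterministic for fixed spec and seed; the
#' ground truth is returned alongside for recovery tests.
#'
#' @param spec a [cohort_spec].
#' @return list with `table` (data.frame: `plan_id`, `model_id`, `x`,
#'   `y`), `truth` (the generating parameters) and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  tab <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(nrow(spec$truth)), function(i) {
      tr <- spec$truth[i, ]
      x <- stats::runif(spec$n, tr$xmin, tr$xmax)
      y <- tr$A * x + tr$B + stats::rnorm(spec$n, 0, tr$sd)
      data.frame(plan_id = sprintf("plan%03d", seq_len(spec$n)),
                 model_id = tr$model_id, x = x, y = y,
                 stringsAsFactors = FALSE)
    }))
  })
  list(table = tab, truth = spec$truth, spec = spec)
}

#' Fit every registry model on a feature table
#'
#' @param specs named list of [kbp_model_spec] (default
#'   [kbp_default_models()]); models absent from the table are skipped.
#' @param table data.frame with columns `model_id`, `x`, `y` (e.g. from
#'   [make_cohort] or the CLI `features` step).
#' @return named list of [fitted_kbp_model].
#' @export
fit_models_from_table <- function(specs = kbp_default_models(), table) {
  stopifnot(all(c("model_id", "x", "y") %in% names(table)))
  specs <- Filter(function(s) s$id %in% table$model_id, specs)
  if (length(specs) == 0) stop("no registry model present in the table")
  stats::setNames(lapply(specs, function(s) {
    sub <- table[table$model_id == s$id, ]
    fit_kbp_model(s, sub$x, sub$y)
  }), vapply(specs, `[[`, "", "id"))
}
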