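#' Compute a named dose metric for one structure
#'
#' Dispatches the metric descriptors used in constraint templates and
#' model registries: `"Dmax"`, `"Davg"`, `"VxGy"` (e.g. `"V45Gy"`) and
#' `"Dq%"` (e.g. `"D95%"`). VxGy honours `unit` (`"cc"` or `"percent"`);
#' D-type metrics are in Gy.
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid.
#' @param metric metric descriptor string.
#' @param unit unit for VxGy metrics; ignored for D-type metrics.
#' @return metric value.
#' @export
compute_metric <- function(dose, mask, metric, unit = "cc") {
  m <- parse_metric(metric)
  switch(m$kind,
         dmax = max_dose(dose, mask),
         davg = mean_dose(dose, mask),
         vdose = v_dose(dose, mask, m$value, unit),
         dquant = d_at_volume_percent(dose, mask, m$value))
}

parse_metric <- function(metric) {
  stopifnot(is.character(metric), length(metric) == 1)
  if (metric == "Dmax") return(list(kind = "dmax"))
  if (metric == "Davg") return(list(kind = "davg"))
  mv <- regmatches(metric, regexec("^V([0-9]+\\.?[0-9]*)Gy$", metric))[[1]]
  if (length(mv) == 2) return(list(kind = "vdose", value = as.numeric(mv[2])))
  md <- regmatches(metric, regexec("^D([0-9]+\\.?[0-9]*)%$", metric))[[1]]
  if (length(md) == 2) return(list(kind = "dquant", value = as.numeric(md[2])))
  stop(sprintf("unknown metric descriptor '%s' (expected Dmax, Davg, VxGy or Dq%%)", metric))
}

#' Paddick conformity index
#'
#' PCI = TV_PIV^2 / (TV x PIV), where TV is the target volume, PIV the
#' volume of the *whole grid* receiving at least the reference isodose,
#' and TV_PIV their intersection. 1 means the prescription isodose
#' conforms perfectly to the target; values above 0.7 are conventionally
#' acceptable for pelvic VMAT.
#'
#' @param dose a [dose_grid].
#' @param ptv target [structure_mask] (non-empty).
#' @param reference_isodose isodose level in Gy defining the PIV. Default
#'   95% of the prescription dose, matching the coverage acceptance level;
#'   clinics using the 100% isodose can pass `dose$prescription_dose`.
#' @return PCI in `[0, 1]`. If no voxel reaches the reference isodose the
#'   index is 0 (with a warning).
#' @export
paddick_ci <- function(dose, ptv, reference_isodose = 0.95 * dose$prescription_dose) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "structure_mask"))
  stop_if_geometry_mismatch(dose$geometry, ptv$geometry,
                            sprintf("dose grid and structure '%s'", ptv$name))
  stop_if_empty(ptv)
  if (!is.finite(reference_isodose) || reference_isodose <= 0)
    stop("reference_isodose must be > 0")
  piv_vox <- dose$dose >= reference_isodose
  n_piv <- sum(piv_vox)
  if (n_piv == 0) {
    warning("no voxel reaches the reference isodose; PCI defined as 0")
    return(0)
  }
  n_tv <- sum(ptv$occupancy)
  n_both <- sum(piv_vox & ptv$occupancy)
  n_both^2 / (n_tv * n_piv)
}

#' Homogeneity index
#'
#' HI = (D2% - D98%) / D50% within the target volume. 0 for a perfectly
#' uniform target dose; invariant under uniform dose scaling.
#'
#' @param dose a [dose_grid].
#' @param ptv target [structure_mask] (non-empty, D50% > 0).
#' @return dimensionless HI >= 0.
#' @export
homogeneity_index <- function(dose, ptv) {
  d2 <- d_at_volume_percent(dose, ptv, 2)
  d98 <- d_at_volume_percent(dose, ptv, 98)
  d50 <- d_at_volume_percent(dose, ptv, 50)
  if (d50 <= 0) stop("median target dose is zero; homogeneity index undefined")
  (d2 - d98) / d50
}

#' Target coverage check
#'
#' Plan acceptance rule for target coverage: 95% of the PTV must receive
#' at least 95% of the prescription, and the maximum target dose must stay
#' below 107% of the prescription.
#'
#' @param dose a [dose_grid].
#' @param ptv target [structure_mask].
#' @param prescription prescription dose in Gy; defaults to the grid's.
#' @return list with `d95_pct` and `dmax_pct` (% of prescription),
#'   `d95_pass` (D95% >= 95), `dmax_pass` (Dmax < 107) and `pass` (both).
#' @export
coverage_check <- function(dose, ptv, prescription = dose$prescription_dose) {
  if (!is.finite(prescription) || prescription <= 0)
    stop("prescription must be > 0")
  d95 <- 100 * d_at_volume_percent(dose, ptv, 95) / prescription
  dmax <- 100 * max_dose(dose, ptv) / prescription
  list(d95_pct = d95, dmax_pct = dmax,
       d95_pass = d95 >= 95, dmax_pass = dmax < 107,
       pass = d95 >= 95 && dmax < 107)
}

#' OAR dose-constraint template
#'
#' The default template carries the clinic's planning constraints for
#' prostate VMAT, applied to the sum of the two treatment series
#' (46 Gy pelvis + 30 Gy boost): peritoneal cavity Dmax < 54 Gy,
#' V45Gy < 150 cc, V15Gy < 830 cc; rectum V40Gy < 40%, V60Gy < 50%,
#' V70Gy < 25%, V75Gy < 5%; bladder V60Gy < 50%, V70Gy < 25%; anal canal
#' V55Gy < 100%; femoral heads V52Gy < 10% each side.
#'
#' @param entries optional data.frame with columns `structure`, `metric`,
#'   `unit` (`"Gy"`, `"cc"` or `"percent"`), `comparator` (`"<"` or
#'   `"<="`) and `limit`; omitted for the default template.
#' @return data.frame of class `constraint_template`.
#' @export
constraint_template <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      structure = c(rep("PeritonealCavity", 3), rep("Rectum", 4),
                    rep("Bladder", 2), "AnalCanal",
                    "FemoralHeadRight", "FemoralHeadLeft"),
      metric = c("Dmax", "V45Gy", "V15Gy",
                 "V40Gy", "V60Gy", "V70Gy", "V75Gy",
                 "V60Gy", "V70Gy", "V55Gy", "V52Gy", "V52Gy"),
      unit = c("Gy", "cc", "cc",
               "percent", "percent", "percent", "percent",
               "percent", "percent", "percent", "percent", "percent"),
      comparator = "<",
      limit = c(54, 150, 830, 40, 50, 25, 5, 50, 25, 100, 10, 10),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("structure", "metric", "unit", "comparator", "limit") %in%
                  names(entries)))
  if (any(!is.finite(entries$limit)) || any(entries$limit <= 0))
    stop("constraint limits must be positive")
  if (any(!entries$comparator %in% c("<", "<=")))
    stop("comparators must be '<' or '<='")
  if (anyDuplicated(entries[c("structure", "metric")]))
    stop("duplicate (structure, metric) constraint entry")
  invisible(lapply(entries$metric, parse_metric))  # validate descriptors
  class(entries) <- c("constraint_template", "data.frame")
  entries
}

#' Read / write a constraint template as YAML
#'
#' The template is a plain, human-editable YAML list of entries
#' (`structure`, `metric`, `unit`, `comparator`, `limit`), so a clinic can
#' keep its protocol under version control.
#'
#' @param path file path.
#' @param template a [constraint_template].
#' @return `read_constraint_template` returns a [constraint_template];
#'   `write_constraint_template` returns `path` invisibly.
#' @export
read_constraint_template <- function(path) {
  y <- yaml::read_yaml(path)
  constraint_template(do.call(rbind, lapply(y$constraints, function(e)
    data.frame(structure = e$structure, metric = e$metric, unit = e$unit,
               comparator = e$comparator, limit = as.numeric(e$limit),
               stringsAsFactors = FALSE))))
}

#' @rdname read_constraint_template
#' @export
write_constraint_template <- function(template, path) {
  yaml::write_yaml(list(constraints = lapply(seq_len(nrow(template)), function(i)
    as.list(template[i, , drop = FALSE]))), path)
  invisible(path)
}

#' Evaluate one plan against a constraint template
#'
#' Computes every template metric from the dose grid, compares against the
#' limit, and attaches target-coverage indices (D95%, Dmax in % of the
#' prescription, Paddick CI at the 95% isodose, homogeneity index) for the
#' coverage target. Template structures absent from the structure set are
#' flagged `not_evaluated`, never fatal.
#'
#' @param dose a [dose_grid] (the summed plan when two series are used).
#' @param structures named list of [structure_mask] objects.
#' @param template a [constraint_template]; default [constraint_template()].
#' @param plan_id identifier recorded in the result.
#' @param coverage_target name of the structure used for coverage indices
#'   (default `"PTV46"`, the composite pelvic target); skipped with a
#'   warning when absent.
#' @return object of class `plan_evaluation`: list with `plan_id`,
#'   `constraints` (data.frame: structure, metric, unit, comparator,
#'   limit, achieved, status in {pass, fail, not_evaluated}), `coverage`
#'   (list from [coverage_check] plus `pci`, `hi`, or NULL), `pass`
#'   (TRUE iff all evaluated entries pass).
#' @export
evaluate_plan <- function(dose, structures, template = constraint_template(),
                          plan_id = "plan", coverage_target = "PTV46") {
  stopifnot(inherits(dose, "dose_grid"), is.list(structures))
  res <- template
  res$achieved <- NA_real_
  res$status <- "not_evaluated"
  for (i in seq_len(nrow(res))) {
    m <- structures[[res$structure[i]]]
    if (is.null(m) || !any(m$occupancy)) next
    unit <- if (res$unit[i] %in% c("cc", "percent")) res$unit[i] else "cc"
    val <- compute_metric(dose, m, res$metric[i], unit)
    ok <- if (res$comparator[i] == "<") val < res$limit[i] else val <= res$limit[i]
    res$achieved[i] <- val
    res$status[i] <- if (ok) "pass" else "fail"
  }
  coverage <- NULL
  ptv <- structures[[coverage_target]]
  if (!is.null(ptv) && any(ptv$occupancy)) {
    coverage <- coverage_check(dose, ptv)
    # degenerate dose fields (e.g. all-zero plans) leave the indices NA
    coverage$pci <- tryCatch(suppressWarnings(paddick_ci(dose, ptv)),
                             error = function(e) NA_real_)
    coverage$hi <- tryCatch(homogeneity_index(dose, ptv),
                            error = function(e) NA_real_)
  } else {
    warning(sprintf("coverage target '%s' absent; coverage indices skipped",
                    coverage_target))
  }
  class(res) <- "data.frame"
  structure(list(plan_id = plan_id, constraints = res, coverage = coverage,
                 pass = all(res$status[res$status != "not_evaluated"] == "pass")),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("plan '%s': OAR constraints %s\n", x$plan_id,
              if (x$pass) "all pass" else "FAILED"))
  df <- x$constraints
  df$achieved <- round(df$achieved, 2)
  print(df, row.names = FALSE)
  if (!is.null(x$coverage))
    cat(sprintf("coverage: D95%% = %.1f%%, Dmax = %.1f%%, PCI = %.3f, HI = %.3f\n",
                x$coverage$d95_pct, x$coverage$dmax_pct,
                x$coverage$pci, x$coverage$hi))
  invisible(x)
}
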