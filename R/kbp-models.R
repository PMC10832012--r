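#' KBP model specification
#'
#' One predictor/response pairing of the knowledge-based planning layer:
#' an OAR dose metric predicted from a geometric feature of the patient's
#' anatomy relative to a target volume.
#'
#' @param id short unique identifier, e.g. `"rectum_v60"`.
#' @param oar OAR structure name, e.g. `"Rectum"`.
#' @param metric response dose metric descriptor (`"V60Gy"`, `"Davg"`...).
#' @param metric_unit `"percent"`, `"cc"` or `"Gy"`.
#' @param predictor one of `"overlap_fraction"` (% of the OAR volume
#'   inside the target), `"centroid_distance"` (cm between centers of
#'   mass), `"overlap_times_volume"` (overlap volume in cc times OAR
#'   volume in cc, unit cc^2).
#' @param target reference target volume name (`"PTV76"` or `"PTV46"`).
#' @return object of class `kbp_model_spec`.
#' @export
kbp_model_spec <- function(id, oar, metric, metric_unit, predictor, target) {
  predictor <- match.arg(predictor,
                         c("overlap_fraction", "centroid_distance",
                           "overlap_times_volume"))
  metric_unit <- match.arg(metric_unit, c("percent", "cc", "Gy"))
  invisible(parse_metric(metric))
  structure(list(id = id, oar = oar, metric = metric,
                 metric_unit = metric_unit, predictor = predictor,
                 target = target,
                 predictor_unit = switch(predictor,
                                         overlap_fraction = "percent",
                                         centroid_distance = "cm",
                                         overlap_times_volume = "cc2")),
            class = "kbp_model_spec")
}

#' Default KBP model registry
#'
#' The seven pairings of the prostate VMAT model set: rectum and bladder
#' V60Gy(%) and V70Gy(%) against their overlap fraction with the boost
#' target PTV76; peritoneal cavity Davg(Gy) against the cavity-to-PTV46
#' centroid distance; cavity V45Gy(cc) against the cavity/PTV46 overlap
#' fraction; cavity V15Gy(cc) against the product of overlap volume and
#' cavity volume (cc^2). Extensible: build additional [kbp_model_spec]s
#' and append.
#'
#' @return named list of [kbp_model_spec] objects.
#' @export
kbp_default_models <- function() {
  specs <- list(
    kbp_model_spec("rectum_v60", "Rectum", "V60Gy", "percent",
                   "overlap_fraction", "PTV76"),
    kbp_model_spec("rectum_v70", "Rectum", "V70Gy", "percent",
                   "overlap_fraction", "PTV76"),
    kbp_model_spec("bladder_v60", "Bladder", "V60Gy", "percent",
                   "overlap_fraction", "PTV76"),
    kbp_model_spec("bladder_v70", "Bladder", "V70Gy", "percent",
                   "overlap_fraction", "PTV76"),
    kbp_model_spec("cavity_davg", "PeritonealCavity", "Davg", "Gy",
                   "centroid_distance", "PTV46"),
    kbp_model_spec("cavity_v45", "PeritonealCavity", "V45Gy", "cc",
                   "overlap_fraction", "PTV46"),
    kbp_model_spec("cavity_v15", "PeritonealCavity", "V15Gy", "cc",
                   "overlap_times_volume", "PTV46"))
  stats::setNames(specs, vapply(specs, `[[`, "", "id"))
}

#' Extract the geometric predictor of a KBP model from a structure set
#'
#' @param spec a [kbp_model_spec].
#' @param structures named list of [structure_mask] objects containing the
#'   spec's OAR and target.
#' @return predictor value in the spec's predictor unit.
#' @export
extract_predictor <- function(spec, structures) {
  stopifnot(inherits(spec, "kbp_model_spec"))
  oar <- structures[[spec$oar]]
  tgt <- structures[[spec$target]]
  if (is.null(oar) || is.null(tgt))
    stop(sprintf("model '%s' needs structures '%s' and '%s'",
                 spec$id, spec$oar, spec$target))
  switch(spec$predictor,
         overlap_fraction = overlap_fraction(oar, tgt),
         centroid_distance = centroid_distance(oar, tgt),
         overlap_times_volume = overlap_volume(oar, tgt) * structure_volume(oar))
}

#' Fit a KBP model by ordinary least squares
#'
#' Fits `y = A x + B` to the training pairs of one model: the response
#' dose metric achieved in prior high-quality plans against their
#' geometric predictor. Stores the sufficient statistics needed to
#' reconstruct prediction intervals after serialization.
#'
#' @param spec a [kbp_model_spec].
#' @param x predictor values of the training plans.
#' @param y response metric values, same length.
#' @return object of class `fitted_kbp_model`: spec plus `A` (slope), `B`
#'   (intercept), `n`, `r_squared`, `residual_sd` (sqrt(SSE/(n-2))),
#'   `x_bar`, `sxx`.
#' @export
fit_kbp_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "kbp_model_spec"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("training pairs must be finite")
  n <- length(x)
  if (n < 3) stop(sprintf("model '%s': need at least 3 training plans", spec$id))
  if (diff(range(x)) == 0)
    stop(sprintf("model '%s': predictor is constant; cannot fit a line", spec$id))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless fits are legitimate here
  structure(list(spec = spec,
                 A = unname(stats::coef(fit)[2]),
                 B = unname(stats::coef(fit)[1]),
                 n = n,
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 x_bar = mean(x),
                 sxx = sum((x - mean(x))^2)),
            class = "fitted_kbp_model")
}

#' @export
print.fitted_kbp_model <- function(x, ...) {
  cat(sprintf("%s: %s %s(%s) = %.4g * %s(%s) + %.4g   [n = %d, R2 = %.3f, residual sd = %.3g]\n",
              x$spec$id, x$spec$oar, x$spec$metric, x$spec$metric_unit,
              x$A, x$spec$predictor, x$spec$predictor_unit, x$B,
              x$n, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict an achievable dose metric with a 95% band
#'
#' Point prediction `A x + B` with a t-based prediction interval for a
#' single new plan's achieved metric:
#' `yhat +/- t * s * sqrt(1 + 1/n + (x - x_bar)^2 / Sxx)`. The band is a
#' new-observation prediction interval, not a mean-response confidence
#' interval, because the clinical comparison is one new plan's achieved
#' value against the band.
#'
#' @param model a [fitted_kbp_model].
#' @param x predictor value(s) of the new plan(s).
#' @param level interval level in (0, 1); default 0.95.
#' @return data.frame with columns `model_id`, `x`, `predicted`, `lower`,
#'   `upper` (one row per element of `x`).
#' @export
predict_with_interval <- function(model, x, level = 0.95) {
  stopifnot(inherits(model, "fitted_kbp_model"))
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be inside (0, 1)")
  if (!is.finite(model$residual_sd))
    stop("model residual sd is not finite")
  x <- as.numeric(x)
  yhat <- model$A * x + model$B
  tq <- stats::qt((1 + level) / 2, df = model$n - 2)
  hw <- tq * model$residual_sd *
    sqrt(1 + 1 / model$n + (x - model$x_bar)^2 / model$sxx)
  data.frame(model_id = model$spec$id, x = x, predicted = yhat,
             lower = yhat - hw, upper = yhat + hw,
             stringsAsFactors = FALSE)
}

# interval comparison shared by audit paths
kbp_status <- function(achieved, lower, upper) {
  ifelse(achieved > upper, "above_upper",
         ifelse(achieved < lower, "below_lower", "within"))
}

#' Audit a plan against fitted KBP models
#'
#' For each model: extract the plan's geometric predictor, predict the
#' achievable metric with its 95% band, compute the achieved metric from
#' the dose grid, and flag the result. `above_upper` marks a suboptimal
#' result (more OAR dose than the model predicts is achievable) and is the
#' actionable alert; `below_lower` (better than predicted) is
#' informational. Per-model failures (e.g. a missing structure) are
#' reported in the `error` column without stopping the other models.
#'
#' @param dose a [dose_grid].
#' @param structures named list of [structure_mask] objects.
#' @param models list of [fitted_kbp_model] objects.
#' @param level interval level, default 0.95.
#' @return data.frame of class `kbp_audit` with one row per model:
#'   `model_id`, `oar`, `metric`, `x`, `predicted`, `lower`, `upper`,
#'   `achieved`, `status`, `error`.
#' @export
audit_plan <- function(dose, structures, models, level = 0.95) {
  rows <- lapply(models, function(m) {
    stopifnot(inherits(m, "fitted_kbp_model"))
    out <- data.frame(model_id = m$spec$id, oar = m$spec$oar,
                      metric = paste0(m$spec$metric, "(", m$spec$metric_unit, ")"),
                      x = NA_real_, predicted = NA_real_, lower = NA_real_,
                      upper = NA_real_, achieved = NA_real_,
                      status = NA_character_, error = NA_character_,
                      stringsAsFactors = FALSE)
    tryCatch({
      x <- extract_predictor(m$spec, structures)
      pr <- predict_with_interval(m, x, level)
      unit <- if (m$spec$metric_unit %in% c("cc", "percent")) m$spec$metric_unit else "cc"
      achieved <- compute_metric(dose, structures[[m$spec$oar]], m$spec$metric, unit)
      out$x <- x
      out$predicted <- pr$predicted; out$lower <- pr$lower; out$upper <- pr$upper
      out$achieved <- achieved
      out$status <- kbp_status(achieved, pr$lower, pr$upper)
      out
    }, error = function(e) { out$error <- conditionMessage(e); out })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("kbp_audit", "data.frame")
  res
}

#' @export
print.kbp_audit <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (!is.na(x$error[i])) {
      cat(sprintf("%-12s  not evaluated: %s\n", x$model_id[i], x$error[i]))
    } else {
      cat(sprintf("%-12s %s %-12s predicted %7.2f  [%7.2f, %7.2f]  achieved %7.2f  %s\n",
                  x$model_id[i], x$oar[i], x$metric[i], x$predicted[i],
                  x$lower[i], x$upper[i], x$achieved[i],
                  if (x$status[i] == "above_upper") "** SUBOPTIMAL **" else x$status[i]))
    }
  }
  invisible(x)
}

#' Serialize fitted KBP models to a YAML file and back
#'
#' Models are written as structured text (id, pairing, A, B, n, R2,
#' residual sd, x_bar, Sxx, units) so a clinic can version its model set
#' and reload it without refitting. Numbers are stored at full double
#' precision; the round trip is exact.
#'
#' @param models list of [fitted_kbp_model] objects.
#' @param path file path.
#' @return `read_kbp_models` returns a named list of [fitted_kbp_model];
#'   `write_kbp_models` returns `path` invisibly.
#' @export
write_kbp_models <- function(models, path) {
  num <- function(v) sprintf("%.17g", v)
  yaml::write_yaml(list(
    format = "kbpaudit-models", version = 1L,
    models = lapply(models, function(m) list(
      id = m$spec$id, oar = m$spec$oar, metric = m$spec$metric,
      metric_unit = m$spec$metric_unit, predictor = m$spec$predictor,
      target = m$spec$target,
      A = num(m$A), B = num(m$B), n = m$n,
      r_squared = num(m$r_squared), residual_sd = num(m$residual_sd),
      x_bar = num(m$x_bar), sxx = num(m$sxx)))), path)
  invisible(path)
}

#' @rdname write_kbp_models
#' @export
read_kbp_models <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$format, "kbpaudit-models") || !identical(y$version, 1L))
    stop("not a version-1 kbpaudit model file")
  ms <- lapply(y$models, function(e) {
    spec <- kbp_model_spec(e$id, e$oar, e$metric, e$metric_unit,
                           e$predictor, e$target)
    structure(list(spec = spec, A = as.numeric(e$A), B = as.numeric(e$B),
                   n = as.integer(e$n), r_squared = as.numeric(e$r_squared),
                   residual_sd = as.numeric(e$residual_sd),
                   x_bar = as.numeric(e$x_bar), sxx = as.numeric(e$sxx)),
              class = "fitted_kbp_model")
  })
  stats::setNames(ms, vapply(ms, function(m) m$spec$id, ""))
}
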