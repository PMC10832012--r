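#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent
#' samples, using midranks for ties. For small samples
#' (`max(n_a, n_b) <= 8` by default) the two-sided p-value is computed by
#' exhaustive enumeration of all C(n_a + n_b, n_a) group labelings of the
#' observed ranks; otherwise by the normal approximation with tie
#' correction and a 0.5 continuity correction. If every value in both
#' samples is identical the test is degenerate and p = 1.
#'
#' @param a,b numeric samples, both non-empty.
#' @param exact force exact enumeration (`TRUE`) or the asymptotic
#'   approximation (`FALSE`); default `NULL` applies the size rule.
#' @return list with `U` (statistic of sample `a`), `p` (two-sided),
#'   `method` (`"exact"` or `"asymptotic"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("samples must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (diff(range(c(a, b))) == 0)
    return(list(U = na * nb / 2, p = 1, method = "degenerate"))
  if (is.null(exact)) exact <- max(na, nb) <= 8
  if (exact) {
    picks <- utils::combn(n, na)
    rs <- colSums(matrix(r[picks], nrow = na))
    u_all <- rs - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
    list(U = u, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- min(abs(u - mu), 0.5)  # continuity correction toward the mean
    z <- (abs(u - mu) - cc) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * stats::pnorm(-z)), method = "asymptotic")
  }
}

#' Extract a per-plan metric table from plan evaluations
#'
#' Builds the wide table consumed by [compare_cohorts]: one row per plan,
#' one column per requested (structure, metric) pair, named
#' `"<structure>.<metric>"`.
#'
#' @param evals list of [plan_evaluation] objects.
#' @param keys data.frame with columns `structure` and `metric`; default:
#'   every constraint entry present in the first evaluation.
#' @return data.frame of metric values (NA where a plan lacks the entry).
#' @export
metric_table <- function(evals, keys = NULL) {
  stopifnot(length(evals) > 0)
  if (is.null(keys))
    keys <- evals[[1]]$constraints[c("structure", "metric")]
  cols <- paste(keys$structure, keys$metric, sep = ".")
  out <- as.data.frame(matrix(NA_real_, nrow = length(evals),
                              ncol = length(cols),
                              dimnames = list(NULL, cols)))
  for (i in seq_along(evals)) {
    cs <- evals[[i]]$constraints
    for (j in seq_len(nrow(keys))) {
      hit <- which(cs$structure == keys$structure[j] &
                     cs$metric == keys$metric[j])
      if (length(hit) == 1) out[i, j] <- cs$achieved[hit]
    }
  }
  out
}

#' Compare two plan cohorts metric by metric
#'
#' Reporting engine for a before/after audit: for each metric column it
#' computes Mean and sample SD (n-1 denominator) per arm, the mean
#' difference `delta = mean(wm) - mean(wom)` on *unrounded* means, the
#' two-sided Mann-Whitney p-value, and a significance flag at p < 0.05.
#' `wm`/`wom` conventionally denote the arms planned with / without the
#' predictive models.
#'
#' @param wm,wom data.frames with identical metric columns, one row per
#'   plan (see [metric_table]); both non-empty. NA entries mark a plan
#'   missing the metric; a column with any NA is reported but flagged
#'   incomplete and its test is computed on the complete values.
#' @param alpha significance threshold, default 0.05.
#' @return data.frame of class `cohort_comparison`: `metric`, `n_wm`,
#'   `mean_wm`, `sd_wm`, `n_wom`, `mean_wom`, `sd_wom`, `delta`,
#'   `p_value`, `significant`, `complete`.
#' @export
compare_cohorts <- function(wm, wom, alpha = 0.05) {
  wm <- as.data.frame(wm); wom <- as.data.frame(wom)
  if (nrow(wm) == 0 || nrow(wom) == 0) stop("both cohorts must be non-empty")
  metrics <- intersect(names(wm), names(wom))
  if (length(metrics) == 0) stop("the cohorts share no metric columns")
  rows <- lapply(metrics, function(m) {
    x <- wm[[m]]; y <- wom[[m]]
    complete <- !anyNA(x) && !anyNA(y)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0)
      return(data.frame(metric = m, n_wm = length(x), mean_wm = NA_real_,
                        sd_wm = NA_real_, n_wom = length(y),
                        mean_wom = NA_real_, sd_wom = NA_real_,
                        delta = NA_real_, p_value = NA_real_,
                        significant = NA, complete = FALSE,
                        stringsAsFactors = FALSE))
    p <- mann_whitney_u(x, y)$p
    data.frame(metric = m,
               n_wm = length(x), mean_wm = mean(x), sd_wm = stats::sd(x),
               n_wom = length(y), mean_wom = mean(y), sd_wom = stats::sd(y),
               delta = mean(x) - mean(y), p_value = p,
               significant = p < alpha, complete = complete,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("cohort_comparison", "data.frame")
  res
}

#' @export
print.cohort_comparison <- function(x, digits = 1, ...) {
  fmt <- function(m, s) sprintf(paste0("%.", digits, "f (%.", digits, "f)"), m, s)
  df <- data.frame(metric = x$metric,
                   `WM Mean(SD)` = fmt(x$mean_wm, x$sd_wm),
                   `WOM Mean(SD)` = fmt(x$mean_wom, x$sd_wom),
                   delta = sprintf(paste0("%.", digits, "f%s"),
                                   round(x$delta, digits),
                                   ifelse(x$significant, " *", "")),
                   p = sprintf("%.3f", x$p_value),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  cat("* p <", format(0.05), "(Mann-Whitney, two-sided)\n")
  invisible(x)
}

#' Constraint exceedance rate across a cohort
#'
#' How often a cohort failed one template constraint: the count of plans
#' whose evaluation marks the (structure, metric) entry `fail`, and the
#' unrounded percentage of the cohort.
#'
#' @param evals list of [plan_evaluation] objects.
#' @param structure,metric the constraint entry, e.g.
#'   `"PeritonealCavity"`, `"V15Gy"`.
#' @return list with `count`, `n` (plans with the entry evaluated) and
#'   `percent` (100 * count / n, unrounded).
#' @export
exceedance_rate <- function(evals, structure, metric) {
  st <- vapply(evals, function(e) {
    cs <- e$constraints
    hit <- which(cs$structure == structure & cs$metric == metric)
    if (length(hit) != 1) NA_character_ else cs$status[hit]
  }, "")
  st <- st[!is.na(st) & st != "not_evaluated"]
  if (length(st) == 0) stop("constraint entry not evaluated in any plan")
  list(count = sum(st == "fail"), n = length(st),
       percent = 100 * sum(st == "fail") / length(st))
}
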