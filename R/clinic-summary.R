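#' Published clinic audit summary
#'
#' The before/after OAR dose summary of the prostate VMAT clinic whose
#' practice the KBP workflow was developed in: per (structure, metric) the
#' printed Mean(SD) of the 25 plans optimized with the predictive models
#' (`wm`), of the 41 plans from before deployment (`wom`), the printed
#' mean difference and Mann-Whitney p-value. Useful as a reference point
#' and as input to the delta-reproduction checks: a `delta_consistent`
#' column marks the rows whose printed difference agrees with the printed
#' means at one-decimal precision (a few published rows differ by one
#' least digit because the differences were computed on unrounded means).
#'
#' @return data.frame with columns `structure`, `metric`, `unit`,
#'   `mean_wm`, `sd_wm`, `mean_wom`, `sd_wom`, `delta_printed`,
#'   `p_printed`, `delta_consistent`; plus attributes `n_wm` (25) and
#'   `n_wom` (41).
#' @export
clinic_cohort_summary <- function() {
  df <- utils::read.csv(system.file("extdata", "clinic_cohort_summary.csv",
                                    package = "kbpaudit"),
                        stringsAsFactors = FALSE)
  df$delta_consistent <-
    round(df$mean_wm - df$mean_wom, 1) == df$delta_printed
  attr(df, "n_wm") <- 25L
  attr(df, "n_wom") <- 41L
  df
}
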