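#' Benchmark plan-quality table for spherical targets
#'
#' Plan-quality indices (Dmax%, Dmean%, RTOG CI, Paddick GI) of 48
#' benchmark VMAT SRS plans: 8 spherical GTV diameters (0.5-4.0 cm in
#' 0.5 cm steps) x 3 GTV-PTV margins (0/1/2 mm) x 2 beam arrangements
#' (coplanar, non-coplanar). These indices calibrate the radial falloff
#' model for every configuration of the factorial study.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`gtv_diameter_cm, margin_mm, beams, dmax_pct, dmean_pct, rtog_ci,
#'   paddick_gi`).
#' @return A data.frame with one row per plan.
#' @export
plan_quality_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "plan_quality_vmat.csv",
                        package = "idpsrs", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gtv_diameter_cm", "margin_mm", "beams", "dmax_pct",
            "dmean_pct", "rtog_ci", "paddick_gi")
  if (!all(need %in% names(df)))
    stop("plan-quality table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Look up one plan-quality row
#'
#' @param table A [plan_quality_table()].
#' @param gtv_diameter GTV diameter in cm.
#' @param margin Margin in mm.
#' @param beams `"coplanar"` or `"noncoplanar"`.
#' @return A [plan_quality()], or `NULL` (with a warning) when the
#'   configuration is absent from the table.
#' @export
lookup_plan_quality <- function(table, gtv_diameter, margin, beams) {
  row <- table[abs(table$gtv_diameter_cm - gtv_diameter) < 1e-9 &
                 abs(table$margin_mm - margin) < 1e-9 &
                 table$beams == beams, ]
  if (nrow(row) == 0) {
    warning(sprintf("no plan-quality entry for %.1f cm / %g mm / %s; skipped",
                    gtv_diameter, margin, beams))
    return(NULL)
  }
  plan_quality(row$dmax_pct[1], row$dmean_pct[1],
               row$rtog_ci[1], row$paddick_gi[1])
}
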