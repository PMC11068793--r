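#' Summarize a chart into the quantities the classification rules consume
#'
#' Aggregates site-level measurements over present natural teeth: maxima of
#' interdental CAL (sites MB, DB, ML, DL) and buccal/lingual CAL (B, L),
#' maximum probing depth, the bleeding-site fraction (bleeding sites over
#' probed natural-tooth sites), the set of affected teeth (>= 1 interdental
#' site with CAL at or above the case-definition threshold), worst
#' radiographic bone loss, and per-implant summaries. Unmeasured sites (NA
#' probing depth) are excluded from maxima and denominators rather than
#' imputed.
#'
#' @param chart a [periodontal_chart()].
#' @param config a [clinical_config()].
#' @return an object of class `chart_summary`.
#' @export
summarize_chart <- function(chart, config = clinical_config()) {
  stopifnot(inherits(chart, "periodontal_chart"))
  natural <- .present_natural(chart)
  implants <- .present_implants(chart)
  if (length(natural) == 0L && length(implants) == 0L) {
    stop("chart ", chart$chart_id, " has no present teeth or implants",
         call. = FALSE)
  }

  max_id_cal <- NA_integer_
  max_bl_cal <- NA_integer_
  max_pd <- NA_integer_
  n_bleed <- 0L
  n_probed <- 0L
  affected <- integer()
  bl_qualifying <- integer()
  worst_bone <- NA_real_
  max_furcation <- 0L
  any_vertical_defect <- FALSE
  any_cal_anywhere <- FALSE
  cal_threshold <- config$case$interdental_cal_min_mm
  bl_threshold <- config$case$buccal_lingual_cal_min_mm

  for (t in natural) {
    if (!is.na(t$bone_loss_percent)) {
      worst_bone <- max(worst_bone, t$bone_loss_percent, na.rm = TRUE)
    }
    max_furcation <- max(max_furcation, t$furcation_class)
    if ("vertical_defect" %in% t$flags) any_vertical_defect <- TRUE
    tooth_id_cal <- NA_integer_
    tooth_bl_cal <- NA_integer_
    for (s in t$sites) {
      if (is.na(s$pd)) next  # unmeasured site: excluded (no imputation)
      n_probed <- n_probed + 1L
      if (s$bop) n_bleed <- n_bleed + 1L
      cal <- compute_cal(s)
      max_pd <- max(max_pd, s$pd, na.rm = TRUE)
      if (!is.na(cal) && cal >= cal_threshold) any_cal_anywhere <- TRUE
      if (s$site %in% INTERDENTAL_SITES) {
        if (!is.na(cal)) tooth_id_cal <- max(tooth_id_cal, cal, na.rm = TRUE)
      } else {
        if (!is.na(cal)) tooth_bl_cal <- max(tooth_bl_cal, cal, na.rm = TRUE)
      }
    }
    if (!is.na(tooth_id_cal)) {
      max_id_cal <- max(max_id_cal, tooth_id_cal, na.rm = TRUE)
      if (tooth_id_cal >= cal_threshold) {
        affected <- c(affected, t$tooth_number)
      }
    }
    if (!is.na(tooth_bl_cal)) {
      max_bl_cal <- max(max_bl_cal, tooth_bl_cal, na.rm = TRUE)
      if (tooth_bl_cal >= bl_threshold) {
        bl_qualifying <- c(bl_qualifying, t$tooth_number)
      }
    }
  }

  implant_summaries <- lapply(implants, function(t) {
    measured <- Filter(function(s) !is.na(s$pd), t$sites)
    list(tooth_number = t$tooth_number,
         any_bop = any(vapply(measured, `[[`, logical(1), "bop")),
         any_sup = any(vapply(measured, `[[`, logical(1), "sup")),
         progressive_bone_loss = "progressive_bone_loss" %in% t$flags,
         bone_loss_percent = t$bone_loss_percent)
  })
  names(implant_summaries) <- NULL

  structure(
    list(
      max_interdental_cal_mm = max_id_cal,
      max_cal_mm_buccal_lingual = max_bl_cal,
      max_probing_depth_mm = max_pd,
      bleeding_site_fraction = if (n_probed > 0L) n_bleed / n_probed else
        NA_real_,
      affected_teeth = sort(affected),
      buccal_lingual_qualifying_teeth = sort(bl_qualifying),
      scorable_teeth_count = length(natural),
      worst_bone_loss_percent = worst_bone,
      max_furcation_class = max_furcation,
      any_vertical_defect = any_vertical_defect,
      any_attachment_loss = any_cal_anywhere,
      probed_site_count = n_probed,
      implant_summaries = implant_summaries
    ),
    class = "chart_summary"
  )
}
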