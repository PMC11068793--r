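#' @title Classification engine
#' @description Deterministic implementation of the 2017 AAP/EFP logic:
#'   periodontitis case definition, stage (severity + complexity + stage IV
#'   discriminators), grade (indirect evidence ratio with upgrade-only risk
#'   modifiers), extent (30% cut-off and the molar-incisor pattern),
#'   gingival status on intact/reduced periodontium, and peri-implant
#'   status. Every rule that fires is recorded by a stable identifier in the
#'   diagnosis rationale.
#' @name classification
NULL

PERIO_CATEGORIES <- c(
  "clinical_gingival_health_intact", "clinical_gingival_health_reduced",
  "gingivitis", "periodontitis", "peri_implant_health",
  "peri_implant_mucositis", "peri_implantitis"
)

#' Construct a primary diagnosis
#'
#' Stage, grade and extent are "none" unless the category is periodontitis
#' (enforced).
#'
#' @param category one of the seven primary categories.
#' @param extent localized / generalized / molar_incisor_pattern / none.
#' @param stage I / II / III / IV / none.
#' @param grade A / B / C / none.
#' @param rationale character vector of fired-rule identifiers (>= 1).
#' @return object of class `primary_diagnosis`.
#' @export
primary_diagnosis <- function(category, extent = "none", stage = "none",
                              grade = "none", rationale = character()) {
  stopifnot(category %in% PERIO_CATEGORIES)
  stopifnot(extent %in% c("localized", "generalized", "molar_incisor_pattern",
                          "none"))
  stopifnot(stage %in% c("I", "II", "III", "IV", "none"))
  stopifnot(grade %in% c("A", "B", "C", "none"))
  if (category == "periodontitis") {
    if (extent == "none" || stage == "none" || grade == "none") {
      stop("periodontitis requires extent, stage and grade", call. = FALSE)
    }
  } else if (extent != "none" || stage != "none" || grade != "none") {
    stop("extent/stage/grade only apply to periodontitis", call. = FALSE)
  }
  if (length(rationale) == 0L) {
    stop("a diagnosis must carry at least one rationale entry", call. = FALSE)
  }
  structure(list(category = category, extent = extent, stage = stage,
                 grade = grade, rationale = rationale),
            class = "primary_diagnosis")
}

#' Human-readable diagnosis label
#'
#' Periodontitis renders as e.g. "generalized periodontitis stage IV grade
#' C"; other categories render as their category name.
#'
#' @param diagnosis a `primary_diagnosis`.
#' @return character scalar.
#' @export
diagnosis_label <- function(diagnosis) {
  stopifnot(inherits(diagnosis, "primary_diagnosis"))
  if (diagnosis$category != "periodontitis") return(diagnosis$category)
  extent <- switch(diagnosis$extent,
                   localized = "localized",
                   generalized = "generalized",
                   molar_incisor_pattern = "molar-incisor pattern")
  paste0(extent, " periodontitis stage ", diagnosis$stage, " grade ",
         diagnosis$grade)
}

#' Apply the periodontitis case definition
#'
#' A chart is a periodontitis case when (a) >= 2 present natural teeth, at
#' least two of them non-adjacent, each show >= 1 interproximal site with
#' CAL at or above the interdental threshold (interdental rule; takes
#' precedence), or (b) >= 2 teeth show buccal or lingual CAL >= 3 mm
#' (buccal/lingual rule).
#'
#' @param chart a [periodontal_chart()].
#' @param config a [clinical_config()].
#' @param summary optional precomputed [summarize_chart()] result.
#' @return an object of class `case_evidence` with fields
#'   `qualifying_interdental_teeth`, `qualifying_buccal_lingual_teeth`,
#'   `rule_used` (interdental_rule / buccal_lingual_rule / none) and
#'   `is_case`.
#' @export
is_periodontitis_case <- function(chart, config = clinical_config(),
                                  summary = NULL) {
  if (is.null(summary)) summary <- summarize_chart(chart, config)
  id_teeth <- summary$affected_teeth
  bl_teeth <- summary$buccal_lingual_qualifying_teeth
  has_nonadjacent_pair <- function(teeth) {
    if (length(teeth) < 2L) return(FALSE)
    for (i in seq_len(length(teeth) - 1L)) {
      for (j in seq((i + 1L), length(teeth))) {
        if (teeth_non_adjacent(teeth[i], teeth[j])) return(TRUE)
      }
    }
    FALSE
  }
  rule <- "none"
  if (length(id_teeth) >= config$case$min_qualifying_teeth &&
      has_nonadjacent_pair(id_teeth)) {
    rule <- "interdental_rule"
  } else if (length(bl_teeth) >= config$case$min_qualifying_teeth) {
    rule <- "buccal_lingual_rule"
  }
  structure(list(qualifying_interdental_teeth = id_teeth,
                 qualifying_buccal_lingual_teeth = bl_teeth,
                 rule_used = rule, is_case = rule != "none"),
            class = "case_evidence")
}

#' Assign the periodontitis stage
#'
#' Severity stage from the maximum interproximal CAL over affected teeth
#' (1-2 mm -> I, 3-4 mm -> II, >= 5 mm -> III/IV band); complexity factors
#' (max PD >= 6 mm, furcation class >= II, vertical defect) raise the stage
#' to at least the III/IV band; within that band, stage IV requires >= 5
#' teeth lost to periodontitis, < 20 remaining teeth, or masticatory
#' dysfunction, otherwise III. The returned stage is the maximum of the
#' severity and complexity stages.
#'
#' @param summary a [summarize_chart()] result.
#' @param profile a [patient_profile()].
#' @param config a [clinical_config()].
#' @param evidence optional `case_evidence`; staging a non-case is an error.
#' @return list with `stage` and `rationale`.
#' @export
assign_stage <- function(summary, profile, config = clinical_config(),
                         evidence = NULL) {
  if (!is.null(evidence) && !evidence$is_case) {
    stop("assign_stage called on a chart that is not a periodontitis case",
         call. = FALSE)
  }
  rationale <- character()
  cal <- summary$max_interdental_cal_mm
  if (is.na(cal) || cal < config$case$interdental_cal_min_mm) {
    # buccal/lingual-rule case with no interdental breakdown: severity from
    # the worst buccal/lingual CAL instead
    cal <- summary$max_cal_mm_buccal_lingual
    rationale <- c(rationale, "stage.severity_from_buccal_lingual")
  }
  if (is.na(cal)) stop("no CAL evidence available for staging",
                       call. = FALSE)
  s1max <- config$stage$severity_cal_stage1_max_mm
  s2max <- config$stage$severity_cal_stage2_max_mm
  if (cal <= s1max) {
    severity <- 1L
    rationale <- c(rationale, "stage.severity_cal_1_2")
  } else if (cal <= s2max) {
    severity <- 2L
    rationale <- c(rationale, "stage.severity_cal_3_4")
  } else {
    severity <- 3L
    rationale <- c(rationale, "stage.severity_cal_ge_5")
  }
  band <- severity
  if (!is.na(summary$max_probing_depth_mm) &&
      summary$max_probing_depth_mm >= config$stage$complexity_pd_min_mm) {
    band <- max(band, 3L)
    rationale <- c(rationale, "stage.complexity_pd_ge_6")
  }
  if (summary$max_furcation_class >= config$stage$complexity_furcation_min) {
    band <- max(band, 3L)
    rationale <- c(rationale, "stage.complexity_furcation_ge_II")
  }
  if (summary$any_vertical_defect) {
    band <- max(band, 3L)
    rationale <- c(rationale, "stage.complexity_vertical_defect")
  }
  if (band < 3L) {
    stage <- c("I", "II")[band]
  } else {
    remaining <- summary$scorable_teeth_count
    iv <- FALSE
    if (profile$teeth_lost_to_periodontitis >=
        config$stage$stage4_teeth_lost_min) {
      iv <- TRUE
      rationale <- c(rationale, "stage.iv_teeth_lost_ge_5")
    }
    if (remaining < config$stage$stage4_remaining_teeth_lt) {
      iv <- TRUE
      rationale <- c(rationale, "stage.iv_fewer_than_20_teeth")
    }
    if (profile$masticatory_dysfunction) {
      iv <- TRUE
      rationale <- c(rationale, "stage.iv_masticatory_dysfunction")
    }
    stage <- if (iv) "IV" else "III"
    if (!iv) rationale <- c(rationale, "stage.iii_no_iv_discriminator")
  }
  list(stage = stage, rationale = rationale)
}

#' Assign the periodontitis grade
#'
#' Indirect evidence: r = worst radiographic bone loss (% of root length) /
#' age in years. r < 0.25 -> A; 0.25 <= r <= 1.0 -> B (closed interval);
#' r > 1.0 -> C. Risk modifiers only upgrade: smoking >= 10 cigarettes/day
#' or HbA1c >= 7.0% forces C; smoking 1-9/day or diagnosed diabetes with
#' HbA1c < 7.0 or unknown forces at least B.
#'
#' @inheritParams assign_stage
#' @return list with `grade`, `ratio` and `rationale`.
#' @export
assign_grade <- function(summary, profile, config = clinical_config(),
                         evidence = NULL) {
  if (!is.null(evidence) && !evidence$is_case) {
    stop("assign_grade called on a chart that is not a periodontitis case",
         call. = FALSE)
  }
  if (is.na(summary$worst_bone_loss_percent)) {
    stop("grading evidence missing: no radiographic bone loss recorded on ",
         "any tooth", call. = FALSE)
  }
  stopifnot(profile$age_years > 0)
  r <- summary$worst_bone_loss_percent / profile$age_years
  g <- config$grade
  if (r < g$ratio_a_below) {
    base <- 1L
    rationale <- "grade.ratio_below_0.25_A"
  } else if (r <= g$ratio_c_above) {
    base <- 2L
    rationale <- "grade.ratio_0.25_to_1_B"
  } else {
    base <- 3L
    rationale <- "grade.ratio_above_1_C"
  }
  grade <- base
  smk <- profile$smoking_cigarettes_per_day
  if (smk >= g$smoking_c_min) {
    grade <- 3L
    rationale <- c(rationale, "grade.smoking_ge_10_C")
  } else if (smk >= g$smoking_b_min && grade < 2L) {
    grade <- 2L
    rationale <- c(rationale, "grade.smoking_1_9_at_least_B")
  }
  if (profile$has_diabetes) {
    if (!is.na(profile$hba1c_percent) &&
        profile$hba1c_percent >= g$hba1c_c_min) {
      grade <- 3L
      rationale <- c(rationale, "grade.hba1c_ge_7_C")
    } else if (grade < 2L) {
      grade <- 2L
      rationale <- c(rationale, "grade.diabetes_at_least_B")
    }
  }
  list(grade = c("A", "B", "C")[grade], ratio = r, rationale = rationale)
}

#' Assign the periodontitis extent
#'
#' Fraction of scorable (present natural) teeth affected: < 30% localized,
#' >= 30% generalized. When the affected set is confined to first/second
#' molars and incisors with both groups represented, the molar-incisor
#' pattern takes precedence.
#'
#' @param summary a [summarize_chart()] result.
#' @param config a [clinical_config()].
#' @param evidence optional `case_evidence`.
#' @return list with `extent`, `fraction` and `rationale`.
#' @export
assign_extent <- function(summary, config = clinical_config(),
                          evidence = NULL) {
  if (!is.null(evidence) && !evidence$is_case) {
    stop("assign_extent called on a chart that is not a periodontitis case",
         call. = FALSE)
  }
  if (summary$scorable_teeth_count == 0L) {
    stop("no scorable teeth: extent undefined", call. = FALSE)
  }
  affected <- summary$affected_teeth
  f <- length(affected) / summary$scorable_teeth_count
  mi_pool <- c(FIRST_SECOND_MOLARS, INCISORS)
  if (length(affected) > 0L && all(affected %in% mi_pool) &&
      any(affected %in% FIRST_SECOND_MOLARS) &&
      any(affected %in% INCISORS)) {
    return(list(extent = "molar_incisor_pattern", fraction = f,
                rationale = "extent.molar_incisor_pattern"))
  }
  if (f < config$extent$generalized_fraction) {
    list(extent = "localized", fraction = f,
         rationale = "extent.localized_lt_30pct")
  } else {
    list(extent = "generalized", fraction = f,
         rationale = "extent.generalized_ge_30pct")
  }
}

#' Classify gingival status for a non-case chart
#'
#' Bleeding-site fraction < 10% is clinical gingival health: on an intact
#' periodontium when there is no attachment loss, no radiographic bone
#' loss, no teeth lost to periodontitis and no periodontal-treatment
#' history, otherwise on a reduced periodontium. BOP >= 10% is gingivitis,
#' annotated localized (10-30%) or generalized (> 30%).
#'
#' @param summary a [summarize_chart()] result.
#' @param profile a [patient_profile()].
#' @param config a [clinical_config()].
#' @return a `primary_diagnosis`.
#' @export
classify_gingival_status <- function(summary, profile,
                                     config = clinical_config()) {
  if (summary$scorable_teeth_count == 0L) {
    stop("gingival status requires present natural teeth", call. = FALSE)
  }
  bop <- summary$bleeding_site_fraction
  if (is.na(bop)) bop <- 0
  reduced <- .reduced_periodontium(summary, profile)
  if (bop < config$gingival$health_bop_below) {
    if (reduced) {
      primary_diagnosis("clinical_gingival_health_reduced",
                        rationale = c("gingival.bop_below_10pct",
                                      "gingival.reduced_periodontium"))
    } else {
      primary_diagnosis("clinical_gingival_health_intact",
                        rationale = c("gingival.bop_below_10pct",
                                      "gingival.intact_periodontium"))
    }
  } else {
    annot <- if (bop > config$gingival$generalized_bop_above) {
      "gingival.gingivitis_generalized_gt_30pct"
    } else {
      "gingival.gingivitis_localized_10_30pct"
    }
    extra <- if (reduced) "gingival.reduced_periodontium" else character()
    primary_diagnosis("gingivitis",
                      rationale = c("gingival.bop_ge_10pct", annot, extra))
  }
}

.reduced_periodontium <- function(summary, profile) {
  isTRUE(summary$any_attachment_loss) ||
    (!is.na(summary$worst_bone_loss_percent) &&
       summary$worst_bone_loss_percent > 0) ||
    profile$teeth_lost_to_periodontitis > 0L ||
    profile$history_of_periodontal_treatment
}

#' Classify each implant
#'
#' Peri-implant health (no bleeding, no suppuration, no progressive bone
#' loss), peri-implant mucositis (bleeding/suppuration without progressive
#' bone loss) or peri-implantitis (progressive bone loss, with or without
#' bleeding).
#'
#' @param chart a [periodontal_chart()].
#' @param config a [clinical_config()].
#' @return list of `primary_diagnosis` objects, one per implant, named by
#'   position; empty list when the chart has no implants.
#' @export
classify_implants <- function(chart, config = clinical_config()) {
  implants <- .present_implants(chart)
  out <- lapply(implants, function(t) {
    measured <- Filter(function(s) !is.na(s$pd), t$sites)
    any_inflam <- any(vapply(measured, function(s) s$bop || s$sup,
                             logical(1)))
    progressive <- "progressive_bone_loss" %in% t$flags
    if (progressive) {
      primary_diagnosis("peri_implantitis",
                        rationale = paste0("implant.", t$tooth_number,
                                           ".progressive_bone_loss"))
    } else if (any_inflam) {
      primary_diagnosis("peri_implant_mucositis",
                        rationale = paste0("implant.", t$tooth_number,
                                           ".bop_without_bone_loss"))
    } else {
      primary_diagnosis("peri_implant_health",
                        rationale = paste0("implant.", t$tooth_number,
                                           ".no_inflammation"))
    }
  })
  names(out) <- vapply(implants, function(t) as.character(t$tooth_number),
                       character(1))
  out
}

.IMPLANT_SEVERITY <- c(peri_implant_health = 1L, peri_implant_mucositis = 2L,
                       peri_implantitis = 3L)

#' Diagnose a chart
#'
#' Orchestrates the full rule set: applies the case definition; for a case,
#' assigns extent, stage and grade; otherwise classifies gingival status;
#' for an implant-only dentition the worst per-implant status becomes the
#' primary diagnosis. Per-implant diagnoses, secondary findings and static
#' treatment options for every diagnosis are appended. Identical input
#' yields an identical report.
#'
#' @param chart a [periodontal_chart()].
#' @param config a [clinical_config()].
#' @return an object of class `diagnosis_report`: list with `primary`
#'   (`primary_diagnosis`), `label`, `implants`, `secondary`,
#'   `treatment_options` and `rationale`.
#' @export
diagnose <- function(chart, config = clinical_config()) {
  stopifnot(inherits(chart, "periodontal_chart"))
  profile <- chart$profile
  summary <- summarize_chart(chart, config)
  evidence <- is_periodontitis_case(chart, config, summary = summary)
  implants <- classify_implants(chart, config)

  if (summary$scorable_teeth_count > 0L) {
    if (evidence$is_case) {
      ext <- assign_extent(summary, config, evidence)
      stg <- assign_stage(summary, profile, config, evidence)
      grd <- assign_grade(summary, profile, config, evidence)
      primary <- primary_diagnosis(
        "periodontitis", extent = ext$extent, stage = stg$stage,
        grade = grd$grade,
        rationale = c(paste0("case.", evidence$rule_used), ext$rationale,
                      stg$rationale, grd$rationale))
    } else {
      primary <- classify_gingival_status(summary, profile, config)
      primary$rationale <- c("case.none", primary$rationale)
    }
  } else {
    # implant-only dentition: the worst implant status is the primary
    if (length(implants) == 0L) {
      stop("chart has neither natural teeth nor implants", call. = FALSE)
    }
    worst <- implants[[which.max(vapply(
      implants, function(d) .IMPLANT_SEVERITY[[d$category]], integer(1)))]]
    primary <- primary_diagnosis(worst$category,
                                 rationale = c("case.implant_only_dentition",
                                               worst$rationale))
  }

  secondary <- detect_secondary(chart, profile, config)
  treatments <- .treatment_options(primary, secondary)
  rationale <- c(primary$rationale,
                 unlist(lapply(implants, `[[`, "rationale"),
                        use.names = FALSE),
                 unlist(lapply(secondary, `[[`, "rationale"),
                        use.names = FALSE))
  structure(
    list(primary = primary, label = diagnosis_label(primary),
         implants = implants, secondary = secondary,
         treatment_options = treatments, rationale = rationale,
         chart_id = chart$chart_id),
    class = "diagnosis_report"
  )
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat("<diagnosis_report>", x$chart_id, "\n")
  cat("  primary:  ", x$label, "\n")
  if (length(x$implants)) {
    for (nm in names(x$implants)) {
      cat("  implant #", nm, ": ", x$implants[[nm]]$category, "\n", sep = "")
    }
  }
  for (s in x$secondary) {
    cat("  secondary:", s$category,
        if (length(s$teeth)) paste0("(teeth ",
                                    paste(s$teeth, collapse = ", "), ")")
        else "(patient-level)", "\n")
  }
  cat("  treatment options:\n")
  for (t in x$treatment_options) cat("   -", t, "\n")
  invisible(x)
}

#' Serialize a diagnosis report to JSON
#'
#' @param report a `diagnosis_report`.
#' @param pretty pretty-print?
#' @return JSON string.
#' @export
report_to_json <- function(report, pretty = TRUE) {
  stopifnot(inherits(report, "diagnosis_report"))
  obj <- list(
    chart_id = report$chart_id,
    primary = list(category = report$primary$category,
                   extent = report$primary$extent,
                   stage = report$primary$stage,
                   grade = report$primary$grade,
                   label = report$label),
    implants = lapply(report$implants, function(d) {
      list(category = d$category)
    }),
    secondary = lapply(report$secondary, function(s) {
      list(category = s$category, teeth = as.list(s$teeth))
    }),
    treatment_options = as.list(report$treatment_options),
    rationale = as.list(report$rationale)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty, null = "null")
}

# static per-diagnosis treatment text ------------------------------------------

.TREATMENTS <- list(
  clinical_gingival_health_intact = c(
    "Reinforce oral hygiene; routine prophylaxis and periodontal maintenance",
    "Re-evaluate at regular recall intervals"),
  clinical_gingival_health_reduced = c(
    "Reinforce oral hygiene; periodontal maintenance at shortened intervals",
    "Monitor attachment levels for recurrence"),
  gingivitis = c(
    "Oral hygiene instruction and patient motivation",
    "Professional mechanical plaque removal; control local retentive factors",
    "Re-evaluate gingival bleeding after initial therapy"),
  periodontitis = c(
    "Oral hygiene instruction and risk-factor control",
    "Scaling and root planing (non-surgical periodontal therapy)",
    "Periodontal re-evaluation in 4-6 weeks",
    "Consider surgical therapy for residual pockets >= 5 mm",
    "Supportive periodontal therapy at risk-based intervals"),
  peri_implant_health = c(
    "Routine implant maintenance and hygiene reinforcement"),
  peri_implant_mucositis = c(
    "Submarginal professional biofilm removal around the implant",
    "Oral hygiene reinforcement; re-evaluate bleeding in 4-6 weeks"),
  peri_implantitis = c(
    "Non-surgical debridement of the implant surface",
    "Consider surgical access and regenerative or resective therapy",
    "Radiographic monitoring of peri-implant bone levels"),
  tooth_prosthesis_related_factors = c(
    "Correct or replace defective restorations; re-establish cleansable margins"),
  occlusal_trauma = c(
    "Occlusal analysis and selective adjustment; consider splinting mobile teeth"),
  mucogingival_deformity = c(
    "Evaluate need for mucogingival (soft-tissue graft) surgery"),
  periodontitis_systemic_manifestation = c(
    "Coordinate care with the treating physician; intensify periodontal therapy"),
  endo_periodontal_lesion = c(
    "Endodontic therapy first, then re-evaluate periodontal component"),
  periodontal_abscess = c(
    "Drainage and debridement of the abscess; analgesia as needed",
    "Systemic antibiotics only with systemic involvement")
)

.treatment_options <- function(primary, secondary) {
  out <- .TREATMENTS[[primary$category]]
  for (s in secondary) out <- c(out, .TREATMENTS[[s$category]])
  unique(out)
}
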