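#' Detect secondary periodontal conditions
#'
#' Deterministic flag-and-threshold rules for the six tracked secondary
#' categories:
#' \itemize{
#'   \item tooth_prosthesis_related_factors: defective_restoration,
#'     subgingival_margin, enamel_projection or root_proximity flag;
#'   \item occlusal_trauma: fremitus or widened_pdl flag, or mobility class
#'     >= 2;
#'   \item mucogingival_deformity: any site recession >= 2 mm or the
#'     keratinized_tissue_deficiency flag;
#'   \item periodontitis_systemic_manifestation: patient-level, when the
#'     profile's systemic disease codes intersect the configured manifest
#'     list;
#'   \item endo_periodontal_lesion: endodontic_involvement flag plus a site
#'     with PD >= 6 mm on the same tooth;
#'   \item periodontal_abscess: abscess flag, or suppuration at a site with
#'     PD >= 4 mm.
#' }
#' Categories are not mutually exclusive; the output is sorted by category
#' for determinism. Detections over disjoint tooth sets are independent, so
#' merging two charts' flags yields the union of their detections.
#'
#' @param chart a [periodontal_chart()].
#' @param profile a [patient_profile()]; defaults to the chart's.
#' @param config a [clinical_config()].
#' @return list of `secondary_diagnosis` objects (possibly empty), each with
#'   `category`, `teeth` (integer vector; empty for the patient-level
#'   systemic category) and `rationale`.
#' @export
detect_secondary <- function(chart, profile = chart$profile,
                             config = clinical_config()) {
  stopifnot(inherits(chart, "periodontal_chart"))
  sc <- config$secondary
  hits <- list()
  add <- function(category, teeth, rationale) {
    hits[[length(hits) + 1L]] <<- structure(
      list(category = category, teeth = sort(unique(as.integer(teeth))),
           rationale = rationale),
      class = "secondary_diagnosis")
  }

  occupied <- Filter(function(t) t$present, chart$teeth)
  tp_teeth <- integer(); ot_teeth <- integer(); mg_teeth <- integer()
  ep_teeth <- integer(); ab_teeth <- integer()
  tp_flags <- c("defective_restoration", "subgingival_margin",
                "enamel_projection", "root_proximity")
  for (t in occupied) {
    if (any(tp_flags %in% t$flags)) tp_teeth <- c(tp_teeth, t$tooth_number)
    if (any(c("fremitus", "widened_pdl") %in% t$flags) ||
        t$mobility_class >= sc$trauma_mobility_min) {
      ot_teeth <- c(ot_teeth, t$tooth_number)
    }
    max_pd <- suppressWarnings(max(vapply(
      t$sites, function(s) if (is.na(s$pd)) -1L else s$pd, integer(1)),
      -1L))
    any_deep_rec <- any(vapply(t$sites, function(s) {
      !is.na(s$rec) && s$rec >= sc$mucogingival_recession_min_mm
    }, logical(1)))
    if (any_deep_rec || "keratinized_tissue_deficiency" %in% t$flags) {
      mg_teeth <- c(mg_teeth, t$tooth_number)
    }
    if ("endodontic_involvement" %in% t$flags &&
        max_pd >= sc$endo_lesion_pd_min_mm) {
      ep_teeth <- c(ep_teeth, t$tooth_number)
    }
    sup_deep <- any(vapply(t$sites, function(s) {
      s$sup && !is.na(s$pd) && s$pd >= sc$abscess_pd_min_mm
    }, logical(1)))
    if ("abscess" %in% t$flags || sup_deep) {
      ab_teeth <- c(ab_teeth, t$tooth_number)
    }
  }

  if (length(ep_teeth)) {
    add("endo_periodontal_lesion", ep_teeth,
        paste0("secondary.endo_perio.", ep_teeth))
  }
  if (length(mg_teeth)) {
    add("mucogingival_deformity", mg_teeth,
        paste0("secondary.mucogingival.", mg_teeth))
  }
  if (length(ot_teeth)) {
    add("occlusal_trauma", ot_teeth,
        paste0("secondary.occlusal_trauma.", ot_teeth))
  }
  if (length(ab_teeth)) {
    add("periodontal_abscess", ab_teeth,
        paste0("secondary.abscess.", ab_teeth))
  }
  manifest <- intersect(profile$systemic_disease_codes,
                        sc$systemic_manifestation_codes)
  if (length(manifest)) {
    add("periodontitis_systemic_manifestation", integer(),
        paste0("secondary.systemic.", manifest))
  }
  if (length(tp_teeth)) {
    add("tooth_prosthesis_related_factors", tp_teeth,
        paste0("secondary.tooth_prosthesis.", tp_teeth))
  }
  hits[order(vapply(hits, `[[`, character(1), "category"))]
}

SECONDARY_CATEGORIES <- c(
  "endo_periodontal_lesion", "mucogingival_deformity", "occlusal_trauma",
  "periodontal_abscess", "periodontitis_systemic_manifestation",
  "tooth_prosthesis_related_factors"
)
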