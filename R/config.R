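#' Clinical rule constants
#'
#' All numeric thresholds used by the classification engine, the secondary
#' findings rules, and the default decision tree come from this one versioned
#' configuration object, so that future revisions of the classification are
#' data edits rather than code edits, and so that the question tree and the
#' engine cannot drift apart.
#'
#' The defaults encode the 2017 AAP/EFP classification of periodontal and
#' peri-implant diseases: the periodontitis case definition (interproximal
#' CAL in >= 2 non-adjacent teeth, or buccal/lingual CAL >= 3 mm in >= 2
#' teeth), severity staging on interdental CAL (1-2 mm -> I, 3-4 mm -> II,
#' >= 5 mm -> III/IV) with complexity shift-up (PD >= 6 mm, furcation class
#' >= II, vertical defect), stage IV discriminators (>= 5 teeth lost to
#' periodontitis, < 20 remaining teeth, masticatory dysfunction), indirect
#' grading on percent bone loss / age (< 0.25 -> A, 0.25-1.0 -> B, > 1.0 ->
#' C) with upgrade-only risk modifiers (smoking, diabetes/HbA1c), the 30%
#' extent cut-off, and gingival BOP cut-offs (10% / 30%).
#'
#' @param overrides named list of values to override, using the same nesting
#'   as the returned list (e.g. `list(grade = list(smoking_c_min = 20))`).
#' @return a named list of class `perio_config`.
#' @examples
#' cfg <- clinical_config()
#' cfg$stage$complexity_pd_min
#' clinical_config(list(extent = list(generalized_fraction = 0.25)))$extent
#' @export
clinical_config <- function(overrides = list()) {
  cfg <- list(
    version = "2017.1",
    case = list(
      interdental_cal_min_mm     = 1L,
      buccal_lingual_cal_min_mm  = 3L,
      min_qualifying_teeth       = 2L
    ),
    stage = list(
      severity_cal_stage1_max_mm = 2L,  # 1-2 mm CAL -> stage I
      severity_cal_stage2_max_mm = 4L,  # 3-4 mm CAL -> stage II; >= 5 -> III/IV
      complexity_pd_min_mm       = 6L,  # PD >= 6 mm forces stage >= III
      complexity_furcation_min   = 2L,  # furcation class >= II forces stage >= III
      stage4_teeth_lost_min      = 5L,
      stage4_remaining_teeth_lt  = 20L
    ),
    grade = list(
      ratio_a_below   = 0.25, # bone-loss% / age strictly below -> grade A
      ratio_c_above   = 1.00, # strictly above -> grade C; closed [0.25, 1] -> B
      smoking_c_min   = 10L,  # cigarettes/day forcing grade C
      smoking_b_min   = 1L,   # cigarettes/day forcing at least grade B
      hba1c_c_min     = 7.0   # HbA1c % forcing grade C in diabetics
    ),
    extent = list(
      generalized_fraction = 0.30
    ),
    gingival = list(
      health_bop_below          = 0.10,
      generalized_bop_above     = 0.30  # gingivitis annotation cut-off
    ),
    secondary = list(
      mucogingival_recession_min_mm = 2L,
      endo_lesion_pd_min_mm         = 6L,
      abscess_pd_min_mm             = 4L,
      trauma_mobility_min           = 2L,
      systemic_manifestation_codes  = c(
        "papillon_lefevre_syndrome", "leukocyte_adhesion_deficiency",
        "hypophosphatasia", "down_syndrome", "chediak_higashi_syndrome",
        "langerhans_cell_histiocytosis"
      )
    )
  )
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "perio_config"
  cfg
}

# -- tooth anatomy constants (Universal numbering, 1-32) ----------------------

SITE_IDS <- c("MB", "B", "DB", "ML", "L", "DL")
INTERDENTAL_SITES <- c("MB", "DB", "ML", "DL")
BUCCAL_LINGUAL_SITES <- c("B", "L")

# molars incl. third molars, plus maxillary first premolars: furcation-capable
MULTIROOTED_TEETH <- c(1:3, 5, 12, 14:19, 30:32)
# first and second molars (third molars excluded from the molar-incisor pattern)
FIRST_SECOND_MOLARS <- c(2, 3, 14, 15, 18, 19, 30, 31)
INCISORS <- c(7:10, 23:26)

TOOTH_FLAGS <- c(
  "defective_restoration", "subgingival_margin", "enamel_projection",
  "root_proximity", "endodontic_involvement", "abscess", "fremitus",
  "widened_pdl", "progressive_bone_loss", "vertical_defect",
  "keratinized_tissue_deficiency"
)

#' Are two teeth non-adjacent?
#'
#' Adjacency is defined as consecutive Universal numbers within the same
#' arch (1-16 maxilla, 17-32 mandible); teeth 16 and 17 are in different
#' quadrant corners and are therefore not adjacent.
#'
#' @param a,b tooth numbers (Universal 1-32).
#' @return logical.
#' @export
teeth_non_adjacent <- function(a, b) {
  same_arch <- (a <= 16) == (b <= 16)
  !(same_arch & abs(a - b) == 1L)
}

#' Convert Universal tooth numbers to FDI two-digit notation
#'
#' @param tooth integer vector of Universal numbers 1-32.
#' @return character vector of FDI codes ("18" ... "48").
#' @export
universal_to_fdi <- function(tooth) {
  stopifnot(all(tooth %in% 1:32))
  fdi <- character(length(tooth))
  for (i in seq_along(tooth)) {
    t <- tooth[i]
    if (t <= 8)       fdi[i] <- paste0("1", 9 - t)
    else if (t <= 16) fdi[i] <- paste0("2", t - 8)
    else if (t <= 24) fdi[i] <- paste0("3", 25 - t)
    else              fdi[i] <- paste0("4", t - 24)
  }
  fdi
}
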