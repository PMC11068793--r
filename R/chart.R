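#' @title Periodontal chart domain model
#' @description Constructors and validators for site measurements, tooth
#'   records, patient profiles and full-mouth charts. Probing depths and
#'   recession are integer millimetres (probes read in 1 mm increments);
#'   recession is signed, positive when the gingival margin lies apical to
#'   the cemento-enamel junction.
#' @name chart-model
NULL

#' Create a single site measurement
#'
#' @param site site label, one of MB, B, DB, ML, L, DL.
#' @param pd probing depth in mm (integer 0-20), or NA for an unmeasured site.
#' @param rec signed recession in mm (integer -5..15; negative = margin
#'   coronal to the CEJ), or NA.
#' @param bop bleeding on probing (logical).
#' @param sup suppuration (logical).
#' @return an object of class `site_measurement`.
#' @examples
#' s <- site_measurement("MB", pd = 5, rec = 2)
#' compute_cal(s)  # 7
#' @export
site_measurement <- function(site, pd, rec = 0L, bop = FALSE, sup = FALSE) {
  if (!is.character(site) || length(site) != 1L || !(site %in% SITE_IDS)) {
    stop("invalid site id '", site, "': must be one of ",
         paste(SITE_IDS, collapse = ", "), call. = FALSE)
  }
  pd <- .as_int_or_na(pd, "probing depth")
  rec <- .as_int_or_na(rec, "recession")
  if (!is.na(pd) && (pd < 0L || pd > 20L)) {
    stop("probing depth ", pd, " mm out of range [0, 20] at site ", site,
         call. = FALSE)
  }
  if (!is.na(rec) && (rec < -5L || rec > 15L)) {
    stop("recession ", rec, " mm out of range [-5, 15] at site ", site,
         call. = FALSE)
  }
  structure(
    list(site = site, pd = pd, rec = rec,
         bop = isTRUE(bop), sup = isTRUE(sup)),
    class = "site_measurement"
  )
}

.as_int_or_na <- function(x, what) {
  if (length(x) != 1L) stop(what, " must be a single value", call. = FALSE)
  if (is.na(x)) return(NA_integer_)
  if (!is.numeric(x) || x != round(x)) {
    stop(what, " must be an integer millimetre value, got ", x, call. = FALSE)
  }
  as.integer(x)
}

#' Clinical attachment loss at a site
#'
#' CAL = probing depth + signed recession: the distance from the CEJ to the
#' pocket base. A margin coronal to the CEJ (negative recession) subtracts,
#' so a shallow sulcus with coronal margin has CAL <= 0.
#'
#' @param site a `site_measurement`.
#' @return CAL in mm (integer), or NA for an unmeasured site.
#' @export
compute_cal <- function(site) {
  stopifnot(inherits(site, "site_measurement"))
  if (is.na(site$pd) || is.na(site$rec)) return(NA_integer_)
  site$pd + site$rec
}

#' Create a tooth (or implant) record
#'
#' @param tooth_number Universal number 1-32.
#' @param present is the position occupied (by a natural tooth or implant)?
#' @param is_implant TRUE for an implant-supported restoration at this
#'   position; implants carry 4-6 measured sites and never contribute to
#'   tooth-level staging.
#' @param sites list of [site_measurement()] objects: exactly 6 with distinct
#'   labels for a present natural tooth, 4-6 for an implant, none for a
#'   missing position.
#' @param bone_loss_percent radiographic bone loss, % of root length (0-100),
#'   NA when no readable radiograph exists.
#' @param furcation_class 0-3; > 0 only on multirooted teeth (molars and
#'   maxillary first premolars).
#' @param mobility_class 0-3.
#' @param flags character vector of finding flags (defective_restoration,
#'   subgingival_margin, enamel_projection, root_proximity,
#'   endodontic_involvement, abscess, fremitus, widened_pdl,
#'   progressive_bone_loss, vertical_defect, keratinized_tissue_deficiency).
#' @return an object of class `tooth_record`.
#' @export
tooth_record <- function(tooth_number, present = TRUE, is_implant = FALSE,
                         sites = list(), bone_loss_percent = NA,
                         furcation_class = 0L, mobility_class = 0L,
                         flags = character()) {
  if (!is.numeric(tooth_number) || length(tooth_number) != 1L ||
      !(tooth_number %in% 1:32)) {
    stop("tooth_number must be a Universal number 1-32, got ",
         paste(tooth_number, collapse = ","), call. = FALSE)
  }
  tooth_number <- as.integer(tooth_number)
  present <- isTRUE(present)
  is_implant <- isTRUE(is_implant)
  if (!present && length(sites) > 0L) {
    stop("missing tooth ", tooth_number, " must not carry site measurements",
         call. = FALSE)
  }
  for (s in sites) {
    if (!inherits(s, "site_measurement")) {
      stop("tooth ", tooth_number, ": sites must be site_measurement objects",
           call. = FALSE)
    }
  }
  labels <- vapply(sites, `[[`, character(1), "site")
  if (anyDuplicated(labels)) {
    stop("tooth ", tooth_number, ": duplicate site labels ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  if (present && !is_implant && length(sites) != 6L) {
    stop("tooth ", tooth_number, ": a present natural tooth requires ",
         "exactly 6 sites, got ", length(sites), call. = FALSE)
  }
  if (present && is_implant && (length(sites) < 4L || length(sites) > 6L)) {
    stop("implant at position ", tooth_number, ": requires 4-6 sites, got ",
         length(sites), call. = FALSE)
  }
  if (!is.na(bone_loss_percent) &&
      (!is.numeric(bone_loss_percent) || bone_loss_percent < 0 ||
       bone_loss_percent > 100)) {
    stop("tooth ", tooth_number, ": bone_loss_percent out of [0, 100]",
         call. = FALSE)
  }
  furcation_class <- as.integer(furcation_class)
  mobility_class <- as.integer(mobility_class)
  stopifnot(furcation_class %in% 0:3, mobility_class %in% 0:3)
  if (furcation_class > 0L && !is_implant &&
      !(tooth_number %in% MULTIROOTED_TEETH)) {
    stop("tooth ", tooth_number, ": furcation class > 0 on a single-rooted ",
         "tooth", call. = FALSE)
  }
  flags <- as.character(flags)
  bad <- setdiff(flags, TOOTH_FLAGS)
  if (length(bad)) {
    stop("tooth ", tooth_number, ": unknown flag(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(tooth_number = tooth_number, present = present,
         is_implant = is_implant, sites = sites,
         bone_loss_percent = if (is.na(bone_loss_percent)) NA_real_ else
           as.numeric(bone_loss_percent),
         furcation_class = furcation_class, mobility_class = mobility_class,
         flags = sort(unique(flags))),
    class = "tooth_record"
  )
}

#' Create a patient profile
#'
#' Carries the grading risk modifiers (smoking, diabetes/HbA1c) and the
#' stage IV discriminators (teeth lost to periodontitis, masticatory
#' dysfunction) alongside basic demographics.
#'
#' @param age_years positive integer.
#' @param smoking_cigarettes_per_day non-negative integer.
#' @param has_diabetes logical.
#' @param hba1c_percent optional; only meaningful when `has_diabetes`.
#' @param systemic_disease_codes character vector of condition codes.
#' @param teeth_lost_to_periodontitis non-negative integer; validated against
#'   the chart's missing-teeth count at chart construction.
#' @param history_of_periodontal_treatment logical.
#' @param masticatory_dysfunction logical.
#' @return an object of class `patient_profile`.
#' @export
patient_profile <- function(age_years,
                            smoking_cigarettes_per_day = 0L,
                            has_diabetes = FALSE,
                            hba1c_percent = NA,
                            systemic_disease_codes = character(),
                            teeth_lost_to_periodontitis = 0L,
                            history_of_periodontal_treatment = FALSE,
                            masticatory_dysfunction = FALSE) {
  stopifnot(is.numeric(age_years), length(age_years) == 1L, age_years > 0)
  stopifnot(is.numeric(smoking_cigarettes_per_day),
            smoking_cigarettes_per_day >= 0)
  if (!is.na(hba1c_percent)) {
    stopifnot(is.numeric(hba1c_percent), hba1c_percent >= 0)
    if (!isTRUE(has_diabetes)) {
      stop("hba1c_percent supplied without a recorded diabetes context",
           call. = FALSE)
    }
  }
  stopifnot(is.numeric(teeth_lost_to_periodontitis),
            teeth_lost_to_periodontitis >= 0)
  structure(
    list(age_years = as.integer(age_years),
         smoking_cigarettes_per_day = as.integer(smoking_cigarettes_per_day),
         has_diabetes = isTRUE(has_diabetes),
         hba1c_percent = if (is.na(hba1c_percent)) NA_real_ else
           as.numeric(hba1c_percent),
         systemic_disease_codes = sort(unique(as.character(
           systemic_disease_codes))),
         teeth_lost_to_periodontitis = as.integer(teeth_lost_to_periodontitis),
         history_of_periodontal_treatment =
           isTRUE(history_of_periodontal_treatment),
         masticatory_dysfunction = isTRUE(masticatory_dysfunction)),
    class = "patient_profile"
  )
}

#' Create a full-mouth periodontal chart
#'
#' @param chart_id character identifier.
#' @param profile a [patient_profile()].
#' @param teeth list of [tooth_record()] objects, one per Universal number
#'   1-32 (any order; stored sorted by tooth number).
#' @param exam_date ISO-8601 date string or Date.
#' @return an object of class `periodontal_chart`.
#' @export
periodontal_chart <- function(chart_id, profile, teeth,
                              exam_date = Sys.Date()) {
  stopifnot(is.character(chart_id), length(chart_id) == 1L, nzchar(chart_id))
  stopifnot(inherits(profile, "patient_profile"))
  nums <- vapply(teeth, function(t) {
    if (!inherits(t, "tooth_record")) {
      stop("chart ", chart_id, ": teeth must be tooth_record objects",
           call. = FALSE)
    }
    t$tooth_number
  }, integer(1))
  if (anyDuplicated(nums)) {
    stop("chart ", chart_id, ": duplicate tooth number(s) ",
         paste(unique(nums[duplicated(nums)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(nums, 1:32)) {
    stop("chart ", chart_id, ": expected exactly one record per tooth 1-32; ",
         "missing ", paste(setdiff(1:32, nums), collapse = ", "),
         call. = FALSE)
  }
  teeth <- teeth[order(nums)]
  names(teeth) <- as.character(1:32)
  n_occupied <- sum(vapply(teeth, `[[`, logical(1), "present"))
  if (n_occupied == 0L) {
    stop("chart ", chart_id, ": no present teeth or implants; ",
         "not diagnosable", call. = FALSE)
  }
  n_natural <- sum(vapply(
    teeth, function(t) t$present && !t$is_implant, logical(1)))
  n_missing_natural <- 32L - n_natural
  if (profile$teeth_lost_to_periodontitis > n_missing_natural) {
    stop("chart ", chart_id, ": teeth_lost_to_periodontitis (",
         profile$teeth_lost_to_periodontitis, ") exceeds missing natural ",
         "teeth (", n_missing_natural, ")", call. = FALSE)
  }
  structure(
    list(chart_id = chart_id, profile = profile, teeth = teeth,
         exam_date = format(as.Date(exam_date), "%Y-%m-%d")),
    class = "periodontal_chart"
  )
}

#' @export
print.periodontal_chart <- function(x, ...) {
  nat <- sum(vapply(x$teeth, function(t) t$present && !t$is_implant,
                    logical(1)))
  imp <- sum(vapply(x$teeth, function(t) t$present && t$is_implant,
                    logical(1)))
  cat("<periodontal_chart> ", x$chart_id, " (", x$exam_date, "): ",
      nat, " natural teeth, ", imp, " implants, patient age ",
      x$profile$age_years, "\n", sep = "")
  invisible(x)
}

# helpers used across modules -------------------------------------------------

.present_natural <- function(chart) {
  Filter(function(t) t$present && !t$is_implant, chart$teeth)
}

.present_implants <- function(chart) {
  Filter(function(t) t$present && t$is_implant, chart$teeth)
}
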