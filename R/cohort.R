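#' @title Synthetic cohort generation
#' @description Seeded generators that build labeled charts by rule
#'   inversion: measurements are constructed to satisfy exactly the target
#'   diagnosis under [diagnose()], with randomness confined to fields that
#'   do not determine the label (which teeth are affected, cosmetic
#'   variation, bleeding pattern). Rule inversion rather than rejection
#'   sampling guarantees coverage of rare labels such as the molar-incisor
#'   pattern.
#' @name synth-cohort
NULL

.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Default primary-diagnosis sampling weights
#'
#' The 18 periodontitis label frequencies of the chairside study cohort
#' (totals column), renormalized to sum to one. Four labels carry weight
#' zero (they did not occur) but remain reachable by
#' [chart_for_diagnosis()].
#'
#' @return named numeric vector summing to 1.
#' @export
default_diagnosis_weights <- function() {
  counts <- c(
    "localized periodontitis stage II grade A"   = 1,
    "localized periodontitis stage II grade B"   = 5,
    "localized periodontitis stage II grade C"   = 1,
    "generalized periodontitis stage II grade A" = 1,
    "generalized periodontitis stage II grade B" = 10,
    "generalized periodontitis stage II grade C" = 0,
    "localized periodontitis stage III grade A"  = 2,
    "localized periodontitis stage III grade B"  = 25,
    "localized periodontitis stage III grade C"  = 15,
    "generalized periodontitis stage III grade A" = 0,
    "generalized periodontitis stage III grade B" = 15,
    "generalized periodontitis stage III grade C" = 6,
    "generalized periodontitis stage IV grade A" = 1,
    "generalized periodontitis stage IV grade B" = 25,
    "generalized periodontitis stage IV grade C" = 43,
    "molar-incisor pattern periodontitis stage III grade A" = 0,
    "molar-incisor pattern periodontitis stage III grade B" = 0,
    "molar-incisor pattern periodontitis stage III grade C" = 1
  )
  counts / sum(counts)
}

#' Default secondary-condition injection rates
#'
#' Per-patient probabilities of each secondary condition, matching the
#' chairside study's condition frequencies over 150 patients (129/150
#' tooth/prosthesis factors, 118/150 occlusal trauma, 52/150 mucogingival,
#' 49/150 systemic manifestation, 18/150 endo-periodontal, 13/150 abscess).
#'
#' @return named numeric vector of rates in [0, 1].
#' @export
default_secondary_rates <- function() {
  c(tooth_prosthesis_related_factors     = 129 / 150,
    occlusal_trauma                      = 118 / 150,
    mucogingival_deformity               = 52 / 150,
    periodontitis_systemic_manifestation = 49 / 150,
    endo_periodontal_lesion              = 18 / 150,
    periodontal_abscess                  = 13 / 150)
}

#' Cohort generation configuration
#'
#' @param n_patients number of charts to generate.
#' @param diagnosis_weights named probability vector over primary labels
#'   (must sum to 1 within 1e-9).
#' @param secondary_rates named per-category injection probabilities.
#' @param seed integer RNG seed.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          diagnosis_weights = default_diagnosis_weights(),
                          secondary_rates = default_secondary_rates(),
                          seed = 1L) {
  stopifnot(is.numeric(n_patients), n_patients >= 0)
  if (abs(sum(diagnosis_weights) - 1) > 1e-9) {
    stop("diagnosis_weights must sum to 1", call. = FALSE)
  }
  if (any(secondary_rates < 0 | secondary_rates > 1)) {
    stop("secondary_rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 diagnosis_weights = diagnosis_weights,
                 secondary_rates = secondary_rates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

PERIO_LABEL_RE <- paste0(
  "^(localized|generalized|molar-incisor pattern) periodontitis ",
  "stage (I|II|III|IV) grade (A|B|C)$")

#' All reachable primary labels
#' @return character vector: the 18 study periodontitis labels plus the
#'   gingival and peri-implant categories.
#' @export
reachable_labels <- function() {
  c(names(default_diagnosis_weights()),
    "clinical_gingival_health_intact", "clinical_gingival_health_reduced",
    "gingivitis", "peri_implant_health", "peri_implant_mucositis",
    "peri_implantitis")
}

.healthy_sites <- function(bleed_sites = character()) {
  lapply(SITE_IDS, function(id) {
    site_measurement(id, pd = 2L, rec = -2L, bop = id %in% bleed_sites)
  })
}

#' Construct a chart that diagnoses to a given label
#'
#' Inverts the classification rules: severity sites, bone loss/age, tooth
#' counts and flags are chosen so that [diagnose()] returns exactly
#' `label`. Randomness (which teeth are affected, bleeding pattern, small
#' age jitter) never touches a label-determining threshold. The same label
#' and seed always produce an identical chart.
#'
#' @param label a label from [reachable_labels()].
#' @param seed integer seed.
#' @param config a [clinical_config()].
#' @return a [periodontal_chart()].
#' @export
chart_for_diagnosis <- function(label, seed = 1L,
                                config = clinical_config()) {
  if (grepl(PERIO_LABEL_RE, label)) {
    m <- regmatches(label, regexec(PERIO_LABEL_RE, label))[[1]]
    extent <- switch(m[2], localized = "localized",
                     generalized = "generalized",
                     "molar-incisor pattern" = "molar_incisor_pattern")
    return(.with_seed(seed, function() {
      .perio_chart(extent, m[3], m[4], label, seed, config)
    }))
  }
  if (label %in% c("clinical_gingival_health_intact",
                   "clinical_gingival_health_reduced", "gingivitis")) {
    return(.with_seed(seed, function() .gingival_chart(label, seed)))
  }
  if (label %in% c("peri_implant_health", "peri_implant_mucositis",
                   "peri_implantitis")) {
    return(.with_seed(seed, function() .implant_chart(label, seed)))
  }
  stop("unreachable or unknown diagnosis label: '", label, "'",
       call. = FALSE)
}

.PREMOLAR_ANCHORS <- c(5, 12, 21, 28)
.STAGE4_REMOVAL_POOL <- c(4, 6, 11, 13, 20, 22, 27, 29)

.perio_chart <- function(extent, stage, grade, label, seed, config) {
  present <- setdiff(1:32, c(1, 16, 17, 32))  # third molars unscored
  teeth_lost <- 0L
  if (stage == "IV") {
    # >= 5 teeth lost to periodontitis; removal pool avoids the molars,
    # incisors and the premolar anchors used below
    present <- setdiff(present, sample(.STAGE4_REMOVAL_POOL, 5L))
    teeth_lost <- 5L
  }
  n <- length(present)

  if (extent == "molar_incisor_pattern") {
    molars <- intersect(FIRST_SECOND_MOLARS, present)
    incis <- intersect(INCISORS, present)
    affected <- c(sample(molars, sample(1:3, 1)),
                  sample(incis, sample(1:3, 1)))
  } else if (extent == "localized") {
    kmax <- ceiling(config$extent$generalized_fraction * n) - 1L
    k <- sample(3:min(kmax, 6L), 1)
    anchor <- sample(intersect(.PREMOLAR_ANCHORS, present), 1)
    affected <- c(anchor, sample(setdiff(present, anchor), k - 1L))
  } else {
    kmin <- ceiling(config$extent$generalized_fraction * n)
    k <- sample(kmin:min(n, kmin + 6L), 1)
    anchor <- sample(intersect(.PREMOLAR_ANCHORS, present), 1)
    affected <- c(anchor, sample(setdiff(present, anchor), k - 1L))
  }
  affected <- sort(unique(affected))

  # severity site targets per stage band; stages I/II must avoid every
  # complexity trigger (PD >= 6, furcation >= II, vertical defects)
  tgt <- switch(stage,
                I = list(pd = 4L, rec = -2L),   # CAL 2
                II = list(pd = 5L, rec = -1L),  # CAL 4
                list(pd = 6L, rec = 0L))        # CAL 6; PD 6 also complexity
  demo <- switch(grade,
                 A = list(age = 60L, bone = 10),
                 B = list(age = 50L, bone = 30),
                 C = list(age = 40L, bone = 55))
  age <- demo$age + sample(-2:2, 1)

  teeth <- lapply(1:32, function(tn) {
    if (!(tn %in% present)) return(tooth_record(tn, present = FALSE))
    if (tn %in% affected) {
      sites <- lapply(SITE_IDS, function(id) {
        if (id == "MB") {
          site_measurement(id, pd = tgt$pd, rec = tgt$rec, bop = TRUE)
        } else if (id == "DB") {
          site_measurement(id, pd = 3L, rec = -2L, bop = TRUE)  # CAL 1
        } else {
          site_measurement(id, pd = 2L, rec = -2L)
        }
      })
      tooth_record(tn, sites = sites, bone_loss_percent = demo$bone)
    } else {
      tooth_record(tn, sites = .healthy_sites(), bone_loss_percent = 0)
    }
  })
  profile <- patient_profile(age_years = age,
                             teeth_lost_to_periodontitis = teeth_lost)
  periodontal_chart(paste0("synth-", seed), profile, teeth,
                    exam_date = "2023-03-01")
}

.gingival_chart <- function(label, seed) {
  present <- setdiff(1:32, c(1, 16, 17, 32))
  n_sites <- length(present) * 6L
  frac <- switch(label,
                 gingivitis = stats::runif(1, 0.15, 0.45),
                 stats::runif(1, 0, 0.05))
  n_bleed <- round(frac * n_sites)
  bleed_idx <- sample(n_sites, n_bleed)
  history <- label == "clinical_gingival_health_reduced"
  teeth <- lapply(1:32, function(tn) {
    if (!(tn %in% present)) return(tooth_record(tn, present = FALSE))
    pos <- (match(tn, present) - 1L) * 6L
    bleed_here <- SITE_IDS[which((pos + 1:6) %in% bleed_idx)]
    sites <- .healthy_sites(bleed_here)
    if (history && tn == 8L) {
      # single-tooth recession-only attachment loss: one qualifying tooth
      # can never satisfy the two-tooth case definition
      sites[[1]] <- site_measurement("MB", pd = 2L, rec = 1L,
                                     bop = "MB" %in% bleed_here)
    }
    tooth_record(tn, sites = sites, bone_loss_percent = 0)
  })
  profile <- patient_profile(age_years = sample(25:45, 1),
                             history_of_periodontal_treatment = history)
  periodontal_chart(paste0("synth-", seed), profile, teeth,
                    exam_date = "2023-03-01")
}

.implant_chart <- function(label, seed) {
  implant_at <- c(8L, 9L, 24L, 25L)
  target <- sample(implant_at, 1)
  teeth <- lapply(1:32, function(tn) {
    if (!(tn %in% implant_at)) return(tooth_record(tn, present = FALSE))
    inflamed <- tn == target && label != "peri_implant_health"
    sites <- lapply(SITE_IDS, function(id) {
      site_measurement(id, pd = 3L, rec = -3L,
                       bop = inflamed && id %in% c("MB", "DB"))
    })
    tooth_record(tn, is_implant = TRUE, sites = sites,
                 bone_loss_percent = NA,
                 flags = if (tn == target && label == "peri_implantitis") {
                   "progressive_bone_loss"
                 } else character())
  })
  profile <- patient_profile(age_years = sample(55:75, 1))
  periodontal_chart(paste0("synth-", seed), profile, teeth,
                    exam_date = "2023-03-01")
}

# secondary-condition injection -------------------------------------------------

.inject_secondary <- function(chart, category, config) {
  natural <- .present_natural(chart)
  pick_tooth <- function(candidates) {
    if (length(candidates) == 0L) return(NA_integer_)
    if (length(candidates) == 1L) candidates else sample(candidates, 1)
  }
  nat_nums <- vapply(natural, `[[`, integer(1), "tooth_number")
  switch(
    category,
    tooth_prosthesis_related_factors = {
      tn <- pick_tooth(nat_nums)
      if (is.na(tn)) return(NULL)
      chart$teeth[[as.character(tn)]]$flags <- sort(unique(c(
        chart$teeth[[as.character(tn)]]$flags, "defective_restoration")))
      chart
    },
    occlusal_trauma = {
      tn <- pick_tooth(nat_nums)
      if (is.na(tn)) return(NULL)
      chart$teeth[[as.character(tn)]]$mobility_class <- max(
        chart$teeth[[as.character(tn)]]$mobility_class,
        config$secondary$trauma_mobility_min)
      chart
    },
    mucogingival_deformity = {
      tn <- pick_tooth(nat_nums)
      if (is.na(tn)) return(NULL)
      chart$teeth[[as.character(tn)]]$flags <- sort(unique(c(
        chart$teeth[[as.character(tn)]]$flags,
        "keratinized_tissue_deficiency")))
      chart
    },
    periodontitis_systemic_manifestation = {
      code <- sample(config$secondary$systemic_manifestation_codes, 1)
      chart$profile$systemic_disease_codes <- sort(unique(c(
        chart$profile$systemic_disease_codes, code)))
      chart
    },
    endo_periodontal_lesion = {
      # needs a tooth that already probes >= the endo-lesion PD threshold,
      # so the injection never perturbs staging
      deep <- nat_nums[vapply(natural, function(t) {
        any(vapply(t$sites, function(s) {
          !is.na(s$pd) && s$pd >= config$secondary$endo_lesion_pd_min_mm
        }, logical(1)))
      }, logical(1))]
      tn <- pick_tooth(deep)
      if (is.na(tn)) return(NULL)
      chart$teeth[[as.character(tn)]]$flags <- sort(unique(c(
        chart$teeth[[as.character(tn)]]$flags, "endodontic_involvement")))
      chart
    },
    periodontal_abscess = {
      tn <- pick_tooth(nat_nums)
      if (is.na(tn)) return(NULL)
      chart$teeth[[as.character(tn)]]$flags <- sort(unique(c(
        chart$teeth[[as.character(tn)]]$flags, "abscess")))
      chart
    },
    stop("unknown secondary category: ", category, call. = FALSE)
  )
}

#' Sample a labeled synthetic cohort
#'
#' Primary labels are drawn i.i.d. from the configured weights; each chart
#' is built by [chart_for_diagnosis()]; secondary conditions are injected
#' per category with the configured rates. After injection the chart is
#' re-diagnosed and any injection that would alter the intended primary
#' label is rolled back (e.g. an endodontic-periodontal lesion cannot be
#' placed on a chart without a deep pocket). Fully reproducible under the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @param clinical a [clinical_config()].
#' @return object of class `perio_cohort`: list with `charts`, `labels`
#'   (intended primary labels), `secondary` (list of intended category
#'   sets) and `config`.
#' @export
sample_cohort <- function(config, clinical = clinical_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  rates <- config$secondary_rates
  plan <- .with_seed(config$seed, function() {
    labels <- if (n > 0) {
      sample(names(config$diagnosis_weights), n, replace = TRUE,
             prob = config$diagnosis_weights)
    } else character()
    child_seeds <- if (n > 0) sample.int(2147483646L, n) else integer()
    sec <- lapply(seq_len(n), function(i) {
      names(rates)[stats::runif(length(rates)) < rates]
    })
    list(labels = labels, child_seeds = child_seeds, sec = sec)
  })
  charts <- vector("list", n)
  secondary <- vector("list", n)
  for (i in seq_len(n)) {
    chart <- chart_for_diagnosis(plan$labels[i], plan$child_seeds[i],
                                 clinical)
    kept <- character()
    injected <- .with_seed(plan$child_seeds[i] %% 2000000000L + 7L,
                           function() {
      out <- chart
      for (cat in plan$sec[[i]]) {
        cand <- .inject_secondary(out, cat, clinical)
        if (!is.null(cand)) {
          out <- cand
          kept <<- c(kept, cat)
        }
      }
      out
    })
    injected$chart_id <- sprintf("%s-%04d", "cohort", i)
    if (length(kept) &&
        diagnosis_label(diagnose(injected, clinical)$primary) !=
          plan$labels[i]) {
      # rollback all injections rather than ship a mislabeled chart
      chart$chart_id <- sprintf("%s-%04d", "cohort", i)
      injected <- chart
      kept <- character()
    }
    charts[[i]] <- injected
    secondary[[i]] <- sort(kept)
  }
  structure(list(charts = charts, labels = plan$labels,
                 secondary = secondary, config = config),
            class = "perio_cohort")
}

#' Write a cohort to a directory
#'
#' One chart JSON per patient plus a `labels.csv` with the intended primary
#' label and intended secondary categories.
#'
#' @param cohort a `perio_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "perio_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$charts))
  for (i in seq_along(cohort$charts)) {
    files[i] <- paste0(cohort$charts[[i]]$chart_id, ".json")
    write_chart(cohort$charts[[i]], file.path(dir, files[i]))
  }
  utils::write.csv(
    data.frame(chart_file = files, label = cohort$labels,
               secondary = vapply(cohort$secondary, paste,
                                  character(1), collapse = ";")),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
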