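test_that("case definition: interdental rule needs two non-adjacent teeth", {
  cfg <- clinical_config()
  # interdental CAL 2 mm at #3 and #19 -> case via the interdental rule
  ev <- is_periodontitis_case(perio_fixture(c(3, 19), cal = 2), cfg)
  expect_true(ev$is_case)
  expect_equal(ev$rule_used, "interdental_rule")

  # CAL 6 mm confined to adjacent #8 and #9 -> not a case
  ev2 <- is_periodontitis_case(perio_fixture(c(8, 9), cal = 6), cfg)
  expect_false(ev2$is_case)
  expect_equal(ev2$rule_used, "none")

  # buccal CAL 3 mm at #6 and #11 with no interproximal CAL -> case via
  # the buccal/lingual rule
  ch <- make_chart(sites = list(
    list(tooth = 6, site = "B", pd = 5, rec = -2),
    list(tooth = 11, site = "B", pd = 5, rec = -2)))
  ev3 <- is_periodontitis_case(ch, cfg)
  expect_true(ev3$is_case)
  expect_equal(ev3$rule_used, "buccal_lingual_rule")
})

test_that("stage follows severity CAL with exact boundaries", {
  for (case in list(list(cal = 2, stage = "I"), list(cal = 3, stage = "II"),
                    list(cal = 4, stage = "II"), list(cal = 5, stage = "III"),
                    list(cal = 6, stage = "III"))) {
    rep <- diagnose(perio_fixture(c(3, 19, 28), cal = case$cal))
    expect_equal(rep$primary$stage, case$stage,
                 label = paste("stage at CAL", case$cal))
  }
})

test_that("complexity factors shift the stage up to at least III", {
  # CAL 4 alone is stage II ...
  base <- perio_fixture(c(3, 19, 28), cal = 4)
  expect_equal(diagnose(base)$primary$stage, "II")
  # ... but PD 6 mm anywhere forces stage III
  deep <- make_chart(sites = c(lapply(c(3, 19, 28), cal_site, cal = 4),
                               list(list(tooth = 30, site = "B", pd = 6,
                                         rec = -5))),
                     bone = list(`3` = 30, `19` = 30, `28` = 30))
  expect_equal(diagnose(deep)$primary$stage, "III")
  # ... as does furcation class II
  furc <- make_chart(sites = lapply(c(3, 19, 28), cal_site, cal = 4),
                     bone = list(`3` = 30), furcation = list(`19` = 2))
  expect_equal(diagnose(furc)$primary$stage, "III")
  # ... and a vertical defect flag
  vert <- make_chart(sites = lapply(c(3, 19, 28), cal_site, cal = 4),
                     bone = list(`3` = 30),
                     flags = list(`19` = "vertical_defect"))
  expect_equal(diagnose(vert)$primary$stage, "III")
})

test_that("stage IV discriminators: tooth loss, short dentition, dysfunction", {
  # CAL 6 with an intact dentition and no discriminator stays III
  expect_equal(diagnose(perio_fixture(c(3, 19, 28), cal = 6))$primary$stage,
               "III")
  # >= 5 teeth lost to periodontitis forces IV
  short <- perio_fixture(c(5, 19, 28), cal = 6,
                         present = setdiff(DEFAULT_PRESENT,
                                           c(2, 4, 13, 20, 29)),
                         teeth_lost_to_periodontitis = 5)
  expect_equal(diagnose(short)$primary$stage, "IV")
  # < 20 remaining teeth forces IV
  few <- perio_fixture(c(5, 19, 28), cal = 6,
                       present = setdiff(DEFAULT_PRESENT,
                                         c(2, 4, 6, 11, 13, 14, 20, 22,
                                           27, 29)))
  expect_equal(diagnose(few)$primary$stage, "IV")
  # masticatory dysfunction forces IV
  dys <- perio_fixture(c(3, 19, 28), cal = 6,
                       masticatory_dysfunction = TRUE)
  expect_equal(diagnose(dys)$primary$stage, "IV")
})

test_that("grade bands are closed at 0.25 and 1.0 and modifiers only upgrade", {
  g <- function(bone, age, ...) {
    diagnose(perio_fixture(c(3, 19, 28), cal = 6, bone = bone, age = age,
                           ...))$primary$grade
  }
  expect_equal(g(bone = 10, age = 50), "A")   # r = 0.2
  expect_equal(g(bone = 12.5, age = 50), "B") # r = 0.25 boundary -> B
  expect_equal(g(bone = 50, age = 50), "B")   # r = 1.0 boundary -> B
  expect_equal(g(bone = 35, age = 25), "C")   # r = 1.4
  # upgrade-only modifiers
  expect_equal(g(bone = 10, age = 50, smoking_cigarettes_per_day = 15), "C")
  expect_equal(g(bone = 10, age = 50, smoking_cigarettes_per_day = 5), "B")
  expect_equal(g(bone = 10, age = 50, has_diabetes = TRUE), "B")
  expect_equal(g(bone = 10, age = 50, has_diabetes = TRUE,
                 hba1c_percent = 7.5), "C")
  # heavy smoking never downgrades an already-C chart
  expect_equal(g(bone = 60, age = 40, smoking_cigarettes_per_day = 15), "C")
})

test_that("grading without any radiographic evidence is an error", {
  teeth <- lapply(1:32, function(tn) {
    if (tn %in% c(3, 19, 28)) {
      ov <- cal_site(tn, 6)
      s <- healthy_sites()
      s[[1]] <- site_measurement("MB", pd = ov$pd, rec = ov$rec, bop = TRUE)
      tooth_record(tn, sites = s, bone_loss_percent = NA)
    } else if (tn %in% DEFAULT_PRESENT) {
      tooth_record(tn, sites = healthy_sites(), bone_loss_percent = NA)
    } else tooth_record(tn, present = FALSE)
  })
  ch <- periodontal_chart("no-xray", patient_profile(50), teeth)
  expect_error(diagnose(ch), "grading evidence missing")
})

test_that("extent: 30% cut-off and molar-incisor pattern precedence", {
  # 4 affected of 28 scorable (14%) -> localized
  expect_equal(diagnose(perio_fixture(c(3, 12, 19, 28),
                                      cal = 6))$primary$extent, "localized")
  # 12 of 28 (43%) -> generalized
  gen <- perio_fixture(c(2, 4, 6, 8, 12, 15, 19, 21, 24, 27, 29, 31),
                       cal = 6)
  expect_equal(diagnose(gen)$primary$extent, "generalized")
  # molars + incisors only, both represented -> molar-incisor pattern
  mip <- perio_fixture(c(3, 14, 19, 30, 8, 9, 25), cal = 6)
  expect_equal(diagnose(mip)$primary$extent, "molar_incisor_pattern")
  expect_equal(diagnose(mip)$label,
               "molar-incisor pattern periodontitis stage III grade B")
  # molars only (no incisor) is not the pattern
  mol <- perio_fixture(c(3, 14, 19, 30), cal = 6)
  expect_equal(diagnose(mol)$primary$extent, "localized")
})

test_that("gingival status splits on BOP 10% and periodontium integrity", {
  # BOP below 10%, no attachment loss -> gingival health, intact
  healthy <- make_chart(bop_sites = list(`3` = "MB", `19` = "B"))
  expect_equal(diagnose(healthy)$primary$category,
               "clinical_gingival_health_intact")
  # same bleeding with recession-only CAL on one tooth -> reduced
  reduced <- make_chart(bop_sites = list(`3` = "MB"),
                        sites = list(list(tooth = 8, site = "MB", pd = 2,
                                          rec = 1)))
  expect_equal(diagnose(reduced)$primary$category,
               "clinical_gingival_health_reduced")
  # BOP ~40% -> gingivitis with the generalized annotation
  bleed <- stats::setNames(
    lapply(DEFAULT_PRESENT, function(i) c("MB", "B", "DB")),
    as.character(DEFAULT_PRESENT))
  ging <- make_chart(bop_sites = bleed[1:22])
  rep <- diagnose(ging)
  expect_equal(rep$primary$category, "gingivitis")
  expect_true("gingival.gingivitis_generalized_gt_30pct" %in%
                rep$primary$rationale)
})

test_that("implants classify independently and drive implant-only charts", {
  ch <- make_chart(implants = c(19, 30),
                   bop_sites = list(`19` = c("MB", "B")),
                   flags = list(`30` = "progressive_bone_loss"))
  imp <- classify_implants(ch)
  expect_equal(imp[["19"]]$category, "peri_implant_mucositis")
  expect_equal(imp[["30"]]$category, "peri_implantitis")
  expect_length(classify_implants(make_chart()), 0)

  # implant-only dentition: the worst implant becomes the primary
  only <- make_chart(present = integer(), implants = c(8, 25),
                     bop_sites = list(`8` = "MB"))
  expect_equal(diagnose(only)$primary$category, "peri_implant_mucositis")
})

test_that("stage and grade are monotone in measurements (never downgrade)", {
  set.seed(402)
  for (i in 1:25) {
    lab <- sample(names(default_diagnosis_weights()), 1)
    ch <- chart_for_diagnosis(lab, seed = i)
    rep0 <- diagnose(ch)
    # deepen one measured site by 1-3 mm
    tn <- sample(rep0$primary$rationale, 1)  # just for rng mixing
    cand <- Filter(function(t) t$present && !t$is_implant, ch$teeth)
    t <- cand[[sample(length(cand), 1)]]
    k <- sample(seq_along(t$sites), 1)
    s <- t$sites[[k]]
    bump <- sample(1:3, 1)
    ch$teeth[[as.character(t$tooth_number)]]$sites[[k]] <-
      site_measurement(s$site, pd = min(s$pd + bump, 20), rec = s$rec,
                       bop = s$bop)
    rep1 <- diagnose(ch)
    if (rep1$primary$category == "periodontitis") {
      expect_gte(stage_rank(rep1$primary$stage),
                 stage_rank(rep0$primary$stage))
    }
    # raise bone loss on the worst tooth: grade never decreases
    ch2 <- chart_for_diagnosis(lab, seed = i)
    worst <- which.max(vapply(ch2$teeth, function(t) {
      if (isTRUE(t$present) && !t$is_implant &&
          !is.na(t$bone_loss_percent)) t$bone_loss_percent else -1
    }, numeric(1)))
    key <- names(ch2$teeth)[worst]
    ch2$teeth[[key]]$bone_loss_percent <- min(
      ch2$teeth[[key]]$bone_loss_percent + 25, 100)
    rep2 <- diagnose(ch2)
    expect_gte(match(rep2$primary$grade, c("A", "B", "C")),
               match(rep0$primary$grade, c("A", "B", "C")))
  }
})

test_that("every valid chart maps to exactly one primary category", {
  set.seed(403)
  for (i in 1:60) {
    rep <- diagnose(random_chart())
    expect_true(rep$primary$category %in% c(
      "clinical_gingival_health_intact", "clinical_gingival_health_reduced",
      "gingivitis", "periodontitis"))
    expect_gte(length(rep$primary$rationale), 1)
    if (rep$primary$category == "periodontitis") {
      expect_false(rep$primary$stage == "none")
      expect_false(rep$primary$grade == "none")
      expect_false(rep$primary$extent == "none")
    } else {
      expect_equal(rep$primary$stage, "none")
    }
  }
})

test_that("diagnosis reports are deterministic and serialize to JSON", {
  ch <- chart_for_diagnosis("generalized periodontitis stage IV grade C",
                            seed = 9)
  ch$teeth[["19"]]$flags <- "defective_restoration"
  r1 <- diagnose(ch)
  r2 <- diagnose(ch)
  expect_identical(report_to_json(r1), report_to_json(r2))
  parsed <- jsonlite::fromJSON(report_to_json(r1))
  expect_equal(parsed$primary$label,
               "generalized periodontitis stage IV grade C")
  expect_equal(parsed$secondary$category, "tooth_prosthesis_related_factors")
  expect_true(length(parsed$treatment_options) > 0)
})
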