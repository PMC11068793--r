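test_that("CAL is probing depth plus signed recession", {
  expect_equal(compute_cal(site_measurement("MB", pd = 5, rec = 2)), 7)
  expect_equal(compute_cal(site_measurement("B", pd = 3, rec = -1)), 2)
  expect_equal(compute_cal(site_measurement("DL", pd = 4, rec = 0)), 4)
  expect_true(is.na(compute_cal(site_measurement("MB", pd = NA, rec = 0))))
})

test_that("CAL is translation-consistent in recession", {
  set.seed(401)
  for (i in 1:50) {
    pd <- sample(0:12, 1)
    rec <- sample(-4:8, 1)
    k <- sample(1:5, 1)
    s0 <- site_measurement("ML", pd = pd, rec = rec)
    s1 <- site_measurement("ML", pd = pd, rec = rec + k)
    expect_equal(compute_cal(s1), compute_cal(s0) + k)
  }
})

test_that("constructors enforce the chart invariants", {
  expect_error(site_measurement("XX", pd = 3, rec = 0), "invalid site id")
  expect_error(site_measurement("MB", pd = 25, rec = 0), "out of range")
  expect_error(site_measurement("MB", pd = 3, rec = -7), "out of range")
  expect_error(tooth_record(8, present = FALSE, sites = healthy_sites()),
               "must not carry site")
  expect_error(tooth_record(8, sites = healthy_sites()[1:5]),
               "exactly 6 sites")
  expect_error(tooth_record(9, furcation_class = 2,
                            sites = healthy_sites()),
               "single-rooted")
  # molars and maxillary first premolars may carry furcation involvement
  expect_s3_class(tooth_record(3, furcation_class = 2,
                               sites = healthy_sites()),
                  "tooth_record")
  expect_error(tooth_record(8, sites = healthy_sites(),
                            flags = "not_a_flag"), "unknown flag")
  expect_error(patient_profile(40, hba1c_percent = 7.5),
               "diabetes context")
})

test_that("chart requires one record per tooth and a diagnosable dentition", {
  teeth_dup <- c(lapply(1:32, function(tn) tooth_record(tn, present = FALSE)),
                 list(tooth_record(1, present = FALSE)))
  expect_error(
    periodontal_chart("c1", patient_profile(40), teeth_dup),
    "duplicate tooth")
  teeth_none <- lapply(1:32, function(tn) tooth_record(tn, present = FALSE))
  expect_error(periodontal_chart("c1", patient_profile(40), teeth_none),
               "not diagnosable")
  # teeth lost to periodontitis cannot exceed total missing teeth
  expect_error(
    make_chart(teeth_lost_to_periodontitis = 10),
    "exceeds missing")
})

test_that("healthy fixture loads, summarizes to zero disease and round-trips", {
  ch <- make_chart(present = 1:32)
  s <- summarize_chart(ch)
  expect_equal(s$scorable_teeth_count, 32)
  expect_equal(s$bleeding_site_fraction, 0)
  expect_length(s$affected_teeth, 0)
  expect_false(s$any_attachment_loss)

  path <- withr::local_tempfile(fileext = ".json")
  write_chart(ch, path)
  ch2 <- load_chart(path)
  expect_identical(chart_to_json(ch), chart_to_json(ch2))
})

test_that("JSON loader rejects malformed charts with location info", {
  ch <- make_chart()
  j <- jsonlite::fromJSON(chart_to_json(ch), simplifyVector = FALSE)
  j$teeth[[33]] <- j$teeth[[1]]
  expect_error(chart_from_json(jsonlite::toJSON(j, auto_unbox = TRUE)),
               "duplicate tooth number 1")
  j2 <- jsonlite::fromJSON(chart_to_json(ch), simplifyVector = FALSE)
  j2$teeth[[1]]$surprise <- 1
  expect_error(chart_from_json(jsonlite::toJSON(j2, auto_unbox = TRUE)),
               "unknown field.*tooth 1")
})

test_that("CSV dialect round-trips and rejects invalid site labels", {
  ch <- make_chart(sites = list(cal_site(3, 6), cal_site(19, 6)),
                   bone = list(`3` = 30, `19` = 30))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(chart_to_csv(ch), f, row.names = FALSE)
  ch2 <- load_chart(f)
  expect_equal(diagnose(ch2)$label, diagnose(ch)$label)

  df <- chart_to_csv(ch)
  df$site[df$row_type == "site"][1] <- "XX"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_chart(f), "invalid site label 'XX'")
})

test_that("summaries take maxima over present natural teeth only", {
  ch <- make_chart(sites = list(list(tooth = 3, site = "MB", pd = 6,
                                     rec = 1)))
  s <- summarize_chart(ch)
  expect_equal(s$max_interdental_cal_mm, 7)
  expect_equal(s$max_probing_depth_mm, 6)

  # implant measurements never enter tooth-level maxima
  ch_imp <- make_chart(implants = 19)
  s2 <- summarize_chart(ch_imp)
  expect_equal(s2$scorable_teeth_count, length(DEFAULT_PRESENT) - 1)
  expect_length(s2$implant_summaries, 1)
})

test_that("summarize is permutation-invariant over tooth ordering", {
  ch <- make_chart(sites = list(cal_site(5, 4), cal_site(20, 4)),
                   bone = list(`5` = 20, `20` = 40))
  set.seed(77)
  shuffled <- periodontal_chart(ch$chart_id, ch$profile,
                                sample(ch$teeth), ch$exam_date)
  expect_identical(summarize_chart(ch), summarize_chart(shuffled))
})

test_that("unmeasured sites are excluded, not imputed", {
  sites3 <- c(list(site_measurement("MB", pd = NA, rec = NA, bop = TRUE)),
              healthy_sites()[-1])
  teeth <- lapply(1:32, function(tn) {
    if (tn == 3) tooth_record(3, sites = sites3)
    else if (tn %in% DEFAULT_PRESENT) tooth_record(tn,
                                                   sites = healthy_sites())
    else tooth_record(tn, present = FALSE)
  })
  ch <- periodontal_chart("na-site", patient_profile(40), teeth)
  s <- summarize_chart(ch)
  expect_equal(s$probed_site_count, length(DEFAULT_PRESENT) * 6 - 1)
  expect_equal(s$bleeding_site_fraction, 0)  # the NA site's bop not counted
})

test_that("Universal to FDI conversion covers all quadrants", {
  expect_equal(universal_to_fdi(c(1, 8, 9, 16, 17, 24, 25, 32)),
               c("18", "11", "21", "28", "38", "31", "41", "48"))
})
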