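test_that("pool_row reproduces the study tables' printed cells", {
  r <- pool_row(list(c(10, 15), c(2, 2), c(5, 8)), decimals = 1)
  expect_equal(c(r$correct, r$total, r$percent), c(17, 25, 68.0))
  r2 <- pool_row(list(c(2, 89), c(2, 10), c(1, 30)), decimals = 2)
  expect_equal(c(r2$correct, r2$total, r2$percent), c(5, 129, 3.88))
  r3 <- pool_row(list(c(0, 0), c(0, 0)))
  expect_true(is.na(r3$percent))
  expect_equal(render_cell(0, 0), "0/0 (-)")
  expect_equal(render_cell(17, 25, 1), "17/25 (68)")
  expect_error(pool_row(list(c(3, 2))), "correct <= total")
})

test_that("pooling is associative over any grouping of cells", {
  set.seed(31)
  for (i in 1:20) {
    totals <- sample(0:30, 6, replace = TRUE)
    cells <- lapply(totals, function(t) {
      c(if (t > 0) sample(0:t, 1) else 0, t)
    })
    whole <- pool_row(cells)
    left <- pool_row(cells[1:3])
    right <- pool_row(cells[4:6])
    regrouped <- pool_row(list(c(left$correct, left$total),
                               c(right$correct, right$total)))
    expect_equal(regrouped$correct, whole$correct)
    expect_equal(regrouped$total, whole$total)
    expect_equal(regrouped$percent, whole$percent)
  }
})

test_that("percent cells round half up to the printed precision", {
  expect_equal(round_half_up(87.5, 0), 88)
  expect_equal(round_half_up(3.875, 2), 3.88)
  expect_equal(round_half_up(57.69, 1), 57.7)
})

# per-group (correct, total) incident counts for the six secondary
# conditions as observed in the chairside study
SEC_COUNTS <- list(
  tooth_prosthesis_related_factors     = list(DS3 = c(2, 89), DS4 = c(2, 10), ISP2 = c(1, 30)),
  occlusal_trauma                      = list(DS3 = c(7, 80), DS4 = c(3, 10), ISP2 = c(3, 28)),
  mucogingival_deformity               = list(DS3 = c(18, 36), DS4 = c(3, 4), ISP2 = c(9, 12)),
  periodontitis_systemic_manifestation = list(DS3 = c(4, 34), DS4 = c(0, 5), ISP2 = c(0, 5)),
  endo_periodontal_lesion              = list(DS3 = c(1, 16), DS4 = c(0, 0), ISP2 = c(1, 2)),
  periodontal_abscess                  = list(DS3 = c(0, 11), DS4 = c(0, 0), ISP2 = c(0, 2))
)

records_from_counts <- function(counts) {
  rows <- list()
  id <- 0
  for (cat in names(counts)) {
    for (g in names(counts[[cat]])) {
      cell <- counts[[cat]][[g]]
      for (j in seq_len(cell[2])) {
        id <- id + 1
        rows[[id]] <- data.frame(
          case_id = paste0("c", id), group = g,
          gold_label = "generalized periodontitis stage III grade B",
          control_correct = FALSE, test_correct = TRUE,
          secondary_gold = cat,
          secondary_found_control = if (j <= cell[1]) cat else "",
          secondary_found_test = cat,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("incident scoring reproduces the secondary-condition tables", {
  res <- score_accuracy(records_from_counts(SEC_COUNTS))
  sec <- res$secondary
  tp <- sec[sec$category == "tooth_prosthesis_related_factors", ]
  expect_equal(c(tp$total_correct, tp$total_n), c(5, 129))
  mg <- sec[sec$category == "mucogingival_deformity", ]
  expect_equal(round_half_up(100 * mg$total_correct / mg$total_n, 1), 57.7)
  # group margins over the per-cell counts
  expect_equal(c(sum(sec$DS3_correct), sum(sec$DS3_total)), c(32, 266))
  expect_equal(c(sum(sec$DS4_correct), sum(sec$DS4_total)), c(8, 29))
  expect_equal(c(sum(sec$ISP2_correct), sum(sec$ISP2_total)), c(14, 79))
  # the pooled grand total follows the cells exactly (sums of the printed
  # group cells; the published row-totals column carries five additional
  # systemic-manifestation incidents absent from its own group cells)
  expect_equal(res$totals$secondary$correct, 54)
  expect_equal(res$totals$secondary$total, sum(sec$total_n))
})

test_that("primary scoring handles perfect, partial and single-group input", {
  rec <- data.frame(
    case_id = paste0("c", 1:6), group = c("DS3", "DS3", "DS3", "DS4",
                                          "ISP2", "ISP2"),
    gold_label = rep(c("localized periodontitis stage III grade B",
                       "gingivitis"), 3),
    control_correct = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    test_correct = TRUE, stringsAsFactors = FALSE)
  res <- score_accuracy(rec)
  expect_equal(res$totals$primary$total, 6)
  expect_equal(res$totals$primary$correct, 4)
  expect_equal(sum(res$primary$test_correct), 6)

  all_right <- rec
  all_right$control_correct <- TRUE
  expect_equal(score_accuracy(all_right)$totals$primary$percent, 100)

  one_group <- rec[rec$group == "DS3", ]
  res1 <- score_accuracy(one_group)
  expect_false("DS4_total" %in% names(res1$primary))
  expect_equal(res1$totals$primary$total, 3)

  bad <- rec
  bad$group[1] <- "DS9"
  expect_error(score_accuracy(bad), "unknown group")
})

test_that("accuracy tables render in the n/n (%) cell syntax", {
  res <- score_accuracy(records_from_counts(SEC_COUNTS))
  md <- render_accuracy_markdown(res$secondary, decimals = 2)
  expect_true(any(grepl("2/89 \\(2.25\\)", md)))
  expect_true(any(grepl("0/0 \\(-\\)", md)))
})

test_that("exact Wilcoxon p-values match the enumerated references", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 0.0625)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1.0)
  deg <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("exact p equals brute-force sign enumeration (untied inputs)", {
  set.seed(32)
  for (i in 1:120) {
    n <- sample(1:10, 1)
    d <- round(stats::rnorm(n, sample(c(-1, 0, 1), 1), 2), 3)
    d <- d[d != 0]
    if (length(d) == 0) next
    got <- wilcoxon_signed_rank(d)
    expect_true(got$exact)
    expect_equal(got$p_value, wsr_brute_force(d), tolerance = 1e-12)
    # two-sided symmetry under negation
    expect_equal(wilcoxon_signed_rank(-d)$p_value, got$p_value)
  }
})

test_that("exact p agrees with the reference implementation in stats", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    d <- stats::rnorm(n, 0.5, 1)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("paired condition comparison reports means, SEM and the verdict", {
  set.seed(34)
  control <- stats::rnorm(22, 15, 8)
  test <- control + stats::rnorm(22, 40, 5)
  res <- compare_conditions(control, test, alpha = 0.01)
  expect_true(res$reject)
  expect_equal(res$direction, "test > control")
  expect_equal(res$sem_control, stats::sd(control) / sqrt(22))

  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$reject)
  expect_equal(same$p_value, 1)
  expect_error(compare_conditions(1:3, 1:4), "equal length")
})

test_that("Likert summaries format as mean (range lo-hi) per group", {
  out <- summarize_likert(c(5, 4, 4, 5, 4, 3, 5, 4),
                          group = c(rep("DS3", 4), rep("DS4", 4)))
  expect_equal(nrow(out), 2)
  expect_equal(out$formatted[out$group == "DS3"], "4.50 (range 4-5)")
  expect_equal(out$min[out$group == "DS4"], 3)
})
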