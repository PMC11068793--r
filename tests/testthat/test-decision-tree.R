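test_that("the default tree validates cleanly and covers every leaf", {
  tree <- build_default_tree()
  expect_length(validate_tree(tree), 0)
  paths <- enumerate_paths(tree)
  expect_true(length(paths) > 0)
  leaves_in_paths <- unique(vapply(paths, `[[`, character(1), "leaf_id"))
  all_leaves <- names(Filter(function(n) n$kind == "leaf", tree$nodes))
  expect_setequal(leaves_in_paths, all_leaves)
  # all 36 extent x stage x grade periodontitis leaves exist
  expect_equal(sum(grepl("^leaf\\.perio\\.", all_leaves)), 36)
})

test_that("validation reports dangling references, bad leaves and cycles", {
  qa <- tree_node("qa", "question", question_text = "a?", predicate = "p.case",
                  answers = list(list(label = "yes", next_node_id = "qb"),
                                 list(label = "no", next_node_id = "Q99")))
  leaf <- tree_node("qb", "leaf",
                    diagnosis = list(category = "gingivitis"),
                    treatment_options = "clean")
  tree <- decision_tree("qa", list(qa, leaf))
  issues <- validate_tree(tree)
  expect_true(any(grepl("dangling reference.*Q99", issues)))

  # a leaf stripped of treatment options violates the leaf contract
  leaf2 <- leaf
  leaf2$treatment_options <- character()
  issues2 <- validate_tree(decision_tree("qa", list(qa, leaf2)))
  expect_true(any(grepl("lacks treatment options", issues2)))

  # two questions pointing at each other form a cycle
  q1 <- tree_node("q1", "question", predicate = "p.case",
                  answers = list(list(label = "yes", next_node_id = "q2"),
                                 list(label = "no", next_node_id = "q2")))
  q2 <- tree_node("q2", "question", predicate = "p.case",
                  answers = list(list(label = "yes", next_node_id = "q1"),
                                 list(label = "no", next_node_id = "q1")))
  expect_true(any(grepl("cycle", validate_tree(
    decision_tree("q1", list(q1, q2))))))

  # unreachable nodes are reported
  lone <- tree_node("lone", "leaf",
                    diagnosis = list(category = "gingivitis"),
                    treatment_options = "clean")
  expect_true(any(grepl("unreachable.*lone", validate_tree(
    decision_tree("qa", list(qa, leaf, lone))))))

  # node-level contracts are enforced at construction
  expect_error(tree_node("q", "question", predicate = "p.case",
                         answers = list(list(label = "only",
                                             next_node_id = "x"))),
               ">= 2 answers")
  expect_error(tree_node("l", "leaf",
                         diagnosis = list(category = "gingivitis")),
               "treatment options")
})

test_that("traverse consumes answers and rejects invalid labels", {
  tree <- build_default_tree()
  # no answers: the root question is pending
  r0 <- traverse(tree)
  expect_false(r0$done)
  expect_equal(r0$node$node_id, tree$root_id)
  # the gingival-health path: healthy dentition, no bleeding, intact
  r <- traverse(tree, c("natural teeth present", "no", "under 10%",
                        "intact"))
  expect_true(r$done)
  expect_equal(r$node$diagnosis$category, "clinical_gingival_health_intact")
  expect_true(length(r$node$treatment_options) > 0)
  # invalid label names the node and the offered answers
  expect_error(traverse(tree, "maybe"),
               "invalid answer 'maybe'.*natural teeth present")
})

test_that("auto-answer reaches the same diagnosis as the engine", {
  tree <- build_default_tree()
  healthy <- make_chart()
  aa <- auto_answer(tree, healthy)
  expect_equal(aa$leaf$diagnosis$category,
               "clinical_gingival_health_intact")
  expect_equal(aa$leaf$diagnosis$category,
               diagnose(healthy)$primary$category)

  severe <- chart_for_diagnosis("generalized periodontitis stage IV grade C",
                                seed = 4)
  aa2 <- auto_answer(tree, severe)
  expect_equal(aa2$leaf$diagnosis$label,
               "generalized periodontitis stage IV grade C")
})

test_that("auto-answer fails with the predicate id when evidence is missing", {
  # periodontitis case without any radiographic bone loss: the grading
  # question cannot be answered
  teeth <- lapply(1:32, function(tn) {
    if (tn %in% c(3, 19)) {
      s <- healthy_sites()
      s[[1]] <- site_measurement("MB", pd = 6, rec = 0, bop = TRUE)
      tooth_record(tn, sites = s, bone_loss_percent = NA)
    } else if (tn %in% DEFAULT_PRESENT) {
      tooth_record(tn, sites = healthy_sites(), bone_loss_percent = NA)
    } else tooth_record(tn, present = FALSE)
  })
  ch <- periodontal_chart("no-xray", patient_profile(50), teeth)
  expect_error(auto_answer(build_default_tree(), ch), "p\\.grade_band")
})

test_that("tree/engine equivalence holds across a generated cohort", {
  tree <- build_default_tree()
  co <- sample_cohort(cohort_config(40, seed = 505))
  mismatches <- 0
  for (i in seq_along(co$charts)) {
    d <- auto_answer(tree, co$charts[[i]])$leaf$diagnosis
    e <- diagnose(co$charts[[i]])$primary
    if (!(d$category == e$category && d$extent == e$extent &&
            d$stage == e$stage && d$grade == e$grade)) {
      mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("trees round-trip through JSON and loading validates", {
  tree <- build_default_tree()
  f <- withr::local_tempfile(fileext = ".json")
  save_tree(tree, f)
  tree2 <- load_tree(f)
  expect_equal(length(tree2$nodes), length(tree$nodes))
  expect_equal(tree2$version, tree$version)
  ch <- chart_for_diagnosis("localized periodontitis stage III grade B",
                            seed = 2)
  expect_equal(auto_answer(tree2, ch)$leaf$diagnosis$label,
               auto_answer(tree, ch)$leaf$diagnosis$label)

  writeLines("this is { not json", f)
  expect_error(load_tree(f), "cannot parse")
})

test_that("glossary lookups resolve shipped definitions", {
  defs <- define_term()
  expect_true(length(defs) > 10)
  expect_match(define_term("CAL"), "cemento-enamel", ignore.case = TRUE)
  expect_error(define_term("flux capacitor"), "no definition")
})
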