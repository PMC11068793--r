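#' @title Question-tree front end
#' @description A serializable directed question/answer graph whose leaves
#'   carry a diagnosis plus treatment options. Question nodes carry a
#'   machine-readable predicate identifier so the tree can be auto-answered
#'   from a chart and cross-checked against the rule engine; both draw their
#'   clinical constants from the same [clinical_config()], so they cannot
#'   drift apart.
#' @name decision-tree
NULL

#' Construct a tree node
#'
#' @param node_id stable string id.
#' @param kind "question" or "leaf".
#' @param question_text,info_text question wording and the expandable
#'   explanatory text (question nodes).
#' @param predicate predicate id resolvable by [auto_answer()] (question
#'   nodes).
#' @param answers list of `list(label=, next_node_id=)` (question nodes,
#'   >= 2 entries).
#' @param diagnosis for leaves: list with category/extent/stage/grade.
#' @param treatment_options for leaves: non-empty character vector (every
#'   leaf must pair its diagnosis with suggested treatment).
#' @param refs citation strings.
#' @return a `tree_node`.
#' @export
tree_node <- function(node_id, kind = c("question", "leaf"),
                      question_text = NULL, info_text = NULL,
                      predicate = NULL, answers = NULL, diagnosis = NULL,
                      treatment_options = NULL, refs = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(node_id), nzchar(node_id))
  if (kind == "question") {
    if (is.null(answers) || length(answers) < 2L) {
      stop("question node '", node_id, "' must offer >= 2 answers",
           call. = FALSE)
    }
  } else {
    if (is.null(diagnosis)) {
      stop("leaf node '", node_id, "' must carry a diagnosis", call. = FALSE)
    }
    if (is.null(treatment_options) || length(treatment_options) == 0L) {
      stop("leaf node '", node_id, "' must carry treatment options",
           call. = FALSE)
    }
  }
  structure(list(node_id = node_id, kind = kind,
                 question_text = question_text, info_text = info_text,
                 predicate = predicate, answers = answers,
                 diagnosis = diagnosis,
                 treatment_options = treatment_options, refs = refs),
            class = "tree_node")
}

#' Construct a decision tree
#'
#' @param root_id id of the root node.
#' @param nodes list of [tree_node()]s (named by id or not).
#' @param version version string of the tree content.
#' @param resources citation strings shown in the tree's resources section.
#' @return a `decision_tree`.
#' @export
decision_tree <- function(root_id, nodes, version = "1.0.0",
                          resources = character()) {
  ids <- vapply(nodes, `[[`, character(1), "node_id")
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ", paste(ids[duplicated(ids)],
                                         collapse = ", "), call. = FALSE)
  }
  names(nodes) <- ids
  if (!(root_id %in% ids)) stop("root id '", root_id, "' not among nodes",
                                call. = FALSE)
  structure(list(root_id = root_id, nodes = nodes, version = version,
                 resources = resources),
            class = "decision_tree")
}

#' Validate a decision tree
#'
#' Reports dangling answer references, nodes unreachable from the root,
#' cycles, leaves without treatment options, and question nodes with fewer
#' than two answers.
#'
#' @param tree a `decision_tree`.
#' @return character vector of issues; empty iff the tree is valid.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  issues <- character()
  ids <- names(tree$nodes)
  for (n in tree$nodes) {
    if (n$kind == "question") {
      if (length(n$answers) < 2L) {
        issues <- c(issues, paste0("question '", n$node_id,
                                   "' has fewer than 2 answers"))
      }
      for (a in n$answers) {
        if (!(a$next_node_id %in% ids)) {
          issues <- c(issues, paste0("dangling reference: '", n$node_id,
                                     "' answer '", a$label, "' -> '",
                                     a$next_node_id, "'"))
        }
      }
    } else {
      if (length(n$treatment_options) == 0L) {
        issues <- c(issues, paste0(
          "leaf '", n$node_id, "' lacks treatment options (every leaf ",
          "must pair its diagnosis with suggested treatment)"))
      }
    }
  }
  # reachability and cycle detection (iterative DFS over the answer graph)
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new 1 open 2 done
  cycle_found <- FALSE
  visit <- function(id) {
    stack <- list(list(id = id, i = 0L))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- tree$nodes[[top$id]]
      if (top$i == 0L) color[[top$id]] <<- 1L
      nexts <- if (node$kind == "question") {
        vapply(node$answers, `[[`, character(1), "next_node_id")
      } else character()
      nexts <- nexts[nexts %in% ids]
      if (top$i < length(nexts)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nx <- nexts[top$i + 1L]
        if (color[[nx]] == 1L) {
          cycle_found <<- TRUE
        } else if (color[[nx]] == 0L) {
          stack[[length(stack) + 1L]] <- list(id = nx, i = 0L)
        }
      } else {
        color[[top$id]] <<- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  visit(tree$root_id)
  if (cycle_found) issues <- c(issues, "cycle detected in answer graph")
  unreachable <- ids[color == 0L]
  if (length(unreachable)) {
    issues <- c(issues, paste0("unreachable node(s): ",
                               paste(unreachable, collapse = ", ")))
  }
  issues
}

#' Traverse a tree with an ordered list of answer labels
#'
#' Pure function: consumes labels from the root and returns the reached
#' leaf, or the pending question when the answers are exhausted.
#'
#' @param tree a `decision_tree`.
#' @param answers character vector of answer labels, in order.
#' @return list with `node` (the reached `tree_node`), `path` (node ids
#'   visited) and `done` (TRUE iff a leaf was reached).
#' @export
traverse <- function(tree, answers = character()) {
  stopifnot(inherits(tree, "decision_tree"))
  node <- tree$nodes[[tree$root_id]]
  path <- node$node_id
  for (lab in answers) {
    if (node$kind == "leaf") {
      stop("answer '", lab, "' supplied after reaching leaf '",
           node$node_id, "'", call. = FALSE)
    }
    labels <- vapply(node$answers, `[[`, character(1), "label")
    k <- match(lab, labels)
    if (is.na(k)) {
      stop("invalid answer '", lab, "' at node '", node$node_id,
           "'; offered: ", paste(labels, collapse = " | "), call. = FALSE)
    }
    node <- tree$nodes[[node$answers[[k]]$next_node_id]]
    path <- c(path, node$node_id)
  }
  list(node = node, path = path, done = node$kind == "leaf")
}

#' Enumerate all root-to-leaf paths
#'
#' @param tree a `decision_tree`.
#' @return list of lists with `labels` (answer labels) and `leaf_id`.
#' @export
enumerate_paths <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  out <- list()
  walk <- function(id, labels) {
    node <- tree$nodes[[id]]
    if (node$kind == "leaf") {
      out[[length(out) + 1L]] <<- list(labels = labels, leaf_id = id)
      return(invisible())
    }
    for (a in node$answers) walk(a$next_node_id, c(labels, a$label))
  }
  walk(tree$root_id, character())
  out
}

#' Auto-answer a tree from a chart
#'
#' Evaluates each question node's predicate against the chart, its summary
#' and the patient profile, follows the matching answer, and returns the
#' reached leaf with the answer path. Deterministic; the reached leaf's
#' diagnosis equals [diagnose()]'s primary diagnosis for every chart (the
#' core tree/engine consistency property).
#'
#' @param tree a `decision_tree`.
#' @param chart a [periodontal_chart()].
#' @param profile a [patient_profile()]; defaults to the chart's.
#' @param config the [clinical_config()] shared with the engine.
#' @return list with `path` (answer labels), `node_path` (node ids) and
#'   `leaf` (the reached `tree_node`).
#' @export
auto_answer <- function(tree, chart, profile = chart$profile,
                        config = clinical_config()) {
  stopifnot(inherits(tree, "decision_tree"),
            inherits(chart, "periodontal_chart"))
  summary <- summarize_chart(chart, config)
  evidence <- is_periodontitis_case(chart, config, summary = summary)
  ctx <- list(chart = chart, profile = profile, summary = summary,
              evidence = evidence, config = config)
  node <- tree$nodes[[tree$root_id]]
  labels <- character()
  node_path <- node$node_id
  while (node$kind == "question") {
    pred <- node$predicate
    if (is.null(pred) || !(pred %in% names(.PREDICATES))) {
      stop("question '", node$node_id, "' has unresolvable predicate id '",
           if (is.null(pred)) "<none>" else pred, "'", call. = FALSE)
    }
    lab <- .PREDICATES[[pred]](ctx)
    offered <- vapply(node$answers, `[[`, character(1), "label")
    k <- match(lab, offered)
    if (is.na(k)) {
      stop("predicate '", pred, "' produced answer '", lab,
           "' not offered at node '", node$node_id, "'", call. = FALSE)
    }
    labels <- c(labels, lab)
    node <- tree$nodes[[node$answers[[k]]$next_node_id]]
    node_path <- c(node_path, node$node_id)
  }
  list(path = labels, node_path = node_path, leaf = node)
}

# predicate registry: each maps an evaluation context to an answer label ------

.PREDICATES <- list(
  p.dentition = function(ctx) {
    if (ctx$summary$scorable_teeth_count > 0L) "natural teeth present"
    else "implants only"
  },
  p.worst_implant_status = function(ctx) {
    imp <- ctx$summary$implant_summaries
    if (length(imp) == 0L) {
      stop("predicate 'p.worst_implant_status' unresolvable: chart has no ",
           "implants", call. = FALSE)
    }
    sev <- vapply(imp, function(s) {
      if (s$progressive_bone_loss) 3L else if (s$any_bop || s$any_sup) 2L
      else 1L
    }, integer(1))
    c("no inflammation", "bleeding without progressive bone loss",
      "progressive bone loss")[max(sev)]
  },
  p.case = function(ctx) if (ctx$evidence$is_case) "yes" else "no",
  p.bop_band = function(ctx) {
    bop <- ctx$summary$bleeding_site_fraction
    if (is.na(bop)) bop <- 0
    g <- ctx$config$gingival
    if (bop < g$health_bop_below) "under 10%"
    else if (bop > g$generalized_bop_above) "over 30%"
    else "10-30%"
  },
  p.periodontium = function(ctx) {
    if (.reduced_periodontium(ctx$summary, ctx$profile)) "reduced" else
      "intact"
  },
  p.extent = function(ctx) {
    e <- assign_extent(ctx$summary, ctx$config)
    switch(e$extent, localized = "localized", generalized = "generalized",
           molar_incisor_pattern = "molar-incisor pattern")
  },
  p.severity_band = function(ctx) {
    cal <- ctx$summary$max_interdental_cal_mm
    cfg <- ctx$config
    if (is.na(cal) || cal < cfg$case$interdental_cal_min_mm) {
      cal <- ctx$summary$max_cal_mm_buccal_lingual
    }
    if (is.na(cal)) {
      stop("predicate 'p.severity_band' unresolvable: no CAL evidence",
           call. = FALSE)
    }
    if (cal <= cfg$stage$severity_cal_stage1_max_mm) "CAL 1-2 mm"
    else if (cal <= cfg$stage$severity_cal_stage2_max_mm) "CAL 3-4 mm"
    else "CAL 5 mm or more"
  },
  p.complexity = function(ctx) {
    s <- ctx$summary; cfg <- ctx$config$stage
    hit <- (!is.na(s$max_probing_depth_mm) &&
              s$max_probing_depth_mm >= cfg$complexity_pd_min_mm) ||
      s$max_furcation_class >= cfg$complexity_furcation_min ||
      s$any_vertical_defect
    if (hit) "yes" else "no"
  },
  p.stage4 = function(ctx) {
    cfg <- ctx$config$stage
    iv <- ctx$profile$teeth_lost_to_periodontitis >=
      cfg$stage4_teeth_lost_min ||
      ctx$summary$scorable_teeth_count < cfg$stage4_remaining_teeth_lt ||
      ctx$profile$masticatory_dysfunction
    if (iv) "yes" else "no"
  },
  p.grade_band = function(ctx) {
    if (is.na(ctx$summary$worst_bone_loss_percent)) {
      stop("predicate 'p.grade_band' unresolvable: no radiographic bone ",
           "loss recorded", call. = FALSE)
    }
    r <- ctx$summary$worst_bone_loss_percent / ctx$profile$age_years
    g <- ctx$config$grade
    if (r < g$ratio_a_below) "under 0.25"
    else if (r <= g$ratio_c_above) "0.25 to 1.0"
    else "over 1.0"
  },
  p.modifier_band = function(ctx) {
    p <- ctx$profile; g <- ctx$config$grade
    if (p$smoking_cigarettes_per_day >= g$smoking_c_min ||
        (p$has_diabetes && !is.na(p$hba1c_percent) &&
           p$hba1c_percent >= g$hba1c_c_min)) {
      "severe"
    } else if (p$smoking_cigarettes_per_day >= g$smoking_b_min ||
                 p$has_diabetes) {
      "moderate"
    } else "none"
  }
)
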