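#' Build the default diagnostic question tree
#'
#' Programmatically generates the full question tree for the 2017
#' classification from the same [clinical_config()] the engine uses: case
#' definition, extent, severity band, complexity shift-up, stage IV
#' discriminators, grade band and risk-modifier upgrade, the gingival
#' branch, and the peri-implant branch for implant-only dentitions. Leaves
#' carry the diagnosis and its suggested treatment options. The generated
#' tree validates cleanly and is provably equivalent to [diagnose()] (see
#' the package tests).
#'
#' @param config a [clinical_config()].
#' @param version tree content version string.
#' @return a [decision_tree()].
#' @export
build_default_tree <- function(config = clinical_config(),
                               version = "1.0.0") {
  nodes <- list()
  add <- function(node) nodes[[node$node_id]] <<- node
  q <- function(id, text, info, predicate, answers) {
    add(tree_node(id, "question", question_text = text, info_text = info,
                  predicate = predicate, answers = answers))
  }
  ans <- function(label, nxt) list(label = label, next_node_id = nxt)
  perio_leaf <- function(extent, stage, grade) {
    id <- paste0("leaf.perio.", extent, ".", stage, ".", grade)
    if (is.null(nodes[[id]])) {
      d <- primary_diagnosis("periodontitis", extent = extent, stage = stage,
                             grade = grade,
                             rationale = paste0("tree.", id))
      add(tree_node(id, "leaf",
                    diagnosis = list(category = "periodontitis",
                                     extent = extent, stage = stage,
                                     grade = grade,
                                     label = diagnosis_label(d)),
                    treatment_options = .TREATMENTS$periodontitis))
    }
    id
  }
  simple_leaf <- function(category, label = category) {
    id <- paste0("leaf.", category)
    add(tree_node(id, "leaf",
                  diagnosis = list(category = category, extent = "none",
                                   stage = "none", grade = "none",
                                   label = label),
                  treatment_options = .TREATMENTS[[category]]))
    id
  }

  upgrade <- function(base, mod) {
    # risk modifiers only upgrade: severe -> C, moderate -> at least B
    if (mod == "severe") return("C")
    if (mod == "moderate" && base == "A") return("B")
    base
  }

  grade_subtree <- function(tag, extent, stage) {
    # q.gr.<tag>: bone-loss/age band, then q.mod.<tag>.<base>: modifiers
    for (base in c("A", "B", "C")) {
      q(paste0("q.mod.", tag, ".", base),
        "Are grade risk modifiers present (smoking, diabetes)?",
        paste("Smoking of 10 or more cigarettes/day, or diabetes with",
              "HbA1c of 7.0% or more, forces grade C; lighter smoking or",
              "diabetes below that level raises the grade to at least B.",
              "Modifiers never lower a grade."),
        "p.modifier_band",
        list(ans("none", perio_leaf(extent, stage, upgrade(base, "none"))),
             ans("moderate",
                 perio_leaf(extent, stage, upgrade(base, "moderate"))),
             ans("severe",
                 perio_leaf(extent, stage, upgrade(base, "severe")))))
    }
    q(paste0("q.gr.", tag),
      "What is the ratio of worst radiographic bone loss (%) to age?",
      paste("Indirect evidence of progression: percent bone loss at the",
            "worst affected tooth divided by patient age. Under 0.25 points",
            "to grade A, 0.25-1.0 to grade B, over 1.0 to grade C."),
      "p.grade_band",
      list(ans("under 0.25", paste0("q.mod.", tag, ".A")),
           ans("0.25 to 1.0", paste0("q.mod.", tag, ".B")),
           ans("over 1.0", paste0("q.mod.", tag, ".C"))))
    paste0("q.gr.", tag)
  }

  extent_labels <- c(localized = "localized", generalized = "generalized",
                     molar_incisor_pattern = "molar-incisor pattern")
  for (extent in names(extent_labels)) {
    e <- substr(extent, 1, 3)
    g1 <- grade_subtree(paste0(e, ".I"), extent, "I")
    g2 <- grade_subtree(paste0(e, ".II"), extent, "II")
    g3 <- grade_subtree(paste0(e, ".III"), extent, "III")
    g4 <- grade_subtree(paste0(e, ".IV"), extent, "IV")
    q(paste0("q.iv.", e),
      "Are stage IV features present (teeth lost to periodontitis, fewer than 20 teeth, masticatory dysfunction)?",
      paste("Stage IV adds dentition-level damage to severe periodontitis:",
            "5 or more teeth lost to periodontitis, fewer than 20 remaining",
            "teeth, or masticatory dysfunction."),
      "p.stage4",
      list(ans("yes", g4), ans("no", g3)))
    q(paste0("q.cx.", e, ".I"),
      "Are complexity factors present (PD >= 6 mm, furcation class II+, vertical defect)?",
      paste("Probing depths of 6 mm or more, class II/III furcation",
            "involvement, or vertical bony defects raise the stage to at",
            "least III regardless of CAL severity."),
      "p.complexity",
      list(ans("yes", paste0("q.iv.", e)), ans("no", g1)))
    q(paste0("q.cx.", e, ".II"),
      "Are complexity factors present (PD >= 6 mm, furcation class II+, vertical defect)?",
      paste("Probing depths of 6 mm or more, class II/III furcation",
            "involvement, or vertical bony defects raise the stage to at",
            "least III regardless of CAL severity."),
      "p.complexity",
      list(ans("yes", paste0("q.iv.", e)), ans("no", g2)))
    q(paste0("q.sev.", e),
      "What is the maximum interdental CAL?",
      paste("Severity staging uses the worst interproximal clinical",
            "attachment loss: 1-2 mm points to stage I, 3-4 mm to stage II,",
            "5 mm or more to the stage III/IV band."),
      "p.severity_band",
      list(ans("CAL 1-2 mm", paste0("q.cx.", e, ".I")),
           ans("CAL 3-4 mm", paste0("q.cx.", e, ".II")),
           ans("CAL 5 mm or more", paste0("q.iv.", e))))
  }

  # gingival (non-case) branch
  leaf_gi <- simple_leaf("clinical_gingival_health_intact",
                         "clinical gingival health on an intact periodontium")
  leaf_gr <- simple_leaf("clinical_gingival_health_reduced",
                         "clinical gingival health on a reduced periodontium")
  add(tree_node("leaf.gingivitis.localized", "leaf",
                diagnosis = list(category = "gingivitis", extent = "none",
                                 stage = "none", grade = "none",
                                 label = "gingivitis"),
                treatment_options = .TREATMENTS$gingivitis))
  add(tree_node("leaf.gingivitis.generalized", "leaf",
                diagnosis = list(category = "gingivitis", extent = "none",
                                 stage = "none", grade = "none",
                                 label = "gingivitis"),
                treatment_options = .TREATMENTS$gingivitis))
  q("q.periodontium",
    "Is the periodontium intact or reduced?",
    paste("A reduced periodontium shows attachment loss, radiographic bone",
          "loss, teeth lost to periodontitis, or a history of periodontal",
          "treatment, without currently meeting the periodontitis case",
          "definition."),
    "p.periodontium",
    list(ans("intact", leaf_gi), ans("reduced", leaf_gr)))
  q("q.bop",
    "What fraction of probed sites bleed on probing?",
    paste("Bleeding on probing at fewer than 10% of sites is compatible",
          "with gingival health; 10-30% is localized gingivitis; more than",
          "30% is generalized gingivitis."),
    "p.bop_band",
    list(ans("under 10%", "q.periodontium"),
         ans("10-30%", "leaf.gingivitis.localized"),
         ans("over 30%", "leaf.gingivitis.generalized")))

  # peri-implant branch (implant-only dentition)
  leaf_ih <- simple_leaf("peri_implant_health", "peri-implant health")
  leaf_im <- simple_leaf("peri_implant_mucositis", "peri-implant mucositis")
  leaf_ii <- simple_leaf("peri_implantitis", "peri-implantitis")
  q("q.implant",
    "What is the worst peri-implant status?",
    paste("Bleeding or suppuration on probing without progressive bone",
          "loss is peri-implant mucositis; progressive crestal bone loss",
          "is peri-implantitis."),
    "p.worst_implant_status",
    list(ans("no inflammation", leaf_ih),
         ans("bleeding without progressive bone loss", leaf_im),
         ans("progressive bone loss", leaf_ii)))

  q("q.extent",
    "What fraction of scorable teeth is affected?",
    paste("Fewer than 30% of teeth affected is localized, 30% or more is",
          "generalized. When only first/second molars and incisors are",
          "affected (at least one of each) the molar-incisor pattern takes",
          "precedence."),
    "p.extent",
    list(ans("localized", "q.sev.loc"),
         ans("generalized", "q.sev.gen"),
         ans("molar-incisor pattern", "q.sev.mol")))
  q("q.case",
    "Does the chart meet the periodontitis case definition?",
    paste("Interproximal CAL in 2 or more non-adjacent teeth, or buccal or",
          "lingual CAL of 3 mm or more in 2 or more teeth, attributable to",
          "inflammatory periodontal breakdown."),
    "p.case",
    list(ans("yes", "q.extent"), ans("no", "q.bop")))
  q("q.entry",
    "Are natural teeth present?",
    "Implant-only dentitions follow the peri-implant route.",
    "p.dentition",
    list(ans("natural teeth present", "q.case"),
         ans("implants only", "q.implant")))

  decision_tree("q.entry", unname(nodes), version = version,
                resources = c(
                  "2017 World Workshop on the Classification of Periodontal and Peri-Implant Diseases and Conditions (consensus reports)",
                  "Periodontitis case definition and staging/grading framework papers of the 2017 Workshop",
                  "Peri-implant health, mucositis and peri-implantitis case definition papers of the 2017 Workshop"))
}
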