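#' Serialize a decision tree to JSON
#'
#' @param tree a [decision_tree()].
#' @param pretty pretty-print?
#' @return JSON string.
#' @export
tree_to_json <- function(tree, pretty = TRUE) {
  stopifnot(inherits(tree, "decision_tree"))
  nodes <- lapply(unname(tree$nodes), function(n) {
    if (n$kind == "question") {
      list(node_id = n$node_id, kind = "question",
           question_text = n$question_text %||% "",
           info_text = n$info_text %||% "",
           predicate = n$predicate %||% "",
           answers = lapply(n$answers, function(a) {
             list(label = a$label, next_node_id = a$next_node_id)
           }))
    } else {
      list(node_id = n$node_id, kind = "leaf",
           diagnosis = n$diagnosis,
           treatment_options = as.list(n$treatment_options),
           refs = as.list(n$refs))
    }
  })
  jsonlite::toJSON(list(root_id = tree$root_id, version = tree$version,
                        resources = as.list(tree$resources), nodes = nodes),
                   auto_unbox = TRUE, pretty = pretty, null = "null")
}

#' Write a decision tree to a JSON file
#' @param tree a [decision_tree()].
#' @param path output path.
#' @export
save_tree <- function(tree, path) {
  writeLines(tree_to_json(tree), path)
  invisible(path)
}

#' Load a decision tree from a JSON file
#'
#' The loaded tree is validated; validation issues are reported as a
#' warning (use [validate_tree()] for the full list).
#'
#' @param path path to a tree JSON file.
#' @return a [decision_tree()].
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse tree file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nodes <- lapply(x$nodes, function(n) {
    if (identical(n$kind, "question")) {
      tree_node(n$node_id, "question",
                question_text = n$question_text,
                info_text = n$info_text,
                predicate = n$predicate,
                answers = lapply(n$answers, function(a) {
                  list(label = a$label, next_node_id = a$next_node_id)
                }))
    } else {
      tree_node(n$node_id, "leaf",
                diagnosis = n$diagnosis,
                treatment_options = unlist(n$treatment_options),
                refs = unlist(n$refs) %||% character())
    }
  })
  tree <- decision_tree(x$root_id, nodes, version = x$version %||% "0",
                        resources = unlist(x$resources) %||% character())
  issues <- validate_tree(tree)
  if (length(issues)) {
    warning("loaded tree has ", length(issues), " validation issue(s); ",
            "see validate_tree()", call. = FALSE)
  }
  tree
}

#' Look up a glossary definition
#'
#' Definitions of the most common periodontal terms and abbreviations, as
#' shipped in the package's definitions data file.
#'
#' @param term term to look up (case-insensitive); NULL lists all terms.
#' @return named character vector of matching definitions.
#' @export
define_term <- function(term = NULL) {
  path <- system.file("extdata", "definitions.md", package = "periodx")
  lines <- readLines(path, warn = FALSE)
  entries <- grep("^- \\*\\*", lines, value = TRUE)
  keys <- sub("^- \\*\\*([^*]+)\\*\\*.*$", "\\1", entries)
  vals <- sub("^- \\*\\*[^*]+\\*\\*:? *", "", entries)
  names(vals) <- keys
  if (is.null(term)) return(vals)
  hit <- grepl(term, keys, ignore.case = TRUE)
  if (!any(hit)) stop("no definition found for '", term, "'", call. = FALSE)
  vals[hit]
}
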