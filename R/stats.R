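#' @title Diagnostic-accuracy scoring and the exact Wilcoxon test
#' @description Accuracy tables for paired control/test study records
#'   ("n/n (%)" cells with pooled margins), the Wilcoxon matched-pairs
#'   signed-rank test with an exact small-sample null distribution, paired
#'   condition comparison, and Likert summaries.
#' @name study-stats
NULL

#' Round half up
#'
#' Percent cells are rounded half-up to the printed precision (base R's
#' `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pool accuracy cells
#'
#' Component-wise sum of (correct, total) cells with the pooled percent.
#' Pooling is associative: any grouping of the same cells yields identical
#' totals. An all-zero denominator yields an undefined percent (rendered
#' "(-)" in the tables).
#'
#' @param cells list of `c(correct, total)` pairs, or a 2-column matrix.
#' @param decimals decimal places for the percent (tables print 0-2).
#' @return list with `correct`, `total`, `percent` (NA when total = 0).
#' @export
pool_row <- function(cells, decimals = 2) {
  if (is.matrix(cells)) cells <- asplit(cells, 1)
  correct <- sum(vapply(cells, function(x) as.numeric(x[1]), numeric(1)))
  total <- sum(vapply(cells, function(x) as.numeric(x[2]), numeric(1)))
  if (any(vapply(cells, function(x) x[2] < 0 || x[1] < 0 || x[1] > x[2],
                 logical(1)))) {
    stop("cells must satisfy 0 <= correct <= total", call. = FALSE)
  }
  percent <- if (total > 0) round_half_up(100 * correct / total, decimals)
    else NA_real_
  list(correct = correct, total = total, percent = percent)
}

#' Render an accuracy cell as printed in the study tables
#'
#' @param correct,total counts.
#' @param decimals decimal places for the percent.
#' @return character like `"17/25 (68)"`, with `"(-)"` for an empty
#'   denominator.
#' @export
render_cell <- function(correct, total, decimals = 2) {
  if (total == 0) return("0/0 (-)")
  pct <- round_half_up(100 * correct / total, decimals)
  paste0(correct, "/", total, " (", format(pct, trim = TRUE), ")")
}

#' Score paired study records into accuracy tables
#'
#' Primary correctness is the exact match of the full diagnosis tuple
#' (category, extent, stage, grade) against the gold label. Secondary
#' conditions are scored per diagnosis incident: one gold-standard
#' secondary condition on one patient is one incident, so a patient can
#' contribute several.
#'
#' @param records data.frame with columns `case_id`, `group` (DS3, DS4 or
#'   ISP2), `gold_label`, `control_correct`, `test_correct` (logical), and
#'   optionally `secondary_gold`, `secondary_found_control`,
#'   `secondary_found_test` (";"-separated category sets).
#' @return list with `primary` (per gold label x group counts plus pooled
#'   margins), `secondary` (per category incident counts), and `totals`.
#' @export
score_accuracy <- function(records) {
  need <- c("case_id", "group", "gold_label", "control_correct",
            "test_correct")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- c("DS3", "DS4", "ISP2")
  bad <- setdiff(unique(records$group), groups)
  if (length(bad)) {
    stop("unknown group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  present_groups <- groups[groups %in% records$group]

  labels <- sort(unique(records$gold_label))
  prim <- do.call(rbind, lapply(labels, function(lab) {
    sub <- records[records$gold_label == lab, ]
    row <- data.frame(gold_label = lab, stringsAsFactors = FALSE)
    for (g in present_groups) {
      gs <- sub[sub$group == g, ]
      row[[paste0(g, "_correct")]] <- sum(gs$control_correct)
      row[[paste0(g, "_total")]] <- nrow(gs)
    }
    row$total_correct <- sum(sub$control_correct)
    row$total_n <- nrow(sub)
    row$test_correct <- sum(sub$test_correct)
    row
  }))

  sec <- NULL
  if ("secondary_gold" %in% names(records)) {
    split_set <- function(x) {
      if (is.na(x) || x == "") character() else strsplit(x, ";")[[1]]
    }
    rows <- list()
    for (i in seq_len(nrow(records))) {
      gold <- split_set(records$secondary_gold[i])
      found_c <- split_set(records$secondary_found_control[i] %||% "")
      found_t <- split_set(records$secondary_found_test[i] %||% "")
      for (cat in gold) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = records$group[i], category = cat,
          control_found = cat %in% found_c, test_found = cat %in% found_t,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      inc <- do.call(rbind, rows)
      cats <- sort(unique(inc$category))
      sec <- do.call(rbind, lapply(cats, function(cat) {
        sub <- inc[inc$category == cat, ]
        row <- data.frame(category = cat, stringsAsFactors = FALSE)
        for (g in present_groups) {
          gs <- sub[sub$group == g, ]
          row[[paste0(g, "_correct")]] <- sum(gs$control_found)
          row[[paste0(g, "_total")]] <- nrow(gs)
        }
        row$total_correct <- sum(sub$control_found)
        row$total_n <- nrow(sub)
        row$test_correct <- sum(sub$test_found)
        row
      }))
    }
  }

  totals <- list(
    primary = pool_row(lapply(seq_len(nrow(prim)), function(i) {
      c(prim$total_correct[i], prim$total_n[i])
    })),
    secondary = if (!is.null(sec)) {
      pool_row(lapply(seq_len(nrow(sec)), function(i) {
        c(sec$total_correct[i], sec$total_n[i])
      }))
    } else NULL
  )
  list(primary = prim, secondary = sec, totals = totals)
}

#' Render an accuracy table as markdown
#'
#' Mirrors the study tables' "n/n (%)" cell syntax, including "(-)" for
#' empty denominators.
#'
#' @param tab a `primary` or `secondary` data.frame from
#'   [score_accuracy()].
#' @param decimals decimal places for percents.
#' @return character vector of markdown lines.
#' @export
render_accuracy_markdown <- function(tab, decimals = 2) {
  key <- names(tab)[1]
  groups <- sub("_correct$", "",
                grep("_correct$", names(tab), value = TRUE))
  groups <- setdiff(groups, c("total", "test"))
  header <- paste0("| ", key, " | ",
                   paste(groups, collapse = " | "), " | Total |")
  sep <- paste(rep("|---", length(groups) + 2), collapse = "")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    cells <- vapply(groups, function(g) {
      render_cell(tab[[paste0(g, "_correct")]][i],
                  tab[[paste0(g, "_total")]][i], decimals)
    }, character(1))
    paste0("| ", tab[[key]][i], " | ", paste(cells, collapse = " | "),
           " | ", render_cell(tab$total_correct[i], tab$total_n[i],
                              decimals), " |")
  }, character(1))
  c(header, paste0(sep, "|"), rows)
}

# exact signed-rank machinery ---------------------------------------------------

.signrank_cache <- new.env(parent = emptyenv())

# exact null distribution of W+ for n untied ranks, by the shift/convolution
# algorithm: P(W+ = w) for w in 0..n(n+1)/2
signrank_null_distribution <- function(n) {
  key <- as.character(n)
  hit <- .signrank_cache[[key]]
  if (!is.null(hit)) return(hit)
  counts <- 1
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)
    counts <- c(counts, rep(0, k)) + shifted
  }
  probs <- counts / 2^n
  .signrank_cache[[key]] <- probs
  probs
}

# two-sided exact p-values indexed by W+ (p[w + 1]); doubled tail, capped at 1
signrank_pvalue_table <- function(n) {
  key <- paste0("p", n)
  hit <- .signrank_cache[[key]]
  if (!is.null(hit)) return(hit)
  probs <- signrank_null_distribution(n)
  lower <- cumsum(probs)
  upper <- rev(cumsum(rev(probs)))
  ptab <- pmin(1, 2 * pmin(lower, upper))
  .signrank_cache[[key]] <- ptab
  ptab
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped before ranking. For n <= `exact_max`
#' non-zero differences without ties in |d|, the p-value comes from the
#' exact null distribution of W+ (sum of ranks of positive differences),
#' computed by convolution over sign assignments; the two-sided p is the
#' doubled smaller tail, capped at 1. With ties or larger n, mid-ranks with
#' the normal approximation (tie-corrected variance, continuity
#' correction) are used. All differences zero is a degenerate input and
#' returns p = 1 with `degenerate = TRUE`.
#'
#' @param d numeric vector of paired differences.
#' @param alternative only "two.sided" is supported.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `statistic` (W+), `p_value`, `n` (non-zero
#'   differences), `exact`, `degenerate`, `method`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "two.sided",
                                 exact_max = 25L) {
  stopifnot(identical(alternative, "two.sided"))
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE,
                degenerate = TRUE,
                method = "degenerate (all differences zero)"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exact_max) {
    ptab <- signrank_pvalue_table(n)
    return(list(statistic = W, p_value = ptab[W + 1L], n = n, exact = TRUE,
                degenerate = FALSE, method = "exact signed-rank"))
  }
  mu <- n * (n + 1) / 4
  tie_table <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_table^3 - tie_table) / 48
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p_value = p, n = n, exact = FALSE,
       degenerate = FALSE,
       method = "normal approximation with tie correction")
}

#' Compare control and test conditions on paired accuracy scores
#'
#' Runs the two-sided Wilcoxon matched-pairs signed-rank test on
#' per-participant accuracy pairs at the given significance level, and
#' reports means with standard errors in each condition.
#'
#' @param control,test numeric vectors of per-participant accuracy (same
#'   length, paired by position).
#' @param alpha significance level (default 0.01, two-tailed).
#' @return list with `mean_control`, `sem_control`, `mean_test`,
#'   `sem_test`, `statistic`, `p_value`, `reject`, `direction`.
#' @export
compare_conditions <- function(control, test, alpha = 0.01) {
  if (length(control) != length(test)) {
    stop("control and test must be paired vectors of equal length",
         call. = FALSE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- wilcoxon_signed_rank(test - control)
  reject <- !res$degenerate && res$p_value < alpha
  list(mean_control = mean(control), sem_control = sem(control),
       mean_test = mean(test), sem_test = sem(test),
       statistic = res$statistic, p_value = res$p_value,
       n = length(control), reject = reject,
       direction = if (mean(test) > mean(control)) "test > control"
         else if (mean(test) < mean(control)) "test < control" else "none")
}

#' Summarize Likert scores
#'
#' @param scores integer scores (1-5).
#' @param group optional grouping factor.
#' @return data.frame with group, mean, min, max and a formatted
#'   "mean (range min-max)" string.
#' @export
summarize_likert <- function(scores, group = NULL) {
  if (is.null(group)) group <- rep("all", length(scores))
  out <- do.call(rbind, lapply(split(scores, group), function(x) {
    data.frame(mean = mean(x), min = min(x), max = max(x))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out$formatted <- sprintf("%.2f (range %d-%d)", out$mean, out$min,
                           out$max)
  out[, c("group", "mean", "min", "max", "formatted")]
}
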