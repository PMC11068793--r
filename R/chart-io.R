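#' @title Chart file I/O
#' @description Readers and writers for the two chart file dialects: a JSON
#'   dialect (normatively described by `inst/extdata/chart-schema.json`) and
#'   a flat CSV dialect with one row per site plus one row per tooth and one
#'   row per profile field. Both readers validate strictly: unknown fields
#'   and invalid enum values are rejected with the offending tooth/site/row
#'   named in the error.
#' @name chart-io
NULL

.CHART_KEYS <- c("chart_id", "exam_date", "profile", "teeth")
.TOOTH_KEYS <- c("tooth_number", "present", "is_implant", "bone_loss_percent",
                 "furcation_class", "mobility_class", "flags", "sites")
.SITE_KEYS <- c("site", "pd", "rec", "bop", "sup")
.PROFILE_KEYS <- c("age_years", "smoking_cigarettes_per_day", "has_diabetes",
                   "hba1c_percent", "systemic_disease_codes",
                   "teeth_lost_to_periodontitis",
                   "history_of_periodontal_treatment",
                   "masticatory_dysfunction")

#' Load a periodontal chart from file
#'
#' @param path file path.
#' @param dialect "json" or "csv"; defaults from the file extension.
#' @return a [periodontal_chart()].
#' @export
load_chart <- function(path, dialect = c("auto", "json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "json"
  }
  if (!file.exists(path)) stop("chart file not found: ", path, call. = FALSE)
  switch(dialect,
         json = chart_from_json(paste(readLines(path, warn = FALSE),
                                      collapse = "\n")),
         csv = .chart_from_csv(path))
}

.reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown field(s) ", paste(extra, collapse = ", "), " in ", where,
         call. = FALSE)
  }
}

#' Parse a chart from a JSON string
#'
#' @param txt JSON text in the chart dialect.
#' @return a [periodontal_chart()].
#' @export
chart_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  .reject_unknown(x, .CHART_KEYS, "chart")
  for (k in .CHART_KEYS) {
    if (is.null(x[[k]])) stop("chart is missing field '", k, "'",
                              call. = FALSE)
  }
  p <- x$profile
  .reject_unknown(p, .PROFILE_KEYS, "profile")
  profile <- patient_profile(
    age_years = p$age_years,
    smoking_cigarettes_per_day = p$smoking_cigarettes_per_day %||% 0L,
    has_diabetes = p$has_diabetes %||% FALSE,
    hba1c_percent = p$hba1c_percent %||% NA,
    systemic_disease_codes = unlist(p$systemic_disease_codes) %||% character(),
    teeth_lost_to_periodontitis = p$teeth_lost_to_periodontitis %||% 0L,
    history_of_periodontal_treatment =
      p$history_of_periodontal_treatment %||% FALSE,
    masticatory_dysfunction = p$masticatory_dysfunction %||% FALSE
  )
  nums <- vapply(x$teeth, function(t) as.integer(t$tooth_number %||% -1L),
                 integer(1))
  if (anyDuplicated(nums)) {
    stop("duplicate tooth number ",
         paste(unique(nums[duplicated(nums)]), collapse = ", "),
         " in chart '", x$chart_id, "'", call. = FALSE)
  }
  teeth <- lapply(x$teeth, function(t) {
    where <- paste0("tooth ", t$tooth_number %||% "?")
    .reject_unknown(t, .TOOTH_KEYS, where)
    sites <- lapply(seq_along(t$sites %||% list()), function(i) {
      s <- t$sites[[i]]
      .reject_unknown(s, .SITE_KEYS, paste0(where, " site ", i))
      site_measurement(s$site, s$pd %||% NA, s$rec %||% NA,
                       s$bop %||% FALSE, s$sup %||% FALSE)
    })
    tooth_record(t$tooth_number,
                 present = t$present %||% TRUE,
                 is_implant = t$is_implant %||% FALSE,
                 sites = sites,
                 bone_loss_percent = t$bone_loss_percent %||% NA,
                 furcation_class = t$furcation_class %||% 0L,
                 mobility_class = t$mobility_class %||% 0L,
                 flags = unlist(t$flags) %||% character())
  })
  periodontal_chart(x$chart_id, profile, teeth, x$exam_date)
}

#' Serialize a chart to canonical JSON
#'
#' Key order, tooth order (1-32) and site order (MB, B, DB, ML, L, DL) are
#' canonical, so parse -> serialize round trips are byte-stable.
#'
#' @param chart a [periodontal_chart()].
#' @param pretty pretty-print?
#' @return a JSON string.
#' @export
chart_to_json <- function(chart, pretty = TRUE) {
  stopifnot(inherits(chart, "periodontal_chart"))
  p <- chart$profile
  site_order <- match(SITE_IDS, SITE_IDS)
  teeth <- lapply(chart$teeth, function(t) {
    sites <- t$sites[order(match(vapply(t$sites, `[[`, character(1), "site"),
                                 SITE_IDS))]
    list(tooth_number = t$tooth_number, present = t$present,
         is_implant = t$is_implant,
         bone_loss_percent = t$bone_loss_percent,
         furcation_class = t$furcation_class,
         mobility_class = t$mobility_class,
         flags = as.list(t$flags),
         sites = lapply(sites, function(s) {
           list(site = s$site, pd = s$pd, rec = s$rec, bop = s$bop,
                sup = s$sup)
         }))
  })
  names(teeth) <- NULL
  obj <- list(
    chart_id = chart$chart_id,
    exam_date = chart$exam_date,
    profile = list(
      age_years = p$age_years,
      smoking_cigarettes_per_day = p$smoking_cigarettes_per_day,
      has_diabetes = p$has_diabetes,
      hba1c_percent = p$hba1c_percent,
      systemic_disease_codes = as.list(p$systemic_disease_codes),
      teeth_lost_to_periodontitis = p$teeth_lost_to_periodontitis,
      history_of_periodontal_treatment = p$history_of_periodontal_treatment,
      masticatory_dysfunction = p$masticatory_dysfunction
    ),
    teeth = teeth
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                   pretty = pretty, digits = NA)
}

#' Write a chart to a JSON file
#' @param chart a [periodontal_chart()].
#' @param path output path.
#' @export
write_chart <- function(chart, path) {
  writeLines(chart_to_json(chart), path)
  invisible(path)
}

# CSV dialect ------------------------------------------------------------------
# one file per chart; columns: chart_id, row_type (profile|tooth|site), tooth,
# site, pd, rec, bop, sup, present, is_implant, bone_loss_percent,
# furcation_class, mobility_class, flags (';'-separated), field, value.
# profile rows use field/value pairs; tooth rows carry tooth-level fields;
# site rows carry the per-site measurements.

.chart_from_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("chart_id", "row_type")
  if (!all(need %in% names(df))) {
    stop("CSV chart must have columns chart_id and row_type", call. = FALSE)
  }
  chart_id <- unique(df$chart_id)
  if (length(chart_id) != 1L) {
    stop("CSV chart file must describe exactly one chart_id, found: ",
         paste(chart_id, collapse = ", "), call. = FALSE)
  }
  num <- function(x) if (is.null(x) || is.na(x) || x == "") NA else
    as.numeric(x)
  lgl <- function(x) isTRUE(tolower(x) %in% c("true", "1", "t", "yes"))

  prof_rows <- df[df$row_type == "profile", , drop = FALSE]
  pr <- stats::setNames(as.list(prof_rows$value), prof_rows$field)
  bad <- setdiff(names(pr), .PROFILE_KEYS)
  if (length(bad)) {
    stop("unknown profile field(s) in CSV: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(pr$age_years)) stop("CSV profile lacks age_years",
                                  call. = FALSE)
  profile <- patient_profile(
    age_years = num(pr$age_years),
    smoking_cigarettes_per_day = num(pr$smoking_cigarettes_per_day) %|NA|% 0,
    has_diabetes = lgl(pr$has_diabetes %||% "false"),
    hba1c_percent = num(pr$hba1c_percent),
    systemic_disease_codes = if (is.null(pr$systemic_disease_codes) ||
                                 pr$systemic_disease_codes == "") character()
      else strsplit(pr$systemic_disease_codes, ";")[[1]],
    teeth_lost_to_periodontitis = num(pr$teeth_lost_to_periodontitis) %|NA|% 0,
    history_of_periodontal_treatment =
      lgl(pr$history_of_periodontal_treatment %||% "false"),
    masticatory_dysfunction = lgl(pr$masticatory_dysfunction %||% "false")
  )

  tooth_rows <- df[df$row_type == "tooth", , drop = FALSE]
  site_rows <- df[df$row_type == "site", , drop = FALSE]
  if (anyDuplicated(tooth_rows$tooth)) {
    stop("duplicate tooth row(s) in CSV: ",
         paste(unique(tooth_rows$tooth[duplicated(tooth_rows$tooth)]),
               collapse = ", "), call. = FALSE)
  }
  teeth <- lapply(seq_len(nrow(tooth_rows)), function(i) {
    tr <- tooth_rows[i, ]
    tn <- as.integer(tr$tooth)
    srows <- site_rows[site_rows$tooth == tr$tooth, , drop = FALSE]
    sites <- lapply(seq_len(nrow(srows)), function(j) {
      sr <- srows[j, ]
      if (!(sr$site %in% SITE_IDS)) {
        stop("invalid site label '", sr$site, "' in CSV row for tooth ",
             sr$tooth, call. = FALSE)
      }
      site_measurement(sr$site, num(sr$pd), num(sr$rec) %|NA|% 0,
                       lgl(sr$bop), lgl(sr$sup))
    })
    tooth_record(tn,
                 present = lgl(tr$present %||% "true"),
                 is_implant = lgl(tr$is_implant),
                 sites = sites,
                 bone_loss_percent = num(tr$bone_loss_percent),
                 furcation_class = num(tr$furcation_class) %|NA|% 0,
                 mobility_class = num(tr$mobility_class) %|NA|% 0,
                 flags = if (is.na(tr$flags) || tr$flags == "") character()
                   else strsplit(tr$flags, ";")[[1]])
  })
  periodontal_chart(chart_id, profile, teeth,
                    exam_date = Sys.Date())
}

#' Serialize a chart to the flat CSV dialect
#'
#' @param chart a [periodontal_chart()].
#' @return a data.frame in the CSV dialect (write with [utils::write.csv()]
#'   using `row.names = FALSE`).
#' @export
chart_to_csv <- function(chart) {
  stopifnot(inherits(chart, "periodontal_chart"))
  p <- chart$profile
  blank <- function(n) rep("", n)
  prof_fields <- c(
    age_years = p$age_years,
    smoking_cigarettes_per_day = p$smoking_cigarettes_per_day,
    has_diabetes = tolower(p$has_diabetes),
    hba1c_percent = if (is.na(p$hba1c_percent)) "" else p$hba1c_percent,
    systemic_disease_codes = paste(p$systemic_disease_codes, collapse = ";"),
    teeth_lost_to_periodontitis = p$teeth_lost_to_periodontitis,
    history_of_periodontal_treatment =
      tolower(p$history_of_periodontal_treatment),
    masticatory_dysfunction = tolower(p$masticatory_dysfunction)
  )
  rows <- list(data.frame(
    chart_id = chart$chart_id, row_type = "profile", tooth = "", site = "",
    pd = "", rec = "", bop = "", sup = "", present = "", is_implant = "",
    bone_loss_percent = "", furcation_class = "", mobility_class = "",
    flags = "", field = names(prof_fields),
    value = as.character(prof_fields), stringsAsFactors = FALSE))
  for (t in chart$teeth) {
    rows[[length(rows) + 1L]] <- data.frame(
      chart_id = chart$chart_id, row_type = "tooth",
      tooth = t$tooth_number, site = "", pd = "", rec = "", bop = "",
      sup = "", present = tolower(t$present),
      is_implant = tolower(t$is_implant),
      bone_loss_percent = if (is.na(t$bone_loss_percent)) "" else
        t$bone_loss_percent,
      furcation_class = t$furcation_class,
      mobility_class = t$mobility_class,
      flags = paste(t$flags, collapse = ";"), field = "", value = "",
      stringsAsFactors = FALSE)
    for (s in t$sites) {
      rows[[length(rows) + 1L]] <- data.frame(
        chart_id = chart$chart_id, row_type = "site",
        tooth = t$tooth_number, site = s$site,
        pd = if (is.na(s$pd)) "" else s$pd,
        rec = if (is.na(s$rec)) "" else s$rec,
        bop = tolower(s$bop), sup = tolower(s$sup), present = "",
        is_implant = "", bone_loss_percent = "", furcation_class = "",
        mobility_class = "", flags = "", field = "", value = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# NULL/empty coalescing: JSON nulls can round-trip as empty lists
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a
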