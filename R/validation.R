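#' Validation findings
#'
#' All validation operations collect findings as data, never as thrown
#' conditions: a finding frame is an ordinary `data.frame` (class
#' `mwtab_issues`) with one row per issue and columns `severity`
#' (`"error"` or `"warning"`), `code` (a stable machine token), `section`,
#' `key`, `line` and `message`.
#'
#' The closed set of issue codes:
#' \describe{
#'   \item{MISSING_REQUIRED_FIELD}{a schema-required key is absent (error).}
#'   \item{CONSTRAINT_VIOLATION}{a value fails its schema rule, e.g. a
#'     malformed EMAIL or PHONE (error).}
#'   \item{UNKNOWN_KEY}{a key in neither the required nor the optional
#'     set (warning).}
#'   \item{MISSING_END}{no terminating `#END` marker (error).}
#'   \item{LEADING_CONTENT}{blank lines or content precede the
#'     `#METABOLOMICS WORKBENCH` header (warning).}
#'   \item{EMPTY_UNITS}{a results data table with an empty mandatory
#'     units field (error).}
#'   \item{SSF_MALFORMED}{a structurally bad subject-sample-factor
#'     record, e.g. empty sample id or duplicated factor names (error).}
#'   \item{COLUMN_MISMATCH}{sample-column count differs from the
#'     SUBJECT_SAMPLE_FACTORS record count (warning).}
#'   \item{ROW_ARITY}{a table row whose cell count differs from the
#'     header (error).}
#'   \item{ID_MISMATCH}{the header ANALYSIS_ID conflicts with the id
#'     embedded in the source address (warning).}
#'   \item{ORPHAN_ITEM}{an item outside any section, attached to the
#'     synthetic UNATTRIBUTED section (error).}
#'   \item{TABLE_WITHOUT_END}{a table not closed by its `*_END` sentinel
#'     (error).}
#'   \item{POST_END_CONTENT}{content after `#END` (warning).}
#'   \item{MULTIPLE_RESULTS}{more than one MS/NMR results data table in
#'     one file (error).}
#' }
#'
#' @name mwtab_issues
NULL

ISSUE_CODES <- c(
  "MISSING_REQUIRED_FIELD", "CONSTRAINT_VIOLATION", "UNKNOWN_KEY",
  "MISSING_END", "LEADING_CONTENT", "EMPTY_UNITS", "SSF_MALFORMED",
  "COLUMN_MISMATCH", "ROW_ARITY", "ID_MISMATCH", "ORPHAN_ITEM",
  "TABLE_WITHOUT_END", "POST_END_CONTENT", "MULTIPLE_RESULTS"
)

empty_issues <- function() {
  structure(
    data.frame(severity = character(), code = character(),
               section = character(), key = character(),
               line = integer(), message = character(),
               stringsAsFactors = FALSE),
    class = c("mwtab_issues", "data.frame")
  )
}

add_issue <- function(issues, severity, code, section = NA_character_,
                      key = NA_character_, line = NA_integer_, message) {
  stopifnot(code %in% ISSUE_CODES, severity %in% c("error", "warning"),
            is_string(message), nzchar(message))
  row <- data.frame(severity = severity, code = code,
                    section = as.character(section), key = as.character(key),
                    line = as.integer(line), message = message,
                    stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(issues), row),
            class = c("mwtab_issues", "data.frame"))
}

bind_issues <- function(...) {
  parts <- list(...)
  structure(do.call(rbind, lapply(parts, as.data.frame)),
            class = c("mwtab_issues", "data.frame"))
}

#' @export
print.mwtab_issues <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No validation findings.\n")
    return(invisible(x))
  }
  cat(nrow(x), "validation finding(s):\n")
  for (i in seq_len(nrow(x))) {
    loc <- x$section[[i]]
    if (!is.na(x$key[[i]])) loc <- paste0(loc, "/", x$key[[i]])
    cat(sprintf("  [%s] %s (%s): %s\n", x$severity[[i]], x$code[[i]],
                if (is.na(loc)) "file" else loc, x$message[[i]]))
  }
  invisible(x)
}

#' Define a per-block schema
#'
#' @param section section name the schema applies to.
#' @param required,optional disjoint sets of key names.
#' @param value_rules named list of constraints, one per key: either a
#'   list `list(regex = <pattern>)`, `list(enum = <values>)`, or `NULL`
#'   (free text).
#' @return an object of class `mwtab_schema`.
#' @export
schema_definition <- function(section, required = character(),
                              optional = character(), value_rules = list()) {
  required <- as.character(required)
  optional <- as.character(optional)
  overlap <- intersect(required, optional)
  if (length(overlap)) {
    stop_mwtab("SCHEMA_LOAD_ERROR",
               paste0("schema for '", section, "': keys both required and optional: ",
                      paste(overlap, collapse = ", ")))
  }
  structure(list(section = section, required = required, optional = optional,
                 value_rules = value_rules),
            class = "mwtab_schema")
}

# regexes are schema data, deliberately permissive: deposited metadata
# is free text and the goal is to catch category errors, not to enforce
# RFC addresses
EMAIL_REGEX <- "^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$"
PHONE_REGEX <- "^[0-9+() .-]{7,}$"

project_schema <- function() {
  schema_definition(
    "PROJECT",
    required = c("PROJECT_TITLE", "PROJECT_SUMMARY", "INSTITUTE", "LAST_NAME",
                 "FIRST_NAME", "ADDRESS", "EMAIL", "PHONE"),
    optional = c("PROJECT_TYPE", "DEPARTMENT", "LABORATORY", "FUNDING_SOURCE",
                 "PROJECT_COMMENTS", "PUBLICATIONS", "CONTRIBUTIONS", "DOI"),
    value_rules = list(EMAIL = list(regex = EMAIL_REGEX),
                       PHONE = list(regex = PHONE_REGEX))
  )
}

#' Default per-block schema definitions
#'
#' Returns the schema set used by [validate_document()]: the PROJECT
#' block schema (eight required and eight optional fields, with regex
#' constraints on EMAIL and PHONE) is built in; schemas for the
#' remaining blocks are loaded from the bundled, user-replaceable schema
#' file (`inst/extdata/mwtab_schema.json`). A user file given via
#' `schema_file` is merged on top and may override any block, e.g. to
#' promote an optional key to required.
#'
#' @param schema_file optional path to a JSON schema file in the same
#'   dialect as the bundled one: an object of
#'   `"SECTION": {"required": [...], "optional": [...],
#'   "rules": {"KEY": {"regex": ...}}}` entries.
#' @return named list of [schema_definition()]s.
#' @export
#' @examples
#' sort(default_schemas()$PROJECT$required)
default_schemas <- function(schema_file = NULL) {
  schemas <- list(PROJECT = project_schema())
  bundled <- system.file("extdata", "mwtab_schema.json", package = "mwtabr")
  if (nzchar(bundled)) {
    schemas <- merge_schema_file(schemas, bundled)
  }
  if (!is.null(schema_file)) {
    if (!file.exists(schema_file)) {
      stop_mwtab("SCHEMA_LOAD_ERROR", paste0("schema file not found: ", schema_file))
    }
    schemas <- merge_schema_file(schemas, schema_file)
  }
  schemas
}

merge_schema_file <- function(schemas, path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_mwtab("SCHEMA_LOAD_ERROR",
                 paste0("cannot parse schema file '", path, "': ", conditionMessage(e)))
    }
  )
  if (!is.list(raw) || is.null(names(raw))) {
    stop_mwtab("SCHEMA_LOAD_ERROR",
               paste0("schema file '", path, "' must contain one object per section"))
  }
  for (name in names(raw)) {
    node <- raw[[name]]
    if (!is.list(node)) {
      stop_mwtab("SCHEMA_LOAD_ERROR",
                 paste0("schema entry '", name, "' in '", path, "' is not an object"))
    }
    rules <- lapply(node$rules %||% list(), function(r) {
      list(regex = r$regex %||% NULL,
           enum = if (is.null(r$enum)) NULL else vapply(r$enum, as.character, ""))
    })
    schemas[[name]] <- schema_definition(
      name,
      required = vapply(node$required %||% list(), as.character, ""),
      optional = vapply(node$optional %||% list(), as.character, ""),
      value_rules = rules
    )
  }
  schemas
}

#' Validate one section against its schema
#'
#' Emits one MISSING_REQUIRED_FIELD error per absent required key (in
#' schema order), then walks the section's keys in file order emitting
#' CONSTRAINT_VIOLATION errors for values failing their rule and
#' UNKNOWN_KEY warnings for keys in neither set. Never fail-fast:
#' findings are data.
#'
#' @param sec an [section()].
#' @param schema the matching [schema_definition()].
#' @return an ordered `mwtab_issues` frame.
#' @export
validate_section <- function(sec, schema) {
  stopifnot(inherits(sec, "mwtab_section"), inherits(schema, "mwtab_schema"))
  if (!identical(sec$name, schema$section)) {
    stop_mwtab("SCHEMA_MISMATCH",
               paste0("schema for '", schema$section, "' applied to section '",
                      sec$name, "'"))
  }
  issues <- empty_issues()
  present <- names(sec$items)
  for (key in schema$required) {
    if (!key %in% present) {
      issues <- add_issue(issues, "error", "MISSING_REQUIRED_FIELD",
        section = sec$name, key = key,
        message = paste0("section '", sec$name, "' is missing the required field '",
                         key, "'"))
    }
  }
  known <- c(schema$required, schema$optional)
  for (key in present) {
    rule <- schema$value_rules[[key]]
    value <- sec$items[[key]]
    if (!is.null(rule)) {
      ok <- TRUE
      if (!is.null(rule$regex)) ok <- grepl(rule$regex, value)
      if (ok && !is.null(rule$enum)) ok <- value %in% rule$enum
      if (!ok) {
        issues <- add_issue(issues, "error", "CONSTRAINT_VIOLATION",
          section = sec$name, key = key,
          message = paste0("value of '", key, "' in section '", sec$name,
                           "' does not satisfy its format constraint: '", value, "'"))
      }
    }
    if (!key %in% known) {
      issues <- add_issue(issues, "warning", "UNKNOWN_KEY",
        section = sec$name, key = key,
        message = paste0("key '", key, "' in section '", sec$name,
                         "' is neither required nor optional in the schema"))
    }
  }
  issues
}

#' Validate a whole document
#'
#' Combines file-level checks (MISSING_END, the parse-time findings such
#' as LEADING_CONTENT or TABLE_WITHOUT_END), per-section schema
#' validation, structural checks on factor records and data-table units,
#' and the cross-block consistency checks of [check_consistency()].
#' Validating the same document twice yields identical ordered findings.
#'
#' @param doc an [mwtab_document()].
#' @param schemas schema set from [default_schemas()].
#' @return an ordered `mwtab_issues` frame.
#' @export
#' @examples
#' doc <- generate_document(fixture_spec(seed = 3))$document
#' nrow(validate_document(doc))  # pristine fixture: 0 findings
validate_document <- function(doc, schemas = default_schemas()) {
  stopifnot(inherits(doc, "mwtab_document"))
  issues <- doc$findings
  if (!doc$end_marker) {
    issues <- add_issue(issues, "error", "MISSING_END",
      message = "file is missing the '#END' marker that signals the end of the file")
  }
  n_results <- 0L
  for (sec in doc$sections) {
    if (!is.null(schemas[[sec$name]])) {
      issues <- bind_issues(issues, validate_section(sec, schemas[[sec$name]]))
    }
    for (j in seq_along(sec$ssf_records)) {
      rec <- sec$ssf_records[[j]]
      bad <- character()
      if (!nzchar(rec$local_sample_id)) bad <- c(bad, "empty sample id")
      if (anyDuplicated(names(rec$factors))) bad <- c(bad, "duplicated factor names")
      if (length(bad)) {
        issues <- add_issue(issues, "error", "SSF_MALFORMED",
          section = sec$name, key = rec$local_sample_id, line = NA_integer_,
          message = sprintf("sample record %d is malformed: %s", j,
                            paste(bad, collapse = "; ")))
      }
    }
    dt <- sec$data_table
    if (!is.null(dt) && dt$kind %in% RESULTS_KINDS) {
      n_results <- n_results + 1L
      if (!nzchar(dt$units)) {
        issues <- add_issue(issues, "error", "EMPTY_UNITS",
          section = sec$name,
          message = paste0("mandatory units field of the ", dt$kind,
                           " table is empty"))
      }
    }
  }
  if (n_results > 1L) {
    issues <- add_issue(issues, "error", "MULTIPLE_RESULTS",
      message = sprintf("document holds %d MS/NMR results tables; at most one is allowed",
                        n_results))
  }
  bind_issues(issues, check_consistency(doc))
}

#' Cross-block consistency checks
#'
#' Checks consistency within one file: the results table's sample-column
#' count against the SUBJECT_SAMPLE_FACTORS record count
#' (COLUMN_MISMATCH), per-row cell arity against the table header
#' (ROW_ARITY), and the header ANALYSIS_ID against an `AN<digits>` id
#' embedded in the source address (ID_MISMATCH).
#'
#' @param doc an [mwtab_document()].
#' @return an ordered `mwtab_issues` frame.
#' @export
check_consistency <- function(doc) {
  stopifnot(inherits(doc, "mwtab_document"))
  issues <- empty_issues()
  n_ssf <- 0L
  for (sec in doc$sections) n_ssf <- n_ssf + length(sec$ssf_records)
  for (sec in doc$sections) {
    dt <- sec$data_table
    if (is.null(dt)) next
    bad <- which(vapply(dt$rows, length, 0L) != length(dt$column_names))
    for (j in bad) {
      issues <- add_issue(issues, "error", "ROW_ARITY",
        section = sec$name, key = dt$feature_ids[[j]],
        message = sprintf("row '%s' has %d values but the table declares %d columns",
                          dt$feature_ids[[j]], length(dt$rows[[j]]),
                          length(dt$column_names)))
    }
    if (dt$kind %in% RESULTS_KINDS && n_ssf > 0L &&
        length(dt$column_names) != n_ssf) {
      issues <- add_issue(issues, "warning", "COLUMN_MISMATCH",
        section = sec$name,
        message = sprintf(
          "data table has %d sample columns but SUBJECT_SAMPLE_FACTORS lists %d samples",
          length(dt$column_names), n_ssf))
    }
  }
  an <- doc$header$analysis_id
  src <- regmatches(doc$source_id, regexpr("AN[0-9]+", doc$source_id))
  if (nzchar(an) && length(src) == 1L && !identical(an, src)) {
    issues <- add_issue(issues, "warning", "ID_MISMATCH",
      section = HEADER_SECTION, key = "ANALYSIS_ID",
      message = paste0("header ANALYSIS_ID '", an,
                       "' conflicts with the id embedded in the source address '",
                       src, "'"))
  }
  issues
}

#' Survey the units fields of a document collection
#'
#' Tallies the mandatory units value of every MS/NMR results table
#' across a collection of documents -- the kind of repository-wide audit
#' that exposes both missing units and case variants of the same unit
#' (e.g. "Peak height" vs "peak height"). With `normalization =
#' "case-folded"` such variants merge into one tally entry (keyed by the
#' lower-cased form).
#'
#' @param docs a list of [mwtab_document()]s (or a [read_files()]
#'   reader, which is drained).
#' @param normalization `"verbatim"` or `"case-folded"`.
#' @return an object of class `mwtab_units_survey`: a list with `tally`
#'   (named integer, decreasing), `missing_count`, `normalization` and
#'   `n_tables`; tally counts plus `missing_count` always sum to
#'   `n_tables`.
#' @export
survey_units <- function(docs, normalization = c("verbatim", "case-folded")) {
  normalization <- match.arg(normalization)
  if (inherits(docs, "mwtab_reader")) docs <- read_all(docs)
  units <- character()
  for (doc in docs) {
    if (!inherits(doc, "mwtab_document")) next
    for (dt in results_tables(doc)) {
      units[[length(units) + 1L]] <- dt$units
    }
  }
  missing <- sum(!nzchar(units))
  present <- units[nzchar(units)]
  keys <- if (normalization == "case-folded") tolower(present) else present
  tally <- if (length(keys)) {
    t <- table(keys)
    sort(stats::setNames(as.integer(t), names(t)), decreasing = TRUE)
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(tally = tally, missing_count = missing,
                 normalization = normalization, n_tables = length(units)),
            class = "mwtab_units_survey")
}

#' @export
print.mwtab_units_survey <- function(x, ...) {
  cat("Units survey (", x$normalization, ") across ", x$n_tables,
      " data table(s):\n", sep = "")
  cat("  missing units:", x$missing_count, "\n")
  for (u in names(x$tally)) cat(sprintf("  %-24s %d\n", u, x$tally[[u]]))
  invisible(x)
}
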