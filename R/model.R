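#' @title The mwTab document model
#' @description Ordered, nested in-memory representation of one analysis
#'   file. A document holds the `METABOLOMICS WORKBENCH` header fields
#'   (also exposed as a pseudo-section for uniform key-based access) and
#'   an ordered collection of sections, each of which carries key-value
#'   items, subject-sample-factor records, or a feature-by-sample data
#'   table. The document is the single source of truth for both the
#'   mwTab and the JSON serialization.
#' @name mwtab_document
NULL

# section name -> two-letter key prefix used in the flat file
SECTION_PREFIX <- c(
  PROJECT = "PR", STUDY = "ST", SUBJECT = "SU", COLLECTION = "CO",
  TREATMENT = "TR", SAMPLEPREP = "SP", CHROMATOGRAPHY = "CH",
  ANALYSIS = "AN", MS = "MS", NMR = "NM"
)

HEADER_SECTION <- "METABOLOMICS WORKBENCH"
SSF_SECTION <- "SUBJECT_SAMPLE_FACTORS"
RESULTS_KINDS <- c("MS_METABOLITE_DATA", "NMR_BINNED_DATA")
TABLE_KINDS <- c("MS_METABOLITE_DATA", "NMR_BINNED_DATA", "METABOLITES", "EXTENDED")

table_kind_for <- function(name) {
  if (name %in% c("MS_METABOLITE_DATA", "NMR_BINNED_DATA", "METABOLITES")) name
  else "EXTENDED"
}

#' Construct a header-info record
#'
#' The distinguished fields of the `#METABOLOMICS WORKBENCH` header line
#' and its adjacent items. A study id groups one or more analyses;
#' the analysis id is unique per file.
#'
#' @param version,created_on,study_id,analysis_id character scalars
#'   (empty string when absent).
#' @return an object of class `mwtab_header`.
#' @export
header_info <- function(version = "", created_on = "", study_id = "",
                        analysis_id = "") {
  h <- list(version = as.character(version), created_on = as.character(created_on),
            study_id = as.character(study_id), analysis_id = as.character(analysis_id))
  if (nzchar(h$study_id) && !grepl("^ST[0-9]+$", h$study_id)) {
    stop_mwtab("INVALID_ID", paste0("study id must match ST<digits>: '", h$study_id, "'"))
  }
  if (nzchar(h$analysis_id) && !grepl("^AN[0-9]+$", h$analysis_id)) {
    stop_mwtab("INVALID_ID", paste0("analysis id must match AN<digits>: '", h$analysis_id, "'"))
  }
  structure(h, class = "mwtab_header")
}

#' Construct a subject-sample-factor record
#'
#' One row of the SUBJECT_SAMPLE_FACTORS block: it maps a local sample id
#' to its subject and experimental factor values.
#'
#' @param subject_type subject descriptor (often `-` in deposited files).
#' @param local_sample_id sample identifier; non-empty in well-formed
#'   records (the validator reports empty ids as `SSF_MALFORMED`).
#' @param factors ordered named character vector of factor name -> value.
#' @param additional_data ordered named character vector of extra
#'   per-sample key -> value pairs (possibly empty).
#' @return an object of class `mwtab_ssf_record`.
#' @export
ssf_record <- function(subject_type = "-", local_sample_id = "",
                       factors = character(), additional_data = character()) {
  # an empty subject field would shift the tab-separated row layout, so
  # the conventional '-' placeholder is substituted
  if (!nzchar(subject_type)) subject_type <- "-"
  structure(
    list(
      subject_type = as.character(subject_type),
      local_sample_id = as.character(local_sample_id),
      factors = named_chr(factors, names(factors) %||% character()),
      additional_data = named_chr(additional_data, names(additional_data) %||% character())
    ),
    class = "mwtab_ssf_record"
  )
}

#' Construct a feature-by-sample data table
#'
#' Holds the measured-value matrices of the results blocks
#' (`MS_METABOLITE_DATA`, `NMR_BINNED_DATA`), the metabolite metadata
#' table (`METABOLITES`) or an extended-data table. All cells are stored
#' verbatim as text -- numeric interpretation is the consumer's job -- and
#' an empty cell is the empty string.
#'
#' @param kind one of `MS_METABOLITE_DATA`, `NMR_BINNED_DATA`,
#'   `METABOLITES`, `EXTENDED`.
#' @param units units string of the measured values; may be empty
#'   (= missing, which the validator reports).
#' @param column_names ordered sample (or metadata-column) labels.
#' @param factor_row optional ordered factor labels aligned to
#'   `column_names`.
#' @param feature_ids ordered feature identifiers (metabolite names or
#'   bin ranges), one per row.
#' @param rows list of character vectors, one per feature, aligned to
#'   `column_names`.
#' @param check validate row arity (every row's cell count equals the
#'   column count). The parser disables this to keep corrupt files
#'   loadable; such rows surface as `ROW_ARITY` validation findings.
#' @return an object of class `mwtab_data_table`.
#' @export
data_table <- function(kind, units = "", column_names = character(),
                       factor_row = NULL, feature_ids = character(),
                       rows = list(), check = TRUE) {
  kind <- match.arg(kind, TABLE_KINDS)
  stopifnot(length(feature_ids) == length(rows))
  rows <- lapply(rows, as.character)
  if (check) {
    bad <- which(vapply(rows, length, 0L) != length(column_names))
    if (length(bad)) {
      stop_mwtab("ROW_ARITY", sprintf(
        "row %d ('%s') has %d values but the table declares %d columns",
        bad[[1]], feature_ids[[bad[[1]]]], length(rows[[bad[[1]]]]), length(column_names)
      ))
    }
    if (!is.null(factor_row) && length(factor_row) != length(column_names)) {
      stop_mwtab("ROW_ARITY", "factor row length differs from the column count")
    }
  }
  structure(
    list(kind = kind, units = as.character(units),
         column_names = as.character(column_names),
         factor_row = if (is.null(factor_row)) NULL else as.character(factor_row),
         feature_ids = as.character(feature_ids), rows = rows),
    class = "mwtab_data_table"
  )
}

#' Construct a section
#'
#' One `#NAME` delimited text block. A section carries ordered key-value
#' items and, depending on its name, subject-sample-factor records or a
#' data table -- never both (structural exclusivity).
#'
#' @param name non-empty uppercase section name (underscores and spaces
#'   allowed).
#' @param items ordered named character vector of key -> value.
#' @param ssf_records list of [ssf_record()]s; only meaningful for the
#'   SUBJECT_SAMPLE_FACTORS section.
#' @param data_table a [data_table()] or `NULL`; only meaningful for
#'   results sections.
#' @param prefix two-letter key prefix used at serialization time;
#'   defaults to the fixed section -> prefix table.
#' @return an object of class `mwtab_section`.
#' @export
section <- function(name, items = character(), ssf_records = list(),
                    data_table = NULL, prefix = NULL) {
  if (!is_string(name) || !nzchar(name) || grepl("[a-z]", name)) {
    stop_mwtab("INVALID_SECTION_NAME",
               paste0("section name must be a non-empty uppercase token: '", name, "'"))
  }
  if (length(ssf_records) && !is.null(data_table)) {
    stop_mwtab("STRUCTURAL_EXCLUSIVITY",
               paste0("section '", name, "' cannot hold both factor records and a data table"))
  }
  if (length(ssf_records) && name != SSF_SECTION) {
    stop_mwtab("STRUCTURAL_EXCLUSIVITY",
               paste0("factor records are only valid in ", SSF_SECTION, ", not '", name, "'"))
  }
  items <- named_chr(items, names(items) %||% character())
  if (anyDuplicated(names(items))) {
    stop_mwtab("DUPLICATE_KEY",
               paste0("duplicate item key in section '", name,
                      "' (continuation lines are merged at parse time)"))
  }
  structure(
    list(name = name,
         prefix = prefix %||% unname(SECTION_PREFIX[name] %||% ""),
         items = items, ssf_records = ssf_records, data_table = data_table),
    class = "mwtab_section"
  )
}

#' Construct an mwTab document
#'
#' @param sections named (by section name) ordered list of [section()]s;
#'   the `METABOLOMICS WORKBENCH` pseudo-section, when present, carries
#'   the header fields as ordinary items.
#' @param source_id provenance: the path, URL or analysis id the
#'   document came from.
#' @param findings parse-time recoverable findings (a `mwtab_issues`
#'   frame), re-reported by [validate_document()].
#' @param end_marker whether a terminating `#END` was seen (writers
#'   always emit one).
#' @return an object of class `mwtab_document`.
#' @export
mwtab_document <- function(sections = list(), source_id = "",
                           findings = NULL, end_marker = TRUE) {
  nm <- vapply(sections, function(s) s$name, "")
  names(sections) <- nm
  if (anyDuplicated(nm)) {
    stop_mwtab("DUPLICATE_SECTION", paste0("duplicate section '", nm[duplicated(nm)][1], "'"))
  }
  doc <- structure(
    list(header = NULL, sections = sections, source_id = as.character(source_id),
         findings = findings %||% empty_issues(), end_marker = isTRUE(end_marker)),
    class = "mwtab_document"
  )
  doc$header <- derive_header(doc)
  doc
}

derive_header <- function(doc) {
  hs <- doc$sections[[HEADER_SECTION]]
  it <- if (is.null(hs)) character() else hs$items
  header_info(
    version = unname(it["VERSION"] %|NA|% ""),
    created_on = unname(it["CREATED_ON"] %|NA|% ""),
    study_id = unname(it["STUDY_ID"] %|NA|% ""),
    analysis_id = unname(it["ANALYSIS_ID"] %|NA|% "")
  )
}

`%|NA|%` <- function(x, y) if (length(x) != 1L || is.na(x)) y else x

#' Names of the sections of a document, in file order
#' @param doc an [mwtab_document()].
#' @return character vector of section names.
#' @export
section_names <- function(doc) {
  stopifnot(inherits(doc, "mwtab_document"))
  names(doc$sections)
}

#' Read one item value
#'
#' Returns the stored (continuation-merged) value of `key` in `section`,
#' unmodified. The `METABOLOMICS WORKBENCH` header is addressable like
#' any other section.
#'
#' @param doc an [mwtab_document()].
#' @param section section name.
#' @param key item key (without the two-letter prefix).
#' @return the value as a character scalar.
#' @export
#' @examples
#' doc <- generate_document(fixture_spec(seed = 1))$document
#' get_value(doc, "METABOLOMICS WORKBENCH", "VERSION")
get_value <- function(doc, section, key) {
  stopifnot(inherits(doc, "mwtab_document"))
  sec <- doc$sections[[section]]
  if (is.null(sec)) {
    stop_mwtab("UNKNOWN_SECTION",
               paste0("document has no section '", section, "'"), section = section)
  }
  if (!key %in% names(sec$items)) {
    stop_mwtab("UNKNOWN_KEY",
               paste0("section '", section, "' has no key '", key, "'"),
               section = section, key = key)
  }
  unname(sec$items[[key]])
}

#' Set or add one item value
#'
#' Existing keys keep their position; new keys are appended at the
#' section tail. Returns the updated document (copy semantics, as usual
#' in R).
#'
#' @inheritParams get_value
#' @param value new value (coerced to character).
#' @return the updated [mwtab_document()].
#' @export
set_value <- function(doc, section, key, value) {
  stopifnot(inherits(doc, "mwtab_document"))
  sec <- doc$sections[[section]]
  if (is.null(sec)) {
    stop_mwtab("UNKNOWN_SECTION",
               paste0("document has no section '", section, "'"), section = section)
  }
  sec$items[[key]] <- as.character(value)
  doc$sections[[section]] <- sec
  if (identical(section, HEADER_SECTION)) doc$header <- derive_header(doc)
  doc
}

#' Sample column labels of the results data table
#'
#' Supports consistency checking: returns the column labels of the
#' MS/NMR results table in order, or an empty vector if the document has
#' no results table.
#'
#' @param doc an [mwtab_document()].
#' @return character vector of sample labels (possibly empty).
#' @export
list_sample_columns <- function(doc) {
  stopifnot(inherits(doc, "mwtab_document"))
  for (sec in doc$sections) {
    dt <- sec$data_table
    if (!is.null(dt) && dt$kind %in% RESULTS_KINDS) return(dt$column_names)
  }
  character()
}

# all results-kind data tables of a document (usually 0 or 1)
results_tables <- function(doc) {
  out <- list()
  for (sec in doc$sections) {
    dt <- sec$data_table
    if (!is.null(dt) && dt$kind %in% RESULTS_KINDS) out[[length(out) + 1L]] <- dt
  }
  out
}

#' @export
`[[.mwtab_document` <- function(x, name) {
  if (name %in% c("header", "sections", "source_id", "findings", "end_marker")) {
    return(.subset2(x, name))
  }
  sec <- .subset2(x, "sections")[[name]]
  if (is.null(sec)) {
    stop_mwtab("UNKNOWN_SECTION", paste0("document has no section '", name, "'"),
               section = name)
  }
  sec
}

#' @export
`[[<-.mwtab_document` <- function(x, name, value) {
  if (name %in% c("header", "sections", "source_id", "findings", "end_marker")) {
    y <- unclass(x)
    y[[name]] <- value
    return(structure(y, class = "mwtab_document"))
  }
  stopifnot(inherits(value, "mwtab_section"))
  y <- unclass(x)
  y$sections[[name]] <- value
  out <- structure(y, class = "mwtab_document")
  if (identical(name, HEADER_SECTION)) out$header <- derive_header(out)
  out
}

#' @export
`[[.mwtab_section` <- function(x, name) {
  if (name %in% c("name", "prefix", "items", "ssf_records", "data_table")) {
    return(.subset2(x, name))
  }
  items <- .subset2(x, "items")
  if (!name %in% names(items)) {
    stop_mwtab("UNKNOWN_KEY",
               paste0("section '", .subset2(x, "name"), "' has no key '", name, "'"),
               section = .subset2(x, "name"), key = name)
  }
  unname(items[[name]])
}

#' @export
`[[<-.mwtab_section` <- function(x, name, value) {
  y <- unclass(x)
  if (name %in% c("name", "prefix", "items", "ssf_records", "data_table")) {
    y[[name]] <- value
  } else {
    y$items[[name]] <- as.character(value)
  }
  structure(y, class = "mwtab_section")
}

#' Model equality of two documents
#'
#' Compares header fields, section order and, per section, items, factor
#' records and data tables. Provenance (`source_id`), parse findings and
#' the end-marker flag are not part of the model and are ignored.
#'
#' @param a,b [mwtab_document()]s.
#' @return `TRUE` or `FALSE`.
#' @export
doc_equal <- function(a, b) {
  identical(doc_model_repr(a), doc_model_repr(b))
}

doc_model_repr <- function(doc) {
  stopifnot(inherits(doc, "mwtab_document"))
  lapply(unname(doc$sections), function(sec) {
    list(
      name = sec$name,
      items = sec$items,
      ssf = lapply(sec$ssf_records, function(r) {
        list(r$subject_type, r$local_sample_id, r$factors, r$additional_data)
      }),
      table = if (is.null(sec$data_table)) NULL else {
        dt <- sec$data_table
        list(dt$kind, dt$units, dt$column_names, dt$factor_row,
             dt$feature_ids, dt$rows)
      }
    )
  })
}

#' @export
print.mwtab_document <- function(x, ...) {
  cat("<mwtab_document>", if (nzchar(x$source_id)) paste0(" [", x$source_id, "]"), "\n", sep = "")
  h <- x$header
  cat("  study ", if (nzchar(h$study_id)) h$study_id else "?",
      ", analysis ", if (nzchar(h$analysis_id)) h$analysis_id else "?", "\n", sep = "")
  for (sec in x$sections) {
    extra <- ""
    if (length(sec$ssf_records)) extra <- sprintf(" + %d sample records", length(sec$ssf_records))
    if (!is.null(sec$data_table)) {
      extra <- sprintf(" + %s table [%d x %d]", sec$data_table$kind,
                       length(sec$data_table$feature_ids), length(sec$data_table$column_names))
    }
    cat(sprintf("  #%s: %d items%s\n", sec$name, length(sec$items), extra))
  }
  invisible(x)
}

#' Coerce a data table to a data.frame
#'
#' Convenience accessor for downstream analysis: feature ids become the
#' first column, sample columns keep their labels, and all cells stay
#' character (values are stored verbatim).
#'
#' @param x an `mwtab_data_table`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.mwtab_data_table <- function(x, ...) {
  ok <- vapply(x$rows, length, 0L) == length(x$column_names)
  rows <- x$rows[ok]
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(), 0L, length(x$column_names))
  colnames(m) <- x$column_names
  df <- data.frame(feature_id = x$feature_ids[ok], m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
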