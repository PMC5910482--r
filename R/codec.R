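#' Build a document from a token stream
#'
#' The syntactic-analysis half of the parser: consumes the flat token
#' stream produced by [tokenize()] and assembles an [mwtab_document()].
#' Repeated item keys within a section are continuation lines and are
#' merged into one value; rows of the SUBJECT_SAMPLE_FACTORS block
#' become [ssf_record()]s; `*_START`/`*_END` delimited tables become
#' [data_table()]s, with units taken from the adjacent `<BLOCK>:UNITS`
#' item when present.
#'
#' Recoverable irregularities (content before the file header, a table
#' left open at a section boundary, items that belong to no section,
#' content after `#END`) are attached to the document as findings and
#' re-reported by [validate_document()]; only the complete absence of a
#' `#METABOLOMICS WORKBENCH` file header is fatal.
#'
#' @param tokens an `mwtab_tokens` stream.
#' @param source_id provenance string recorded on the document.
#' @param layout a [layout_policy()]; only `merge_sep` (the continuation
#'   merge separator) is consulted here.
#' @return an [mwtab_document()].
#' @export
build_document <- function(tokens, source_id = "", layout = layout_policy()) {
  kinds <- vapply(tokens, function(t) t$kind, "")
  hdr_at <- which(kinds == "FILE_HEADER")
  if (length(hdr_at) == 0L) {
    stop_mwtab("NO_FILE_HEADER",
               paste0("not an mwTab file: no '#METABOLOMICS WORKBENCH' header line",
                      if (nzchar(source_id)) paste0(" in ", source_id)))
  }
  findings <- empty_issues()
  pre <- tokens[seq_len(hdr_at[[1]] - 1L)]
  if (length(pre)) {
    what <- if (all(vapply(pre, function(t) t$kind, "") == "BLANK")) {
      sprintf("%d blank line(s) precede the file header", length(pre))
    } else {
      "content precedes the '#METABOLOMICS WORKBENCH' file header"
    }
    findings <- add_issue(findings, "warning", "LEADING_CONTENT",
                          section = HEADER_SECTION, line = 1L, message = what)
  }

  sep <- layout$merge_sep

  # the header pseudo-section collects the KEY:VALUE fields of the
  # header line itself plus the top-of-file items (VERSION, CREATED_ON)
  header_items <- parse_header_fields(tokens[[hdr_at[[1]]]]$value %||% "")
  header_keys <- c("VERSION", "CREATED_ON", "STUDY_ID", "ANALYSIS_ID", "PROJECT_ID")

  secs <- list()
  cur <- NULL             # current section under construction (plain list)
  tbl <- NULL             # open table accumulator
  pending_units <- NULL
  end_seen <- FALSE
  post_end_flagged <- FALSE
  orphans <- character()
  orphan_lines <- integer()

  close_table <- function() {
    if (is.null(tbl)) return()
    arity_bad <- which(vapply(tbl$rows, length, 0L) != length(tbl$columns))
    dt <- data_table(
      kind = table_kind_for(tbl$name),
      units = pending_units %||% "",
      column_names = tbl$columns,
      factor_row = tbl$factor_row,
      feature_ids = tbl$ids,
      rows = tbl$rows,
      check = FALSE
    )
    for (j in arity_bad) {
      findings <<- add_issue(findings, "error", "ROW_ARITY",
        section = cur$name, key = tbl$ids[[j]], line = tbl$row_lines[[j]],
        message = sprintf("table row '%s' has %d values but the header declares %d columns",
                          tbl$ids[[j]], length(tbl$rows[[j]]), length(tbl$columns)))
    }
    cur$data_table <<- dt
    pending_units <<- NULL
    tbl <<- NULL
  }

  flush_section <- function() {
    if (is.null(cur)) return()
    if (!is.null(tbl)) {
      findings <<- add_issue(findings, "error", "TABLE_WITHOUT_END",
        section = cur$name, line = NA_integer_,
        message = paste0("table in section '", cur$name,
                         "' is not closed by a *_END sentinel"))
      close_table()
    }
    if (!is.null(pending_units)) {
      # a units item without any table: keep it as an ordinary item
      cur$items <<- merge_item(cur$items, "UNITS", pending_units, sep)
      pending_units <<- NULL
    }
    secs[[length(secs) + 1L]] <<- section(
      cur$name, items = cur$items, ssf_records = cur$ssf,
      data_table = cur$data_table
    )
    cur <<- NULL
  }

  for (i in seq_along(tokens)[-seq_len(hdr_at[[1]])]) {
    tok <- tokens[[i]]
    kind <- tok$kind
    if (kind == "BLANK") next
    if (end_seen) {
      if (!post_end_flagged) {
        findings <- add_issue(findings, "warning", "POST_END_CONTENT",
          section = NA_character_, line = tok$line,
          message = "content found after the '#END' marker")
        post_end_flagged <- TRUE
      }
      next
    }
    if (kind == "END_MARKER") {
      flush_section()
      end_seen <- TRUE
    } else if (kind == "SECTION_HEADER") {
      flush_section()
      cur <- list(name = tok$key, items = character(), ssf = list(),
                  data_table = NULL)
    } else if (kind == "TABLE_START") {
      if (!is.null(tbl)) close_table()
      tbl <- list(name = tok$key, columns = character(), factor_row = NULL,
                  ids = character(), rows = list(), row_lines = integer(),
                  n_data_rows = 0L)
    } else if (kind == "TABLE_HEADER_ROW") {
      tbl$columns <- tok$cells[-1]        # first cell is the corner label
    } else if (kind == "TABLE_DATA_ROW") {
      if (identical(tok$cells[[1]], "Factors") && tbl$n_data_rows == 0L &&
          is.null(tbl$factor_row)) {
        tbl$factor_row <- tok$cells[-1]
      } else {
        k <- length(tbl$ids) + 1L
        tbl$ids[[k]] <- tok$cells[[1]]
        tbl$rows[[k]] <- if (length(tok$cells) > 1L) tok$cells[-1] else character()
        tbl$row_lines[[k]] <- tok$line
        tbl$n_data_rows <- tbl$n_data_rows + 1L
      }
    } else if (kind == "TABLE_END") {
      close_table()
    } else if (kind == "ITEM") {
      key <- tok$key
      value <- tok$value %||% ""
      if (is.null(cur)) {
        if (key %in% header_keys) {
          header_items <- merge_item(header_items, key, value, sep)
        } else {
          orphans[[length(orphans) + 1L]] <- key
          orphan_lines[[length(orphan_lines) + 1L]] <- tok$line
        }
        next
      }
      if (identical(key, SSF_SECTION) && identical(cur$name, SSF_SECTION)) {
        cur$ssf[[length(cur$ssf) + 1L]] <- parse_ssf_row(value)
        next
      }
      if (identical(key, paste0(cur$name, ":UNITS")) || identical(key, "UNITS")) {
        pending_units <- value
        next
      }
      pfx <- unname(SECTION_PREFIX[cur$name] %|NA|% "")
      if (nzchar(pfx) && startsWith(key, paste0(pfx, ":"))) {
        key <- substring(key, nchar(pfx) + 2L)
      }
      cur$items <- merge_item(cur$items, key, value, sep)
    }
  }
  flush_section()

  hdr_sec <- section(HEADER_SECTION, items = header_items, prefix = "")
  secs <- c(list(hdr_sec), secs)

  if (length(orphans)) {
    secs[[length(secs) + 1L]] <- section("UNATTRIBUTED",
      items = named_chr(rep("", length(unique(orphans))), unique(orphans)))
    for (j in seq_along(orphans)) {
      findings <- add_issue(findings, "error", "ORPHAN_ITEM",
        section = "UNATTRIBUTED", key = orphans[[j]], line = orphan_lines[[j]],
        message = paste0("item '", orphans[[j]], "' appears outside any section"))
    }
  }

  mwtab_document(sections = secs, source_id = source_id,
                 findings = findings, end_marker = end_seen)
}

merge_item <- function(items, key, value, sep) {
  if (key %in% names(items)) {
    old <- items[[key]]
    items[[key]] <- if (nzchar(old)) paste(old, value, sep = sep) else value
  } else {
    items[[key]] <- value
  }
  items
}

parse_header_fields <- function(rest) {
  items <- character()
  if (nzchar(rest)) {
    m <- gregexpr("([A-Z][A-Z_]*):(\\S+)", rest)[[1]]
    if (m[[1]] != -1L) {
      for (frag in regmatches(rest, gregexpr("([A-Z][A-Z_]*):(\\S+)", rest))[[1]]) {
        key <- sub(":.*$", "", frag)
        items[[key]] <- sub("^[A-Z_]+:", "", frag)
      }
    }
  }
  items
}

parse_ssf_row <- function(value) {
  parts <- trimws(strsplit(value, "\t", fixed = TRUE)[[1]])
  st <- if (length(parts) >= 1L) parts[[1]] else ""
  id <- if (length(parts) >= 2L) parts[[2]] else ""
  factors <- if (length(parts) >= 3L) parse_factor_string(parts[[3]]) else character()
  extra <- if (length(parts) >= 4L) parse_additional_string(parts[[4]]) else character()
  ssf_record(subject_type = st, local_sample_id = id,
             factors = factors, additional_data = extra)
}

parse_factor_string <- function(s) {
  out <- character()
  if (!nzchar(s) || identical(s, "-")) return(out)
  for (piece in trimws(strsplit(s, "|", fixed = TRUE)[[1]])) {
    if (!nzchar(piece)) next
    key <- sub(":.*$", "", piece)
    val <- if (grepl(":", piece, fixed = TRUE)) sub("^[^:]*:", "", piece) else ""
    out[[trimws(key)]] <- trimws(val)
  }
  out
}

parse_additional_string <- function(s) {
  out <- character()
  if (!nzchar(s) || identical(s, "-")) return(out)
  for (piece in trimws(strsplit(s, ";", fixed = TRUE)[[1]])) {
    if (!nzchar(piece)) next
    key <- sub("=.*$", "", piece)
    val <- if (grepl("=", piece, fixed = TRUE)) sub("^[^=]*=", "", piece) else ""
    out[[trimws(key)]] <- trimws(val)
  }
  out
}

#' Parse mwTab text into a document
#'
#' Composition of [tokenize()] and [build_document()].
#'
#' @param text mwTab formatted text (single string or character vector of
#'   lines).
#' @inheritParams build_document
#' @return an [mwtab_document()].
#' @export
#' @examples
#' txt <- write_mwtab(generate_document(fixture_spec(seed = 7))$document)
#' doc <- parse_mwtab(txt)
#' get_value(doc, "PROJECT", "PROJECT_TITLE")
parse_mwtab <- function(text, source_id = "", layout = layout_policy()) {
  build_document(tokenize(text), source_id = source_id, layout = layout)
}

#' Serialize a document to mwTab text
#'
#' Emits the file header line, sections in stored order with prefixed
#' keys, table sentinels, and a final `#END`. Long values are re-wrapped
#' into repeated-key continuation lines at `layout$wrap` characters
#' (split at spaces), matching the format's multiline-string convention,
#' so `parse_mwtab(write_mwtab(doc))` reproduces the document.
#'
#' @param doc an [mwtab_document()].
#' @param layout a [layout_policy()].
#' @return a single string of mwTab text (LF line endings, trailing
#'   newline).
#' @export
write_mwtab <- function(doc, layout = layout_policy()) {
  stopifnot(inherits(doc, "mwtab_document"))
  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  hdr_items <- if (HEADER_SECTION %in% names(doc$sections))
    doc$sections[[HEADER_SECTION]]$items else character()
  line_fields <- intersect(c("STUDY_ID", "ANALYSIS_ID", "PROJECT_ID"), names(hdr_items))
  hdr_tok <- token("FILE_HEADER",
    value = paste(sprintf("%s:%s", line_fields, hdr_items[line_fields]), collapse = " "))
  push(detoken_line(hdr_tok, layout))
  for (key in setdiff(names(hdr_items), line_fields)) {
    for (ln in wrap_item_lines(key, hdr_items[[key]], layout)) push(ln)
  }

  for (sec in doc$sections) {
    if (identical(sec$name, HEADER_SECTION)) next
    push("#", sec$name)
    pfx <- if (nzchar(sec$prefix)) paste0(sec$prefix, ":") else ""
    for (key in names(sec$items)) {
      for (ln in wrap_item_lines(paste0(pfx, key), sec$items[[key]], layout)) push(ln)
    }
    for (rec in sec$ssf_records) {
      push(format_item_line(SSF_SECTION, format_ssf_fields(rec), layout))
    }
    dt <- sec$data_table
    if (!is.null(dt)) {
      if (dt$kind %in% RESULTS_KINDS) {
        push(format_item_line(paste0(sec$name, ":UNITS"), dt$units, layout))
      }
      push(sec$name, "_START")
      push(paste(c(table_corner_label(dt$kind), dt$column_names), collapse = "\t"))
      if (!is.null(dt$factor_row)) {
        push(paste(c("Factors", dt$factor_row), collapse = "\t"))
      }
      for (j in seq_along(dt$feature_ids)) {
        push(paste(c(dt$feature_ids[[j]], dt$rows[[j]]), collapse = "\t"))
      }
      push(sec$name, "_END")
    }
  }
  push("#END")
  paste0(paste(out, collapse = "\n"), "\n")
}

table_corner_label <- function(kind) {
  switch(kind,
    MS_METABOLITE_DATA = "Samples",
    NMR_BINNED_DATA = "Bin range(ppm)",
    METABOLITES = "metabolite_name",
    "Samples"
  )
}

format_ssf_fields <- function(rec) {
  factors <- if (length(rec$factors)) {
    paste(sprintf("%s:%s", names(rec$factors), rec$factors), collapse = " | ")
  } else "-"
  extra <- if (length(rec$additional_data)) {
    paste(sprintf("%s=%s", names(rec$additional_data), rec$additional_data),
          collapse = "; ")
  } else ""
  paste(c(rec$subject_type, rec$local_sample_id, factors, extra), collapse = "\t")
}

# greedy re-wrap of a long value into repeated-key continuation lines,
# splitting only at spaces; a single token longer than the wrap width
# stays whole on its own line
wrap_value <- function(value, width) {
  if (!nzchar(value) || nchar(value) <= width) return(value)
  words <- strsplit(value, " ", fixed = TRUE)[[1]]
  frags <- character()
  cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) > width && nzchar(cur)) {
      frags[[length(frags) + 1L]] <- cur
      cur <- w
    } else {
      cur <- cand
    }
  }
  if (nzchar(cur)) frags[[length(frags) + 1L]] <- cur
  frags
}

wrap_item_lines <- function(key, value, layout) {
  vapply(wrap_value(value, layout$wrap),
         function(v) format_item_line(key, v, layout), "")
}

#' Serialize a document to its JSON representation
#'
#' The JSON equivalent of the mwTab format: one top-level object whose
#' keys are the section names in document order (the header appears
#' under `"METABOLOMICS WORKBENCH"`). Ordinary sections map to objects
#' of key -> string; SUBJECT_SAMPLE_FACTORS maps to an array of records;
#' data sections map to `{"Units", "Samples", "Factors" (optional),
#' "Data"}` with one object per feature. All scalars are emitted as JSON
#' strings -- values are stored verbatim as text, which is what makes the
#' mapping lossless in both directions.
#'
#' @param doc an [mwtab_document()].
#' @param pretty pretty-print the JSON.
#' @return a single string of JSON text.
#' @export
write_json <- function(doc, pretty = FALSE) {
  stopifnot(inherits(doc, "mwtab_document"))
  top <- empty_json_object()
  for (sec in doc$sections) {
    top[[sec$name]] <- section_to_json(sec)
  }
  as.character(jsonlite::toJSON(top, auto_unbox = TRUE, pretty = pretty))
}

empty_json_object <- function() structure(list(), names = character())

chr_to_json_object <- function(v) {
  obj <- empty_json_object()
  for (k in names(v)) obj[[k]] <- unname(v[[k]])
  obj
}

section_to_json <- function(sec) {
  if (length(sec$ssf_records)) {
    return(lapply(sec$ssf_records, function(r) {
      obj <- empty_json_object()
      obj[["Subject type"]] <- r$subject_type
      obj[["Sample ID"]] <- r$local_sample_id
      obj[["Factors"]] <- chr_to_json_object(r$factors)
      obj[["Additional sample data"]] <- chr_to_json_object(r$additional_data)
      obj
    }))
  }
  dt <- sec$data_table
  if (!is.null(dt)) {
    obj <- empty_json_object()
    for (k in names(sec$items)) obj[[k]] <- unname(sec$items[[k]])
    obj[["Units"]] <- dt$units
    obj[["Samples"]] <- as.list(dt$column_names)
    if (!is.null(dt$factor_row)) obj[["Factors"]] <- as.list(dt$factor_row)
    fk <- json_feature_key(dt$kind)
    obj[["Data"]] <- lapply(seq_along(dt$feature_ids), function(j) {
      row <- empty_json_object()
      row[[fk]] <- dt$feature_ids[[j]]
      vals <- dt$rows[[j]]
      for (c in seq_along(vals)) {
        lab <- if (c <= length(dt$column_names)) dt$column_names[[c]]
               else paste0("_extra_", c)
        row[[lab]] <- vals[[c]]
      }
      row
    })
    return(obj)
  }
  chr_to_json_object(sec$items)
}

json_feature_key <- function(kind) {
  if (identical(kind, "NMR_BINNED_DATA")) "Bin range" else "Metabolite"
}

#' Parse the JSON representation into a document
#'
#' Inverse of [write_json()] on its image. Structurally foreign JSON
#' (e.g. SUBJECT_SAMPLE_FACTORS given as an object instead of an array,
#' or a non-object top level) raises a `MAPPING_ERROR` naming the
#' offending key; malformed JSON raises a `JSON_SYNTAX` error carrying
#' the parser's position message.
#'
#' @param text JSON text in the canonical mapping.
#' @param source_id provenance string recorded on the document.
#' @return an [mwtab_document()].
#' @export
parse_json <- function(text, source_id = "") {
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      stop_mwtab("JSON_SYNTAX", paste0("invalid JSON: ", conditionMessage(e)))
    }
  )
  if (!is.list(parsed) || is.null(names(parsed))) {
    stop_mwtab("MAPPING_ERROR", "top level of an mwTab JSON document must be an object",
               key = "<top>")
  }
  secs <- list()
  for (name in names(parsed)) {
    node <- parsed[[name]]
    secs[[length(secs) + 1L]] <- json_to_section(name, node)
  }
  if (!HEADER_SECTION %in% names(parsed)) {
    stop_mwtab("MAPPING_ERROR",
               paste0("JSON document lacks the '", HEADER_SECTION, "' header object"),
               key = HEADER_SECTION)
  }
  mwtab_document(sections = secs, source_id = source_id, end_marker = TRUE)
}

json_scalar <- function(x, where) {
  if (is.null(x)) return("")
  if (length(x) != 1L || is.list(x)) {
    stop_mwtab("MAPPING_ERROR", paste0("expected a scalar value at '", where, "'"),
               key = where)
  }
  as.character(x)
}

json_to_chr <- function(node, where) {
  if (length(node) == 0L) return(character())
  if (!is.list(node) || is.null(names(node))) {
    stop_mwtab("MAPPING_ERROR", paste0("expected an object at '", where, "'"), key = where)
  }
  named_chr(vapply(node, json_scalar, "", where = where), names(node))
}

json_to_section <- function(name, node) {
  if (identical(name, SSF_SECTION)) {
    if (!is.list(node) || !is.null(names(node))) {
      stop_mwtab("MAPPING_ERROR",
                 paste0("'", SSF_SECTION, "' must be an array of sample records"),
                 key = SSF_SECTION)
    }
    recs <- lapply(node, function(r) {
      ssf_record(
        subject_type = json_scalar(r[["Subject type"]], "Subject type"),
        local_sample_id = json_scalar(r[["Sample ID"]], "Sample ID"),
        factors = json_to_chr(r[["Factors"]] %||% list(), "Factors"),
        additional_data = json_to_chr(r[["Additional sample data"]] %||% list(),
                                      "Additional sample data")
      )
    })
    return(section(name, ssf_records = recs))
  }
  if (is.list(node) && !is.null(names(node)) && "Data" %in% names(node) &&
      "Samples" %in% names(node)) {
    kind <- table_kind_for(name)
    fk <- json_feature_key(kind)
    samples <- vapply(node[["Samples"]], json_scalar, "", where = "Samples")
    factor_row <- if ("Factors" %in% names(node)) {
      vapply(node[["Factors"]], json_scalar, "", where = "Factors")
    } else NULL
    data <- node[["Data"]]
    if (!is.list(data) || !is.null(names(data))) {
      stop_mwtab("MAPPING_ERROR", paste0("'Data' of section '", name, "' must be an array"),
                 key = name)
    }
    ids <- character(length(data))
    rows <- vector("list", length(data))
    for (j in seq_along(data)) {
      obj <- data[[j]]
      ids[[j]] <- json_scalar(obj[[fk]], fk)
      rest <- setdiff(names(obj), fk)
      # cells are read back in declared column order, missing cells empty
      rows[[j]] <- vapply(samples, function(s) {
        if (s %in% names(obj)) json_scalar(obj[[s]], s) else ""
      }, "", USE.NAMES = FALSE)
      extra <- setdiff(rest, samples)
      if (length(extra)) {
        rows[[j]] <- c(rows[[j]], vapply(obj[extra], json_scalar, "", where = name))
      }
    }
    items <- json_to_chr(node[setdiff(names(node), c("Units", "Samples", "Factors", "Data"))],
                         name)
    return(section(name, items = items,
                   data_table = data_table(kind,
                     units = json_scalar(node[["Units"]], "Units"),
                     column_names = samples, factor_row = factor_row,
                     feature_ids = ids, rows = rows, check = FALSE)))
  }
  section(name, items = json_to_chr(node, name))
}
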