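#' Lexical analysis of mwTab text
#'
#' `tokenize()` splits raw mwTab text into a flat, ordered stream of typed
#' tokens; it performs no grammar-level (cross-line) analysis beyond the
#' minimal state needed to recognise tab-separated table rows between
#' `*_START` / `*_END` sentinel lines. The lexer is total: it never fails
#' on decodable input -- irregular lines become diagnostic-carrying tokens
#' (`LEADING_CONTENT`) so that the validator, not the lexer, decides
#' severity.
#'
#' Token kinds:
#' \describe{
#'   \item{FILE_HEADER}{the first `#METABOLOMICS WORKBENCH` line; `value`
#'     holds the remainder of the line (e.g. `STUDY_ID:ST000001 ...`).}
#'   \item{SECTION_HEADER}{any other `#NAME` line; `key` is the section
#'     name (text after `#`, up to an optional colon, trimmed).}
#'   \item{END_MARKER}{the `#END` line.}
#'   \item{ITEM}{a key-value line; `key` is the first whitespace-delimited
#'     field, `value` the remainder after the separating whitespace run
#'     (trailing whitespace stripped). A key-only line yields `value = ""`.}
#'   \item{TABLE_START / TABLE_END}{`NAME_START` / `NAME_END` sentinel
#'     lines; `key` is `NAME`.}
#'   \item{TABLE_HEADER_ROW / TABLE_DATA_ROW}{tab-split rows between the
#'     sentinels; the first row is the header. `cells` holds the fields.}
#'   \item{BLANK}{an empty or whitespace-only line.}
#'   \item{LEADING_CONTENT}{a non-blank line encountered before the
#'     FILE_HEADER; `value` holds the raw line.}
#' }
#'
#' @param text a character vector (joined with newlines) or single string
#'   of mwTab formatted text. Must be valid UTF-8; a leading byte-order
#'   mark is tolerated and skipped.
#' @return an object of class `mwtab_tokens`: a list of tokens, each a
#'   list with elements `kind`, `key`, `value`, `cells`, `line` (1-based).
#' @seealso [detoken_line()] for the inverse, [build_document()] for the
#'   syntactic analysis that consumes the stream.
#' @export
#' @examples
#' toks <- tokenize("#METABOLOMICS WORKBENCH\nVERSION\t1\n#END")
#' toks[[2]]$kind   # "ITEM"
#' toks[[2]]$key    # "VERSION"
tokenize <- function(text) {
  if (!is.character(text)) {
    stop_mwtab("DECODE_ERROR", "input to tokenize() must be character text")
  }
  text <- paste(text, collapse = "\n")
  bad <- !validUTF8(text)
  if (any(bad)) {
    stop_mwtab("DECODE_ERROR", "input text is not valid UTF-8")
  }
  # tolerate a UTF-8 byte-order mark
  text <- sub("^﻿", "", text)
  lines <- split_lines(text)
  n <- length(lines)
  tokens <- vector("list", n)
  if (n == 0L) return(structure(tokens, class = "mwtab_tokens"))

  # strip trailing whitespace once, up front
  lines <- sub("[ \t]+$", "", lines)

  seen_header <- FALSE
  in_table <- FALSE
  expect_table_header <- FALSE

  for (i in seq_len(n)) {
    line <- lines[[i]]
    tok <- NULL
    if (line == "") {
      tok <- token("BLANK", line = i)
    } else if (startsWith(line, "#")) {
      # '#' lines always reset table state (a table left open is the
      # builder's TABLE_WITHOUT_END case, not the lexer's concern)
      in_table <- FALSE
      if (!seen_header && grepl("^#\\s*METABOLOMICS WORKBENCH", line)) {
        seen_header <- TRUE
        rest <- sub("^#\\s*METABOLOMICS WORKBENCH[ \t]*", "", line)
        tok <- token("FILE_HEADER", value = rest, line = i)
      } else if (grepl("^#\\s*END\\s*$", line)) {
        tok <- token("END_MARKER", line = i)
      } else {
        name <- sub("^#\\s*", "", line)
        name <- sub(":.*$", "", name)
        name <- trimws(name)
        tok <- token("SECTION_HEADER", key = name, line = i)
      }
    } else if (!seen_header) {
      tok <- token("LEADING_CONTENT", value = line, line = i)
    } else if (grepl("^[A-Z][A-Z0-9_]*_START$", line)) {
      in_table <- TRUE
      expect_table_header <- TRUE
      tok <- token("TABLE_START", key = sub("_START$", "", line), line = i)
    } else if (grepl("^[A-Z][A-Z0-9_]*_END$", line) && in_table) {
      in_table <- FALSE
      tok <- token("TABLE_END", key = sub("_END$", "", line), line = i)
    } else if (in_table) {
      cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(cells) == 0L) cells <- ""
      kind <- if (expect_table_header) "TABLE_HEADER_ROW" else "TABLE_DATA_ROW"
      expect_table_header <- FALSE
      tok <- token(kind, cells = cells, line = i)
    } else {
      key <- sub("^(\\S+).*$", "\\1", line)
      value <- sub("^\\S+[ \t]*", "", line)
      tok <- token("ITEM", key = key, value = value, line = i)
    }
    tokens[[i]] <- tok
  }
  structure(tokens, class = "mwtab_tokens")
}

token <- function(kind, key = NULL, value = NULL, cells = NULL, line = NA_integer_) {
  list(kind = kind, key = key, value = value, cells = cells, line = line)
}

#' Render one token back to an mwTab text line
#'
#' The inverse of lexing: produces a line whose tokenization (in stream
#' context) reproduces an equivalent token -- same kind, key, value and
#' cells. Table rows are joined with tabs; items use the layout policy's
#' key column (fixed-width padded key field, or plain single-tab
#' separation). A key longer than the fixed key column falls back to
#' single-tab separation with a warning.
#'
#' @param tok a token as produced by [tokenize()].
#' @param layout a [layout_policy()].
#' @return a single text line (no trailing newline).
#' @export
detoken_line <- function(tok, layout = layout_policy()) {
  switch(tok$kind,
    FILE_HEADER = {
      v <- tok$value %||% ""
      if (nzchar(v)) paste0("#METABOLOMICS WORKBENCH ", v) else "#METABOLOMICS WORKBENCH"
    },
    SECTION_HEADER = paste0("#", tok$key),
    END_MARKER = "#END",
    BLANK = "",
    TABLE_START = paste0(tok$key, "_START"),
    TABLE_END = paste0(tok$key, "_END"),
    TABLE_HEADER_ROW = paste(tok$cells, collapse = "\t"),
    TABLE_DATA_ROW = paste(tok$cells, collapse = "\t"),
    LEADING_CONTENT = tok$value %||% "",
    ITEM = format_item_line(tok$key, tok$value %||% "", layout),
    stop_mwtab("UNKNOWN_TOKEN_KIND", paste0("cannot render token of kind '", tok$kind, "'"))
  )
}

format_item_line <- function(key, value, layout) {
  if (!nzchar(value)) return(key)
  if (identical(layout$style, "fixed")) {
    if (nchar(key) >= layout$key_width) {
      warning(sprintf(
        "key '%s' exceeds the fixed key column width (%d); falling back to single-tab layout",
        key, layout$key_width
      ), call. = FALSE)
      return(paste0(key, "\t", value))
    }
    return(paste0(formatC(key, width = -layout$key_width), "\t", value))
  }
  paste0(key, "\t", value)
}

#' Serialization layout policy
#'
#' Controls how the writer lays out key-value lines. Deposited mwTab
#' files use a visually aligned key column; `style = "fixed"` reproduces
#' that (key left-padded to `key_width` characters, then a tab), while
#' `style = "tab"` emits plain `key<TAB>value` lines. `wrap` is the
#' maximum number of value characters per line before a long value is
#' re-wrapped into repeated-key continuation lines (the format's
#' multiline-string convention); `merge_sep` is the separator used when
#' continuation lines are merged back into one value at parse time.
#'
#' @param style `"fixed"` or `"tab"`.
#' @param key_width key column width in characters (fixed style only).
#' @param wrap maximum value characters per line before continuation
#'   wrapping; `Inf` disables wrapping.
#' @param merge_sep separator inserted between merged continuation
#'   fragments.
#' @return an object of class `mwtab_layout`.
#' @export
layout_policy <- function(style = c("fixed", "tab"), key_width = 33L,
                          wrap = 80L, merge_sep = " ") {
  style <- match.arg(style)
  stopifnot(is.numeric(key_width), key_width >= 1, is.numeric(wrap), wrap >= 1)
  structure(
    list(style = style, key_width = as.integer(key_width), wrap = wrap,
         merge_sep = merge_sep),
    class = "mwtab_layout"
  )
}

#' @export
print.mwtab_tokens <- function(x, ...) {
  kinds <- vapply(x, function(t) t$kind, "")
  cat("mwTab token stream:", length(x), "tokens\n")
  print(table(kinds))
  invisible(x)
}
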