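`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed toolkit error
#'
#' All errors raised by the package carry the condition classes
#' `mwtab_error` and `mwtab_<code>` (lower-cased), so callers can use
#' `tryCatch(..., mwtab_not_found = ...)` instead of matching message text.
#'
#' @param code stable machine token, e.g. `"NOT_FOUND"`.
#' @param message human-readable description.
#' @param ... additional condition fields (e.g. `section`, `key`).
#' @keywords internal
#' @noRd
stop_mwtab <- function(code, message, ...) {
  cond <- errorCondition(
    message,
    code = code,
    ...,
    class = c(paste0("mwtab_", tolower(code)), "mwtab_error")
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# ordered named character vector, the canonical in-memory form for
# key -> value mappings (preserves insertion order, all values text)
named_chr <- function(values = character(), names = character()) {
  v <- as.character(values)
  names(v) <- as.character(names)
  v
}

# split raw text into lines, accepting LF, CRLF and lone CR
split_lines <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (identical(text, "")) return(character())
  strsplit(text, "\r\n|\n|\r")[[1]]
}
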