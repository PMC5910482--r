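#' Fetch configuration for multi-source reading
#'
#' Network access is off by default and must be enabled per call; the
#' REST base URL and the analysis-id-to-URL template are configuration,
#' never hard-coded, so tests never touch the network.
#'
#' @param network allow URL / analysis-id sources to reach the network.
#' @param base_url base URL of the repository REST interface.
#' @param rest_template `sprintf` template expanding an analysis id to a
#'   download URL; `%s` is replaced by the id.
#' @param fail_fast raise per-file parse failures instead of yielding
#'   them as error records.
#' @param extensions file extensions (lower-case, no dot) accepted when
#'   scanning directories and archives.
#' @param text_loader optional function `(spec) -> text` replacing the
#'   built-in source opener -- a seam for tests (e.g. counting how many
#'   file texts are materialized at once).
#' @return an object of class `mwtab_fetch_config`.
#' @export
fetch_config <- function(network = FALSE,
                         base_url = "https://www.metabolomicsworkbench.org",
                         rest_template = NULL,
                         fail_fast = FALSE,
                         extensions = c("txt", "mwtab", "json"),
                         text_loader = NULL) {
  structure(
    list(
      network = isTRUE(network),
      base_url = base_url,
      rest_template = rest_template %||%
        paste0(base_url, "/rest/study/analysis_id/%s/mwtab/txt"),
      fail_fast = isTRUE(fail_fast),
      extensions = tolower(extensions),
      text_loader = text_loader
    ),
    class = "mwtab_fetch_config"
  )
}

ARCHIVE_COMPRESSION <- c(
  "\\.zip$" = "zip",
  "\\.tar\\.gz$" = "gzip-tar", "\\.tgz$" = "gzip-tar",
  "\\.tar\\.bz2$" = "bzip2-tar", "\\.tbz2$" = "bzip2-tar"
)

archive_compression <- function(path) {
  for (pat in names(ARCHIVE_COMPRESSION)) {
    if (grepl(pat, path, ignore.case = TRUE)) return(unname(ARCHIVE_COMPRESSION[[pat]]))
  }
  NULL
}

source_spec <- function(kind, address, member = NULL, compression = "none") {
  structure(list(kind = kind, address = address, member = member,
                 compression = compression),
            class = "mwtab_source")
}

#' @export
print.mwtab_source <- function(x, ...) {
  cat("<mwtab_source ", x$kind, "> ", x$address,
      if (!is.null(x$member)) paste0(" :: ", x$member), "\n", sep = "")
  invisible(x)
}

has_accepted_ext <- function(paths, extensions) {
  tolower(tools::file_ext(paths)) %in% extensions
}

#' Resolve a source address into concrete source specs
#'
#' A single address may stand for many files: a local file resolves to
#' one spec; a directory to one spec per contained file with an accepted
#' extension (lexicographic order); a `.zip` / `.tar.gz` / `.tar.bz2`
#' archive to one spec per member (archive order); an `http(s)` address
#' to one URL spec; and a bare `AN<digits>` analysis identifier to one
#' analysis-id spec.
#'
#' @param address the address to resolve.
#' @param config a [fetch_config()].
#' @return list of `mwtab_source` specs, in resolution order.
#' @export
resolve_source <- function(address, config = fetch_config()) {
  if (!is_string(address) || !nzchar(address)) {
    stop_mwtab("UNRECOGNIZED_ADDRESS", "source address must be a non-empty string")
  }
  if (grepl("^https?://", address)) {
    return(list(source_spec("url", address)))
  }
  if (grepl("^AN[0-9]+$", address)) {
    return(list(source_spec("analysis_id", address)))
  }
  if (dir.exists(address)) {
    files <- list.files(address, full.names = FALSE)
    files <- files[!dir.exists(file.path(address, files))]
    keep <- files[has_accepted_ext(files, config$extensions)]
    for (skipped in setdiff(files, keep)) {
      message("skipping '", skipped, "': extension not in accepted set")
    }
    keep <- sort(keep, method = "radix")
    return(lapply(keep, function(f) source_spec("local_file", file.path(address, f))))
  }
  if (file.exists(address)) {
    comp <- archive_compression(address)
    if (is.null(comp)) {
      ext <- tolower(tools::file_ext(address))
      if (ext %in% c("gz", "bz2", "xz", "rar", "7z", "tar")) {
        stop_mwtab("UNSUPPORTED_ARCHIVE",
                   paste0("unrecognized archive type: '", address,
                          "' (supported: .zip, .tar.gz, .tar.bz2)"))
      }
      return(list(source_spec("local_file", address)))
    }
    members <- list_archive_members(address, comp)
    keep <- members[has_accepted_ext(members, config$extensions)]
    return(lapply(keep, function(m) {
      source_spec("archive_member", address, member = m, compression = comp)
    }))
  }
  if (grepl("^(AN|ST)", address) && !grepl("[/\\\\]", address)) {
    stop_mwtab("UNRECOGNIZED_ADDRESS",
               paste0("'", address, "' looks like a repository id but is malformed ",
                      "(expected AN followed by digits)"))
  }
  stop_mwtab("NOT_FOUND", paste0("no such file or directory: '", address, "'"))
}

# members in archive order (stable streaming order), not name-sorted
list_archive_members <- function(address, compression) {
  if (identical(compression, "zip")) {
    info <- utils::unzip(address, list = TRUE)
    return(info$Name[!endsWith(info$Name, "/")])
  }
  members <- utils::untar(address, list = TRUE, tar = "internal")
  members[!endsWith(members, "/")]
}

#' Read the decoded text of one source
#'
#' @param spec an `mwtab_source` from [resolve_source()].
#' @param config a [fetch_config()]; URL and analysis-id sources require
#'   `network = TRUE` or an explicit `NETWORK_DISABLED` error is raised
#'   (never a hang).
#' @return the text of the member/file/response as one string.
#' @export
open_text <- function(spec, config = fetch_config()) {
  stopifnot(inherits(spec, "mwtab_source"))
  if (!is.null(config$text_loader)) return(config$text_loader(spec))
  switch(spec$kind,
    local_file = read_file_text(spec$address),
    archive_member = read_archive_member(spec),
    url = read_url_text(spec$address, config),
    analysis_id = read_url_text(sprintf(config$rest_template, spec$address), config),
    stop_mwtab("UNRECOGNIZED_ADDRESS", paste0("unknown source kind '", spec$kind, "'"))
  )
}

read_file_text <- function(path) {
  if (!file.exists(path)) {
    stop_mwtab("NOT_FOUND", paste0("no such file: '", path, "'"))
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  txt
}

read_archive_member <- function(spec) {
  if (identical(spec$compression, "zip")) {
    con <- unz(spec$address, spec$member, open = "rb")
    on.exit(close(con), add = TRUE)
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", n = 65536L)
      if (length(b) == 0L) break
      chunks[[length(chunks) + 1L]] <- b
    }
    txt <- rawToChar(do.call(c, chunks) %||% raw())
    Encoding(txt) <- "UTF-8"
    return(txt)
  }
  exdir <- tempfile("mwtab_untar_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::untar(spec$address, files = spec$member, exdir = exdir, tar = "internal")
  read_file_text(file.path(exdir, spec$member))
}

read_url_text <- function(url, config) {
  if (!config$network) {
    stop_mwtab("NETWORK_DISABLED",
               paste0("network access is disabled by configuration; cannot fetch '",
                      url, "' (pass fetch_config(network = TRUE) to allow it)"))
  }
  con <- url(url, open = "rb")
  on.exit(close(con), add = TRUE)
  txt <- paste(readLines(con, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  txt
}

#' Stream documents from one or more addresses
#'
#' The memory-efficient counterpart of parsing files one by one: returns
#' a reader object that resolves every address up front but materializes
#' at most one file's text at a time. Each call to [read_next()] yields
#' the next [mwtab_document()]; the format (mwTab vs JSON) is
#' auto-detected from the first non-blank character (`#` vs `{`).
#' Per-file parse failures are yielded as error records (class
#' `mwtab_error_record`, carrying the address and the condition), not
#' raised mid-stream, unless `fail_fast` is configured.
#'
#' @param ... one or more source addresses (files, directories,
#'   archives, URLs, analysis ids).
#' @param config a [fetch_config()].
#' @return an object of class `mwtab_reader`.
#' @seealso [read_next()], [read_all()]
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_fixture_corpus(dir, n = 2, seed = 1)
#' reader <- read_files(dir)
#' doc <- read_next(reader)
#' length(read_all(reader))  # remaining document
read_files <- function(..., config = fetch_config()) {
  addresses <- c(...)
  specs <- list()
  for (a in addresses) specs <- c(specs, resolve_source(a, config))
  env <- new.env(parent = emptyenv())
  env$specs <- specs
  env$i <- 0L
  env$config <- config
  structure(env, class = "mwtab_reader")
}

#' Number of sources remaining in a reader
#' @param reader an `mwtab_reader`.
#' @return `TRUE` if another document (or error record) is available.
#' @export
has_next <- function(reader) {
  stopifnot(inherits(reader, "mwtab_reader"))
  reader$i < length(reader$specs)
}

#' Yield the next document from a reader
#'
#' @param reader an `mwtab_reader` from [read_files()].
#' @return an [mwtab_document()], an `mwtab_error_record`
#'   (`list(address, member, error)`) for a file that failed to parse,
#'   or `NULL` when the stream is exhausted.
#' @export
read_next <- function(reader) {
  stopifnot(inherits(reader, "mwtab_reader"))
  if (!has_next(reader)) return(NULL)
  reader$i <- reader$i + 1L
  spec <- reader$specs[[reader$i]]
  sid <- paste0(spec$address, if (!is.null(spec$member)) paste0("::", spec$member))
  res <- tryCatch({
    text <- open_text(spec, reader$config)
    doc <- parse_source_text(text, sid)
    rm(text)
    doc
  }, mwtab_error = function(e) {
    if (reader$config$fail_fast) stop(e)
    structure(list(address = spec$address, member = spec$member, error = e),
              class = "mwtab_error_record")
  })
  res
}

#' Drain a reader into a list
#' @param reader an `mwtab_reader`.
#' @return list of documents and/or error records, in resolution order.
#' @export
read_all <- function(reader) {
  out <- list()
  while (has_next(reader)) out[[length(out) + 1L]] <- read_next(reader)
  out
}

# format auto-detection: first non-blank character decides
parse_source_text <- function(text, source_id) {
  first <- regmatches(text, regexpr("[^[:space:]]", text))
  if (length(first) == 1L && identical(first, "{")) {
    parse_json(text, source_id = source_id)
  } else {
    parse_mwtab(text, source_id = source_id)
  }
}

#' @export
print.mwtab_reader <- function(x, ...) {
  cat("<mwtab_reader> ", length(x$specs), " source(s), ",
      length(x$specs) - x$i, " remaining\n", sep = "")
  invisible(x)
}
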