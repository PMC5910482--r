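#' Batch conversion between mwTab and JSON
#'
#' Converts every file a source address resolves to (single file,
#' directory, or zip/tar archive) from one serialization to the other.
#' A single-file input produces a single output file; a directory or
#' archive input produces a directory or archive output with member
#' names preserved and extensions swapped (`.txt` <-> `.json`). Output
#' compression is inferred from the output address extension (`.zip`,
#' `.tar.gz`, `.tar.bz2`); any other extension-less address is written
#' as a directory.
#'
#' Per-file failures (e.g. a file that does not parse in the declared
#' input format) are recorded in the report, not fatal.
#'
#' @param in_address input file, directory or archive.
#' @param out_address output file, directory or archive.
#' @param from_format `"mwtab"`, `"json"`, or `NULL` to auto-detect per
#'   file from the first non-blank character.
#' @param to_format `"mwtab"` or `"json"`.
#' @param overwrite allow replacing an existing output.
#' @param layout a [layout_policy()] for mwTab output.
#' @param config a [fetch_config()].
#' @return a `mwtab_conversion_report`: list with `files_converted` and
#'   `failures` (list of `list(address, error)`).
#' @export
#' @examples
#' src <- tempfile(fileext = ".txt")
#' writeLines(write_mwtab(generate_document(fixture_spec(seed = 1))$document), src)
#' out <- tempfile(fileext = ".json")
#' convert(src, out, to_format = "json")$files_converted
convert <- function(in_address, out_address, from_format = NULL,
                    to_format = c("json", "mwtab"), overwrite = FALSE,
                    layout = layout_policy(), config = fetch_config()) {
  to_format <- match.arg(to_format)
  if (!is.null(from_format)) {
    from_format <- match.arg(from_format, c("mwtab", "json"))
  }
  specs <- tryCatch(resolve_source(in_address, config), mwtab_error = function(e) {
    stop_mwtab("UNRESOLVABLE_INPUT",
               paste0("cannot resolve input '", in_address, "': ", conditionMessage(e)))
  })
  if (length(specs) == 0L) {
    stop_mwtab("UNRESOLVABLE_INPUT",
               paste0("input '", in_address, "' resolves to no readable files"))
  }
  if (file.exists(out_address) && !overwrite) {
    stop_mwtab("OUTPUT_EXISTS",
               paste0("output '", out_address, "' exists; pass overwrite = TRUE to replace it"))
  }

  single <- length(specs) == 1L && specs[[1]]$kind %in% c("local_file", "url", "analysis_id") &&
    !dir.exists(in_address)
  out_comp <- archive_compression(out_address)

  failures <- list()
  converted <- 0L

  render <- function(spec) {
    sid <- paste0(spec$address, if (!is.null(spec$member)) paste0("::", spec$member))
    text <- open_text(spec, config)
    doc <- switch(from_format %||% "auto",
      mwtab = parse_mwtab(text, source_id = sid, layout = layout),
      json = parse_json(text, source_id = sid),
      parse_source_text(text, sid)
    )
    if (identical(to_format, "json")) paste0(write_json(doc, pretty = TRUE), "\n")
    else write_mwtab(doc, layout = layout)
  }

  out_ext <- if (identical(to_format, "json")) "json" else "txt"
  member_name <- function(spec) {
    base <- basename(spec$member %||% spec$address)
    paste0(tools::file_path_sans_ext(base), ".", out_ext)
  }

  if (single && is.null(out_comp) && !dir.exists(out_address)) {
    res <- tryCatch(render(specs[[1]]), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[1]] <- list(address = in_address, error = res)
    } else {
      writeLines(res, out_address, sep = "")
      converted <- 1L
    }
    return(conversion_report(converted, failures))
  }

  # many-to-many: write members into a staging directory, then either
  # leave it (directory output) or pack it into the requested archive
  stage <- if (is.null(out_comp)) out_address else tempfile("mwtab_convert_")
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  for (spec in specs) {
    nm <- member_name(spec)
    res <- tryCatch(render(spec), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(
        address = paste0(spec$address, if (!is.null(spec$member)) paste0("::", spec$member)),
        error = res)
    } else {
      writeLines(res, file.path(stage, nm), sep = "")
      converted <- converted + 1L
    }
  }
  if (!is.null(out_comp)) {
    on.exit(unlink(stage, recursive = TRUE), add = TRUE)
    if (file.exists(out_address)) unlink(out_address)
    pack_archive(stage, out_address, out_comp)
  }
  conversion_report(converted, failures)
}

# pack every file in `dir` into an archive at `out` (zip via the
# miniz-based zip package, tar via R's internal tar implementation)
pack_archive <- function(dir, out, compression) {
  members <- list.files(dir)
  out_abs <- file.path(normalizePath(dirname(out), mustWork = FALSE), basename(out))
  if (identical(compression, "zip")) {
    zip::zip(out_abs, files = members, root = dir, mode = "cherry-pick")
  } else {
    old <- setwd(dir)
    on.exit(setwd(old), add = TRUE)
    utils::tar(out_abs, files = members,
               compression = if (identical(compression, "gzip-tar")) "gzip" else "bzip2",
               tar = "internal")
  }
  invisible(out_abs)
}

conversion_report <- function(files_converted, failures) {
  structure(list(files_converted = files_converted, failures = failures),
            class = "mwtab_conversion_report")
}

#' @export
print.mwtab_conversion_report <- function(x, ...) {
  cat("Converted", x$files_converted, "file(s);", length(x$failures), "failure(s)\n")
  for (f in x$failures) {
    cat("  FAILED ", f$address, ": ", conditionMessage(f$error), "\n", sep = "")
  }
  invisible(x)
}
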